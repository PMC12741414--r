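# chemorep

Annotation and genomic analysis of chemosensory receptor gene repertoires
(ORs, V1Rs, V2Rs and their outparalogs such as CaSR) in R.

Large receptor families expand by tandem gene duplication, so
phylogenetically close paralogs tend to sit physically close in the
genome.  `chemorep` implements the full inference chain that turns raw
homology-search output into that conclusion:

1. **Screening** — forward-hit filtering (E < 1e-3 and alignment >= 250 AA
   against proteomes; E < 1e-10 against genomes), reciprocal best-hit
   confirmation against a curated family panel, a family-specific
   seven-transmembrane domain filter (>= 200 AA of TM7_3 coverage for
   V2Rs), merging of split translated-genome hits (< 100 kb gaps, same
   strand, 900 bp flanks), and reconciliation of gene-model vs
   genome-predicted candidates.
2. **Clade extraction** — maximal clades of focal genes with >= 5 members
   and bootstrap support >= 85 on a rooted gene tree, plus
   reference-anchored family classification (e.g. typical V2R vs CaSR vs
   V2R-like).
3. **Genomic distribution** — for every gene pair, the cophenetic
   (patristic) distance vs the genomic midpoint distance, the fraction of
   intraclade vs interclade pairs within 10 Mbp, and per-scaffold
   occupancy.
4. **Microsynteny** — landmark-anchored flanking-gene comparison across
   species with liftover filtering (E < 1e-100, identity > 99%).
5. **Expression** — log10(TPM + 0.001) transformation and organ-specificity
   calls (expressed at TPM > 1; highest by strict argmax across organs).
6. **Simulation** — a ground-truthed generator of family expansion by
   tandem duplication with occasional dispersal, emitting every file the
   pipeline consumes, so the whole chain is testable without downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on a simulated
repertoire (48 genes from 3 founders, 90% tandem duplication, 20 decoys):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_screen.R
Rscript analysis/03_clades.R
Rscript analysis/04_distribution.R
Rscript analysis/05_synteny.R
Rscript analysis/06_expression.R
Rscript analysis/07_report.R
```

Output of the screening and distribution stages (seed 1):

```
attrition: forward 48 -> reciprocal 48 -> domain 48
recall 100.0%, decoy leakage 0
89 genome hits merged into 5 loci
...
intraclade pairs within 10 Mbp: 84.5% (533/631)
interclade pairs within 10 Mbp: 1.2% (6/497)
top-scaffold concentration: 66.7%
```

Reading: all 48 true family members survive the three screening filters
while all 20 decoys are removed; the merged TBLASTN-style loci collapse
tandem arrays; and the tandem-duplication signature is visible as a large
gap between the intraclade (84.5%) and interclade (1.2%) fractions of gene
pairs lying within 10 Mbp of each other.  Stage tables land under
`results/`, and `07_report.R` writes a machine-readable
`results/pipeline/report.json`.

The same machinery is available programmatically:

```r
library(chemorep)
sim <- simulate_repertoire(sim_config(seed = 1))
survivors <- screen_family(sim$forward_hits, sim$reverse_hits, sim$domains,
                           sim$family_refs, family = "V2R")
clades <- extract_clades(sim$tree, survivors)
pairs <- build_pair_table(sim$genes, clades, sim$tree)
proximity_summary(pairs)   # intraclade vs interclade < 10 Mbp fractions
```

See `vignettes/repertoire-analysis.Rmd` for the full methods account:
threshold semantics, the maximal-clade rule, the midpoint distance
definition, simulator assumptions and known limitations.

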