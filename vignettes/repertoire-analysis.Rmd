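---
title: "Methods: chemosensory repertoire screening, clade extraction and genomic clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemosensory repertoire screening, clade extraction and genomic clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemorep)
```

## The problem

Chemosensory receptor families of vertebrates — odorant receptors (ORs),
vomeronasal type 1 and type 2 receptors (V1Rs, V2Rs) and trace
amine-associated receptors (TAARs) — are large, rapidly evolving GPCR
repertoires.  Annotating such a repertoire in a newly assembled genome is a
multi-stage inference: candidate sequences are screened from homology
searches, confirmed by reciprocal searches, filtered on protein-domain
content, grouped into clades on a gene tree, and characterised by where
they sit in the genome and where they are expressed.  Each stage has
thresholds whose exact semantics (strict or non-strict, per-hit or
aggregated) change the final gene counts, so this package pins every rule
down in tested code.

The package also answers a mechanistic question: gene families that expand
by **tandem duplication** leave a characteristic signature — phylogenetically
close paralogs sit physically close on the same scaffold.  The pipeline
quantifies that signature as the fraction of intraclade gene pairs lying
within a genomic distance cutoff, compared with interclade pairs.

## Screening model

A candidate passes the forward screen iff some hit has E-value strictly
below the cutoff (1e-3 against proteomes, 1e-10 against genomes) **and**
alignment length of at least 250 amino acids.  The strictness follows the
wording of the underlying protocol ("<" for E-values, ">=" for lengths).
Hits are evaluated per HSP; a sequence passes if any one hit passes.  We
chose per-HSP evaluation over summed coverage because HSP aggregation is
protocol-dependent and unstated; the choice is conservative for fragmented
loci, which are instead rescued by split-locus joining (below).

Reciprocal confirmation requires the candidate's best reverse hit — minimum
E-value, ties broken by maximum bitscore, then lexicographically smallest
subject id — to fall inside a curated panel of known family members.  This
operationalises "confirming homology" as a reciprocal-best-hit criterion;
the deterministic tie-break makes the call reproducible.

The domain filter differs by family: OR/V1R candidates need any
seven-transmembrane-class annotation, while V2R candidates need at least
200 AA of TM7_3 (PF00003) coverage, computed as the length of the union of
envelope intervals, so two overlapping envelopes are not double-counted.

Translated genome hits on the same scaffold and strand are merged
transitively when the inter-hit gap is below 100 kb, and each merged locus
gains 900 bp of flank (clipped at scaffold bounds when lengths are known)
for downstream coding prediction.  Gene-model and genome-predicted
candidates are reconciled by >= 1 bp same-strand interval overlap, falling
back to >= 99% peptide identity when a model entry has no coordinates; the
protocol reports matched counts but no matching rule, so both routes are
supported with coordinates as the default.

## Tree-based classification

Trees are consumed, not inferred: the package roots a gene tree on an
explicit outgroup (no midpoint fallback — a wrong root silently flips clade
calls), computes cophenetic distances as path sums of branch lengths, and
extracts clades gated on bootstrap support.

A node qualifies as a clade iff its leaves are all focal genes, it has at
least five of them, and its support is at least 85.  Among qualifying
nodes the **maximal** ones are selected (no qualifying ancestor), which
operationalises "defining clades as large as possible".  Supports are read
on the 0-100 scale; values that all lie in [0, 1] are rejected unless the
caller declares fractional supports, because silent rescaling risks
misreading a low-support integer tree.  Clade labels order by decreasing
size, then by first leaf name — figure-panel numbering is not reproducible,
so a deterministic convention replaces it.  Only all-focal nodes qualify,
consistent with clades described as containing the focal species' genes
alone.

Reference-anchored classification (used, e.g., to separate typical V2Rs
from CaSR and V2R-like outparalogs) defines each reference group's clade as
the smallest clade containing all of the group's reference leaves and
assigns a focal gene to the group with the smallest defining clade
containing it.

## Genomic distribution statistics

For every unordered gene pair the pipeline records the cophenetic distance
and the genomic distance, defined as the absolute difference of interval
midpoints — midpoints are insensitive to gene-length asymmetry, and the
point measure is otherwise unspecified.  Pairs on different scaffolds have
undefined genomic distance but still count in denominators, forced by the
published pair totals themselves (435 intraclade OR pairs across three
clades exceeds any single scaffold's pairing).  A pair is intraclade iff
both genes share a non-Else clade; pairs involving an Else gene count as
interclade, including Else-Else pairs.  The proximity fraction uses a
strict 10 Mbp cutoff.  The function asserts that class denominators sum to
C(n, 2) and flags — rather than reproduces — externally reported totals
that do not add up (the published V2R totals fall two pairs short of
C(135, 2); the discrepancy is unexplained, so the implementation surfaces
it).  The > 0.1 Mbp scaffold-length filter applies only to the occupancy
display ordering, not to pair statistics.

## Microsynteny and expression

Microsynteny around landmark genes (Plch1 and Mme/Nep for the V2R cluster)
uses eight flanking genes per side by default, assembly-liftover matches
accepted at E < 1e-100 and identity > 99 (best target kept, ambiguity
flagged), and orthology maps built at E < 1e-10.  Order conservation is
judged as monotonicity of the shared genes' positions in either direction,
so inversion of a whole block still counts as conserved; this monotonicity
rule is this package's operationalisation, as no explicit criterion was
stated.

Expression: TPM values are log10-transformed after adding a pseudocount of
0.001 (TPM 0 maps to -3).  A gene is "expressed" in the focal organ at
TPM strictly above 1 — stated explicitly only for V1Rs in the protocol, and
adopted here for all families as the single documented threshold — and
"highest" when the focal organ strictly exceeds every other organ; exact
ties do not count as highest (conservative, matching the reading of a
receptor expressed "at the same level" in a second organ as not
olfactory-specific).  One library per organ is assumed; replicates are not
modelled.

## The simulator: what it emulates and what it does not

`simulate_repertoire()` grows a family from `n_founders` founders (each on
its own scaffold) through `n_events` duplications.  With probability
`p_tandem` the copy lands at the nearest free position 5-50 kb from the
parent (downstream scanned first, deterministically); otherwise it
disperses to a uniform scaffold/position.  Duplications bifurcate the true
tree with exponential waiting-time branch lengths.  Founder-subtree roots
with >= 5 leaves receive supports drawn from 90-100, all other nodes from
20-70 — supports encode the ground truth rather than a bootstrap, because
the artifact tests clade-extraction logic, not tree inference.  Family
members receive passing hits (E <= 1e-50, length >= 300) and >= 200 AA of
TM7_3; decoys receive failing hits (E >= 1e-2 or length <= 150), reciprocal
best hits outside the family panel, and absent or short domains.  Focal
organ TPM is log-normal with meanlog `log(50)`, other organs `log(0.05)`,
sdlog 1 — roughly the separation seen between olfactory and non-olfactory
organs for receptor genes.

Defaults are fixed as the study conditions: 3 founders and 45 events
(mirroring an OR-sized family of ~48 genes in three lineages), p_tandem =
0.9 (the families analysed are overwhelmingly tandem-clustered), 20
scaffolds of 100 Mbp, 20 decoys.  A single global random stream keyed by
`seed` makes the whole object byte-reproducible.

What the simulator does **not** emulate: sequence-level evolution (no
substitution model — peptides are dummies), realistic E-value distributions
beyond pass/fail placement, assembly fragmentation or missing data, gene
losses, and bootstrap noise on deep nodes.  Passing tests therefore show
that the pipeline's logic recovers a known truth under clean conditions;
they do not show robustness to misassembly or alignment error on real
genomes.

## Numerical and degenerate-input choices

Internal coordinates are 0-based half-open; files use each format's native
convention (BED half-open, BLAST/TSV 1-based inclusive).  All threshold
comparisons at stated boundaries are strict for E-values, identities and
TPM, non-strict for lengths, supports and coverages, matching the
protocol's wording in each case.  An empty candidate set is a warning
report, not an error; a single-gene family produces zero pairs; interval
ties in tandem placement scan downstream first.  Clade extraction with no
qualifying node returns all-Else with a warning, and warns when fewer than
three clades are found.

## Problem sizes

The validation suite runs the cophenetic oracle on 200 random trees of up
to 32 leaves, exhaustive clade-extraction scans on 10 simulated trees,
and the tandem-signal comparison on 20 seeds per `p_tandem` level with the
default 48-gene family — sizes chosen so the full suite exercises every
code path in well under a minute on a laptop while keeping Monte-Carlo
comparisons stable.

## Known limitations

Reconciliation matches greedily in genome-candidate order when one genome
locus overlaps several model genes (arrays tighter than the locus flank can
be collapsed); the liftover filter assumes one true target per source;
`classify_by_reference_clade` requires the tree to be rooted so that
"smallest containing clade" is well defined; and the published-data
recomputation of the printed proximity fractions requires the original
supplementary gene lists and trees, which are not redistributed with the
package.
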