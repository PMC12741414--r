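#!/usr/bin/env Rscript
# Screen candidates from the simulated hit and domain tables: forward
# E-value/length filter, reciprocal best-hit confirmation against the
# curated family panel, and the TM7_3 domain-coverage filter.  Also joins
# the split TBLASTN-style genome hits into merged loci with 900 bp flanks.

library(chemorep)

sim_dir <- "results/sim"
forward <- read_blast_tab(file.path(sim_dir, "forward_hits.tsv"))
reverse <- read_blast_tab(file.path(sim_dir, "reverse_hits.tsv"))
domains <- read_domain_tab(file.path(sim_dir, "domains.tsv"))
genes <- read_gene_table(file.path(sim_dir, "genes.tsv"))
scaf_len <- read_scaffold_lengths(file.path(sim_dir, "scaffold_lengths.tsv"))

family_refs <- paste0("REF_V2R_", 1:3)
survivors <- screen_family(forward, reverse, domains, family_refs,
                           family = "V2R")
attr_counts <- attr(survivors, "attrition")
cat(sprintf("attrition: forward %d -> reciprocal %d -> domain %d\n",
            attr_counts["forward"], attr_counts["reciprocal"],
            attr_counts["domain"]))

truth <- read.delim(file.path(sim_dir, "truth.tsv"))
cat(sprintf("recall %.1f%%, decoy leakage %d\n",
            100 * mean(truth$gene_id %in% survivors),
            sum(!(survivors %in% truth$gene_id))))

screened <- genes[genes$gene_id %in% survivors, ]
write_candidate_table(screened, "results/candidates.tsv")

ghits <- read_blast_tab(file.path(sim_dir, "genome_hits.tsv"),
                        subject_is_genomic = TRUE)
loci <- join_split_loci(ghits, scaffold_lengths = scaf_len)
write_locus_bed(loci, "results/merged_loci.bed")
cat(sprintf("%d genome hits merged into %d loci\n", nrow(ghits), nrow(loci)))
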