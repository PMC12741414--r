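#!/usr/bin/env Rscript
# Extract bootstrap-gated clades (>= 5 genes, support >= 85) from the
# simulated gene tree and compare them with the true founder lineages.

library(chemorep)

tree <- read_support_tree("results/sim/tree.nwk")
cands <- read_gene_table("results/candidates.tsv")$gene_id
clades <- extract_clades(tree, cands)

write.table(data.frame(gene_id = names(clades), clade = unname(clades)),
            "results/clades.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("clade sizes:\n")
print(table(clades))

truth <- read.delim("results/sim/truth.tsv")
agree <- table(clades[truth$gene_id], truth$founder)
cat("clades vs founder lineages:\n")
print(agree)
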