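#!/usr/bin/env Rscript
# Organ-specificity calls from the simulated TPM matrix: a gene is
# "expressed" in the olfactory organ at TPM > 1 and "highest" when the
# olfactory organ strictly tops all eight other organs.

library(chemorep)

tpm <- read_tpm_matrix("results/sim/tpm.tsv")
cands <- read_gene_table("results/candidates.tsv")$gene_id
tpm <- tpm[rownames(tpm) %in% cands, ]

res <- classify_specificity(tpm, "olfactory_organ")
write.table(res$calls, "results/expression_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("%d of %d genes expressed (TPM > 1) in the olfactory organ;\n",
            res$summary[["n_expressed"]], res$summary[["n_total"]]))
cat(sprintf("%d show their highest expression there\n",
            res$summary[["n_highest"]]))

# log10(TPM + 0.001) heatmap ordered by the tree's leaf order
logm <- log_transform(tpm)
tree <- read_support_tree("results/sim/tree.nwk")
ord <- intersect(tree$tip.label, rownames(logm))
write.table(data.frame(gene_id = ord, round(logm[ord, ], 3),
                       check.names = FALSE),
            "results/expression_log10.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  df <- data.frame(gene = factor(rep(ord, ncol(logm)),
                                 levels = rev(ord)),
                   organ = factor(rep(colnames(logm), each = length(ord)),
                                  levels = colnames(logm)),
                   log10_tpm = as.vector(logm[ord, ]))
  p <- ggplot(df, aes(organ, gene, fill = log10_tpm)) +
    geom_tile() + scale_fill_viridis_c() +
    theme_minimal() + theme(axis.text.x = element_text(angle = 45, hjust = 1),
                            axis.text.y = element_blank())
  ggsave("results/expression_heatmap.pdf", p, width = 5, height = 7)
}
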