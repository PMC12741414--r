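#!/usr/bin/env Rscript
# Phylogenetic vs genomic distance for every gene pair, the <10 Mbp
# proximity fractions per clade class, and scaffold occupancy.  Writes the
# pair table, the proximity summary and (when ggplot2 is present) the
# scatter/violin figure.

library(chemorep)

genes <- read_gene_table("results/candidates.tsv")
tree <- read_support_tree("results/sim/tree.nwk")
cl <- read.delim("results/clades.tsv")
clades <- setNames(cl$clade, cl$gene_id)
scaf_len <- read_scaffold_lengths("results/sim/scaffold_lengths.tsv")

pairs <- build_pair_table(genes, clades, tree)
write.table(pairs, "results/pairs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, na = "NA")

prox <- proximity_summary(pairs)
write.table(prox, "results/proximity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (i in seq_len(nrow(prox)))
  cat(sprintf("%s pairs within 10 Mbp: %.1f%% (%d/%d)\n",
              prox$clade_class[i], prox$percent[i],
              prox$numerator[i], prox$denominator[i]))

occ <- scaffold_occupancy(genes, scaf_len)
write.table(occ, "results/scaffold_occupancy.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("top-scaffold concentration: %.1f%%\n",
            100 * attr(occ, "top_fraction")))

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  intra <- subset(pairs, scaffold_class == "intrascaffold")
  p <- ggplot(intra, aes(genomic_dist / 1e6, phylo_dist,
                         colour = clade_class)) +
    geom_point(alpha = 0.5, size = 0.8) +
    labs(x = "genomic distance (Mbp)", y = "phylogenetic distance",
         colour = NULL) +
    theme_minimal()
  ggsave("results/distance_scatter.pdf", p, width = 5, height = 4)
}
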