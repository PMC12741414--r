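#' Genomic distance between two genes
#'
#' Midpoint-to-midpoint distance in bp when both genes lie on the same
#' scaffold; `NA` (undefined) otherwise.  Midpoints are insensitive to
#' gene-length asymmetry, which is why they are used as the point measure.
#'
#' @param a,b single-row gene records with `scaffold`, `start`, `end`.
#' @return integer bp or `NA`.
#' @export
genomic_distance <- function(a, b) {
  if (a$scaffold != b$scaffold) return(NA_real_)
  mid_a <- (a$start + a$end) / 2
  mid_b <- (b$start + b$end) / 2
  round(abs(mid_a - mid_b))
}

#' Build the phylogenetic-vs-genomic gene-pair table
#'
#' One record per unordered pair of genes (`gene_a < gene_b`
#' lexicographically).  A pair is `intraclade` iff both genes share the same
#' non-`Else` clade label; pairs involving an `Else` gene — including
#' Else-Else pairs — count as `interclade`.  Genomic distance is undefined
#' for interscaffold pairs.
#'
#' @param genes gene table with `gene_id`, `scaffold`, `start`, `end`.
#' @param clades named character vector gene_id -> clade label.
#' @param tree rooted `ape::phylo` with branch lengths covering all genes,
#'   or a precomputed cophenetic matrix.
#' @return data.frame of pair records: `gene_a`, `gene_b`, `phylo_dist`,
#'   `genomic_dist`, `clade_class`, `scaffold_class`.
#' @export
build_pair_table <- function(genes, clades, tree) {
  dmat <- if (is.matrix(tree)) tree else cophenetic_distances(tree)
  missing <- setdiff(genes$gene_id, rownames(dmat))
  if (length(missing))
    stop("genes missing from tree: ", paste(missing, collapse = ", "))
  missing_cl <- setdiff(genes$gene_id, names(clades))
  if (length(missing_cl))
    stop("genes missing clade labels: ", paste(missing_cl, collapse = ", "))
  g <- genes[order(genes$gene_id), , drop = FALSE]
  n <- nrow(g)
  if (n < 2) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      phylo_dist = numeric(0), genomic_dist = numeric(0),
                      clade_class = character(0),
                      scaffold_class = character(0)))
  }
  idx <- combn(n, 2)
  ia <- idx[1, ]; ib <- idx[2, ]
  same_scaf <- g$scaffold[ia] == g$scaffold[ib]
  mid <- (g$start + g$end) / 2
  gd <- ifelse(same_scaf, round(abs(mid[ia] - mid[ib])), NA_real_)
  cl_a <- clades[g$gene_id[ia]]; cl_b <- clades[g$gene_id[ib]]
  intraclade <- cl_a == cl_b & cl_a != "Else"
  data.frame(
    gene_a = g$gene_id[ia], gene_b = g$gene_id[ib],
    phylo_dist = dmat[cbind(g$gene_id[ia], g$gene_id[ib])],
    genomic_dist = gd,
    clade_class = ifelse(intraclade, "intraclade", "interclade"),
    scaffold_class = ifelse(same_scaf, "intrascaffold", "interscaffold"),
    stringsAsFactors = FALSE
  )
}

#' Proximity fractions per clade class
#'
#' For each clade class, the fraction of gene pairs lying within a genomic
#' distance strictly below `threshold_bp` (default 10 Mbp).  Interscaffold
#' pairs have undefined distance and count only in the denominators.  The
#' function asserts that class denominators sum to `C(n, 2)` and attaches a
#' `consistency` attribute; an `expected_pairs` argument lets callers flag
#' externally reported totals that do not add up.
#'
#' @param pairs a pair table from [build_pair_table()].
#' @param threshold_bp genomic distance cutoff in bp (strict `<`).
#' @param expected_pairs optional externally reported total to check.
#' @return data.frame with one row per clade class: `clade_class`,
#'   `numerator`, `denominator`, `fraction` (also rendered to 0.1% in
#'   `percent`).
#' @export
proximity_summary <- function(pairs, threshold_bp = 10000000,
                              expected_pairs = NULL) {
  if (nrow(pairs) == 0) stop("empty pair table")
  classes <- c("intraclade", "interclade")
  rows <- lapply(classes, function(cl) {
    p <- pairs[pairs$clade_class == cl, , drop = FALSE]
    num <- sum(!is.na(p$genomic_dist) & p$genomic_dist < threshold_bp)
    den <- nrow(p)
    data.frame(clade_class = cl, numerator = num, denominator = den,
               fraction = if (den > 0) num / den else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$percent <- round(100 * out$fraction, 1)
  total <- sum(out$denominator)
  n_genes <- length(unique(c(pairs$gene_a, pairs$gene_b)))
  expected <- choose(n_genes, 2)
  consistent <- total == expected
  if (!consistent)
    warning(sprintf("pair-class denominators sum to %d but C(%d,2) = %d",
                    total, n_genes, expected))
  if (!is.null(expected_pairs) && expected_pairs != total)
    warning(sprintf(
      "externally reported pair total %d differs from computed C(n,2) = %d",
      expected_pairs, total))
  attr(out, "consistency") <- list(total_pairs = total,
                                   expected_pairs = expected,
                                   consistent = consistent)
  out
}

#' Scaffold occupancy of a gene set
#'
#' Counts genes per scaffold, ordered by decreasing scaffold length (the
#' genome-browser arrangement), and reports the fraction of genes on the
#' most occupied scaffold.  Scaffolds at or below `min_scaffold_len` are
#' still counted but flagged as below the display cutoff.
#'
#' @param genes gene table with `gene_id`, `scaffold`.
#' @param scaffold_lengths named vector of scaffold lengths.
#' @param min_scaffold_len display cutoff in bp (default 0.1 Mbp, strict
#'   `>` to be shown).
#' @return data.frame `scaffold`, `length`, `n_genes`, `shown`; attribute
#'   `top_fraction` = max count / total genes.
#' @export
scaffold_occupancy <- function(genes, scaffold_lengths,
                               min_scaffold_len = 100000) {
  counts <- table(genes$scaffold)
  len <- scaffold_lengths[names(counts)]
  out <- data.frame(scaffold = names(counts),
                    length = as.numeric(len),
                    n_genes = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$shown <- !is.na(out$length) & out$length > min_scaffold_len
  out <- out[order(-out$length, out$scaffold), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "top_fraction") <- max(out$n_genes) / nrow(genes)
  out
}
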