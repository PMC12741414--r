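# Fixture builders shared across the suite.  Everything is generated in
# code; no binary fixtures.

make_hits <- function(query_id, subject_id, evalue, align_len,
                      bitscore = 100, scaffold = "", sstart = NA,
                      send = NA, strand = "n/a", pident = 50) {
  data.frame(query_id = query_id, subject_id = subject_id,
             percent_identity = pident, align_len = as.integer(align_len),
             evalue = evalue, bitscore = bitscore,
             subject_scaffold = scaffold, subject_start = sstart,
             subject_end = send, subject_strand = strand,
             stringsAsFactors = FALSE)
}

make_genes <- function(gene_id, scaffold, start, end, strand = "+",
                       family = "OR", source = "gene_model") {
  data.frame(gene_id = gene_id, family = family, source = source,
             scaffold = scaffold, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

# Independent cophenetic oracle: shortest paths on the weighted tree graph.
oracle_cophenetic <- function(tree) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = tree$edge[, 1], to = tree$edge[, 2],
               weight = tree$edge.length),
    directed = FALSE)
  tips <- as.character(seq_along(tree$tip.label))
  d <- igraph::distances(g, v = tips, to = tips)
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# Independent clade-extraction oracle: exhaustive node scan with explicit
# subset-based maximality filtering, built on ape::extract.clade.
oracle_extract_clades <- function(tree, focal, min_size = 5,
                                  min_support = 85) {
  ntip <- length(tree$tip.label)
  sup <- suppressWarnings(as.numeric(tree$node.label))
  qualifying <- list()
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    leaves <- ape::extract.clade(tree, node)$tip.label
    s <- sup[node - ntip]
    if (length(leaves) >= min_size && all(leaves %in% focal) &&
        !is.na(s) && s >= min_support)
      qualifying[[length(qualifying) + 1]] <- sort(leaves)
  }
  maximal <- Filter(function(a) {
    !any(vapply(qualifying, function(b)
      length(b) > length(a) && all(a %in% b), logical(1)))
  }, qualifying)
  maximal <- unique(maximal)
  ord <- order(-lengths(maximal),
               vapply(maximal, `[`, character(1), 1))
  assign <- stats::setNames(rep("Else", length(focal)), focal)
  for (k in seq_along(ord)) assign[maximal[[ord[k]]]] <- paste0("Clade", k)
  assign
}

# A tree with one well-supported planted clade of six focal genes.
planted_tree <- function() {
  ape::read.tree(text = paste0(
    "(((((f1:1,f2:1)40:1,(f3:1,f4:1)50:1)95:1,(f5:1,f6:1)60:1)95:1,",
    "(f7:1,f8:1)40:1)30:1,(x1:1,x2:1)99:1);"))
}
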