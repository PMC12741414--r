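#' Validate a support tree
#'
#' Checks that an `ape::phylo` object is usable as a gene tree with
#' bootstrap supports: unique leaf labels, non-negative branch lengths and
#' internal-node supports on the 0-100 scale.  Node labels in `[0, 1]` are
#' rejected unless `fractional_ok = TRUE`, because silently rescaling
#' fractional supports risks misreading a 0-100 tree with tiny supports.
#'
#' @param tree an `ape::phylo`.
#' @param require_lengths require branch lengths (needed for distances).
#' @param fractional_ok accept supports in `[0, 1]` and rescale to 0-100.
#' @return the tree, with numeric supports in attribute handling left to
#'   callers via [node_supports()].
#' @export
validate_tree <- function(tree, require_lengths = FALSE,
                          fractional_ok = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("leaf labels must be unique")
  if (require_lengths) {
    if (is.null(tree$edge.length)) stop("tree has no branch lengths")
    if (any(is.na(tree$edge.length))) stop("missing branch length")
    if (any(tree$edge.length < 0)) stop("negative branch length")
  }
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup <- sup[!is.na(sup)]
  if (length(sup)) {
    if (any(sup < 0 | sup > 100)) stop("supports must lie in [0, 100]")
    if (!fractional_ok && all(sup <= 1) && any(sup > 0))
      stop("supports look fractional (all <= 1); ",
           "pass fractional_ok = TRUE to rescale")
  }
  tree
}

#' Internal-node supports of a tree
#'
#' @param tree an `ape::phylo` with node labels carrying supports.
#' @param fractional_ok rescale supports in `[0, 1]` to 0-100.
#' @return numeric vector of length `tree$Nnode` (NA where absent),
#'   indexed by internal node number minus `Ntip`.
#' @export
node_supports <- function(tree, fractional_ok = FALSE) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  sup <- suppressWarnings(as.numeric(tree$node.label))
  ok <- !is.na(sup)
  if (fractional_ok && any(ok) && all(sup[ok] <= 1)) sup <- sup * 100
  sup
}

#' Root a tree on an outgroup
#'
#' Roots an unrooted gene tree on the edge separating a monophyletic
#' outgroup from the ingroup, keeping node labels attached to the correct
#' bipartitions.  A non-monophyletic outgroup is an error naming the
#' interleaved leaves.
#'
#' @param tree an `ape::phylo`.
#' @param outgroup character vector of outgroup leaf labels.
#' @return a rooted `ape::phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  validate_tree(tree)
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing))
    stop("outgroup leaves absent from tree: ", paste(missing, collapse = ", "))
  if (length(outgroup) > 1) {
    # monophyly in the unrooted sense: check on a tree rooted at an ingroup leaf
    anchor <- setdiff(tree$tip.label, outgroup)[1]
    tmp <- ape::root(tree, outgroup = anchor, resolve.root = TRUE)
    if (!ape::is.monophyletic(tmp, outgroup)) {
      mrca <- ape::getMRCA(tmp, outgroup)
      inside <- ape::extract.clade(tmp, mrca)$tip.label
      stop("outgroup is not monophyletic; interleaved ingroup leaves: ",
           paste(setdiff(inside, outgroup), collapse = ", "))
    }
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE, edgelabel = TRUE)
}

#' Cophenetic (patristic) distances between leaves
#'
#' Sum of branch lengths on the unique path between each leaf pair.
#'
#' @param tree an `ape::phylo` with branch lengths.
#' @return symmetric numeric matrix with zero diagonal, leaf labels as
#'   dimnames.
#' @export
cophenetic_distances <- function(tree) {
  validate_tree(tree, require_lengths = TRUE)
  ape::cophenetic.phylo(tree)
}

# leaf labels under each internal node, as a list indexed by node number
clade_leafsets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  # postorder guarantees children are visited before parents
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1]; ch <- edge[i, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Extract maximal supported clades of focal genes
#'
#' A node qualifies iff all its leaves are focal genes, it has at least
#' `min_size` leaves and its support is at least `min_support`.  The
#' selected clades are the maximal qualifying nodes (no qualifying node is
#' an ancestor of another selected one), operationalizing the aim of
#' defining clades as large as possible.  Clades are labelled
#' `Clade1..CladeK` by decreasing size, ties broken alphabetically by their
#' first (sorted) leaf; focal genes in no clade are labelled `"Else"`.
#'
#' @param tree rooted `ape::phylo` with supports as node labels.
#' @param focal character vector of focal leaf labels.
#' @param min_size minimum clade size (>= 2).
#' @param min_support minimum bootstrap support (0-100 scale).
#' @param fractional_ok accept fractional supports.
#' @param min_clades emit a warning when fewer than this many clades are
#'   found (the survey design aimed for at least three).
#' @return named character vector: leaf -> clade label, for all focal leaves.
#' @export
extract_clades <- function(tree, focal, min_size = 5L, min_support = 85,
                           fractional_ok = FALSE, min_clades = 3L) {
  if (min_size < 2) stop("min_size must be at least 2")
  validate_tree(tree, fractional_ok = fractional_ok)
  missing <- setdiff(focal, tree$tip.label)
  if (length(missing))
    stop("focal genes absent from tree: ", paste(missing, collapse = ", "))
  ntip <- length(tree$tip.label)
  sets <- clade_leafsets(tree)
  sup <- node_supports(tree, fractional_ok)
  qualifies <- logical(tree$Nnode)
  for (j in seq_len(tree$Nnode)) {
    leaves <- sets[[ntip + j]]
    qualifies[j] <- length(leaves) >= min_size &&
      all(leaves %in% focal) &&
      !is.na(sup[j]) && sup[j] >= min_support
  }
  # maximality: drop qualifying nodes with a qualifying ancestor
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  selected <- integer(0)
  for (j in which(qualifies)) {
    node <- ntip + j
    anc_ok <- FALSE
    p <- parent[node]
    while (p != 0) {
      if (p > ntip && qualifies[p - ntip]) { anc_ok <- TRUE; break }
      p <- parent[p]
    }
    if (!anc_ok) selected <- c(selected, node)
  }
  assign <- setNames(rep("Else", length(focal)), focal)
  if (length(selected)) {
    sel_sets <- lapply(selected, function(n) sort(sets[[n]]))
    ord <- order(-lengths(sel_sets),
                 vapply(sel_sets, `[`, character(1), 1))
    for (k in seq_along(ord)) {
      assign[sel_sets[[ord[k]]]] <- paste0("Clade", k)
    }
  }
  n_clades <- length(selected)
  if (n_clades < min_clades)
    warning(sprintf("only %d clade(s) found (aimed for >= %d)",
                    n_clades, min_clades))
  assign
}

#' Classify focal genes by reference-anchored clades
#'
#' Each reference group (e.g. gnathostome V2Rs, CaSRs, V2R-like genes)
#' defines the smallest clade containing all of its reference leaves (the
#' clade of their most recent common ancestor on the rooted tree).  A focal
#' gene is assigned to the group whose defining clade containing it is the
#' smallest; focal genes in no defining clade are `"unclassified"`.
#'
#' @param tree rooted `ape::phylo`.
#' @param refs named list: group name -> character vector of reference
#'   leaf labels (pairwise disjoint).
#' @param focal character vector of focal leaf labels.
#' @return named character vector: focal leaf -> group name or
#'   `"unclassified"`.
#' @export
classify_by_reference_clade <- function(tree, refs, focal) {
  validate_tree(tree)
  if (anyDuplicated(unlist(refs)))
    stop("reference groups must be pairwise disjoint")
  for (g in names(refs)) {
    missing <- setdiff(refs[[g]], tree$tip.label)
    if (length(missing))
      stop("reference group '", g, "' absent from tree: ",
           paste(missing, collapse = ", "))
  }
  defining <- lapply(refs, function(leaves) {
    if (length(leaves) == 1) return(leaves)
    mrca <- ape::getMRCA(tree, leaves)
    ape::extract.clade(tree, mrca)$tip.label
  })
  out <- setNames(rep("unclassified", length(focal)), focal)
  for (leaf in focal) {
    containing <- names(defining)[vapply(defining, function(s) leaf %in% s,
                                         logical(1))]
    if (length(containing)) {
      sizes <- lengths(defining[containing])
      out[leaf] <- containing[which.min(sizes)]
    }
  }
  out
}

#' Read a newick tree with internal-node supports
#'
#' Accepts plain internal labels (`")95:0.1"`).
#'
#' @param path path to a newick file.
#' @return an `ape::phylo`.
#' @export
read_support_tree <- function(path) {
  tree <- ape::read.tree(path)
  validate_tree(tree)
  tree
}

#' Write a newick tree (supports as plain internal labels)
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @export
write_support_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
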