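#' Pipeline configuration
#'
#' Collects input paths and stage parameters for one family analysis.
#' All referenced files must exist at construction time, so configuration
#' errors surface before any compute.
#'
#' @param family family label (e.g. `"V2R"`).
#' @param paths named list of input files: `tree`, `forward_hits`,
#'   `reverse_hits`, `domains`, `genes`, `scaffold_lengths`, and optionally
#'   `genome_hits`, `tpm`.
#' @param known_family_ids curated reference ids for reciprocal
#'   confirmation.
#' @param outgroup optional outgroup leaves used to root the tree.
#' @param thresholds a [screen_thresholds()].
#' @param min_size,min_support clade-extraction parameters.
#' @param threshold_bp genomic proximity cutoff in bp.
#' @param focal_organ,expressed_threshold expression-call parameters.
#' @param out_dir directory for stage outputs.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(family, paths, known_family_ids,
                            outgroup = NULL,
                            thresholds = screen_thresholds(),
                            min_size = 5L, min_support = 85,
                            threshold_bp = 10000000,
                            focal_organ = "olfactory_organ",
                            expressed_threshold = 1,
                            out_dir = tempfile("chemorep_")) {
  required <- c("tree", "forward_hits", "reverse_hits", "domains",
                "genes", "scaffold_lengths")
  missing <- setdiff(required, names(paths))
  if (length(missing))
    stop("configuration error: missing input paths: ",
         paste(missing, collapse = ", "))
  for (nm in names(paths))
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]]))
      stop("configuration error: file not found for '", nm, "': ",
           paths[[nm]])
  if (length(known_family_ids) == 0)
    stop("configuration error: known_family_ids must be non-empty")
  cfg <- as.list(environment())
  cfg$required <- NULL; cfg$missing <- NULL; cfg$nm <- NULL
  class(cfg) <- "pipeline_config"
  cfg
}

#' Consistency-checked per-family count block
#'
#' @param candidates character vector of screened candidate ids.
#' @param clades named character vector gene_id -> clade label (may cover a
#'   subset when no tree was available).
#' @param calls expression calls (from [classify_specificity()]) or `NULL`
#'   when no expression matrix was supplied.
#' @return list of counts; clade sizes plus Else always sum to the number
#'   of genes with clade labels.
#' @export
summarize_counts <- function(candidates, clades, calls = NULL) {
  extra <- setdiff(names(clades), candidates)
  lost <- setdiff(candidates, names(clades))
  if (length(extra) || length(lost))
    stop("mismatched gene sets between screening and clades; ",
         "symmetric difference: ",
         paste(c(extra, lost), collapse = ", "))
  clade_sizes <- as.list(table(clades))
  block <- list(n_candidates = length(candidates),
                clade_sizes = clade_sizes,
                n_clades = sum(names(clade_sizes) != "Else"))
  if (is.null(calls)) {
    block$expression <- "absent"
  } else {
    calls_ids <- calls$calls$gene_id
    sym <- c(setdiff(calls_ids, candidates), setdiff(candidates, calls_ids))
    if (length(sym))
      stop("mismatched gene sets between screening and expression; ",
           "symmetric difference: ", paste(sym, collapse = ", "))
    block$expression <- as.list(calls$summary)
  }
  block
}

#' Run the full analysis pipeline for one family
#'
#' Screening (forward filter, reciprocal confirmation, domain filter),
#' tree rooting and clade extraction, phylogenetic-vs-genomic pair
#' statistics, scaffold occupancy, and (when a TPM matrix is supplied)
#' organ-specificity calls.  All stage outputs are written as TSV under the
#' configured output directory alongside a machine-readable JSON report;
#' the run is deterministic given its inputs.
#'
#' @param config a [pipeline_config()].
#' @return the analysis report (list), invisibly also written to
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(w) warnings_log <<- c(warnings_log, w)
  log_stage <- function(stage, n_in, n_out)
    message(sprintf("[%s] in=%d out=%d", stage, n_in, n_out))

  forward <- read_blast_tab(config$paths$forward_hits)
  reverse <- read_blast_tab(config$paths$reverse_hits)
  domains <- read_domain_tab(config$paths$domains)
  genes <- read_gene_table(config$paths$genes)
  scaf_len <- read_scaffold_lengths(config$paths$scaffold_lengths)
  tree <- read_support_tree(config$paths$tree)

  survivors <- screen_family(forward, reverse, domains,
                             config$known_family_ids,
                             family = config$family,
                             thresholds = config$thresholds)
  attrition <- attr(survivors, "attrition")
  log_stage("screen", length(unique(forward$subject_id)), length(survivors))

  report <- list(version = "1", family = config$family,
                 thresholds = unclass(config$thresholds),
                 attrition = as.list(attrition))
  if (length(survivors) == 0) {
    note("no candidates survived screening")
    report$n_candidates <- 0L
    report$warnings <- warnings_log
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    return(report)
  }

  genes <- genes[genes$gene_id %in% survivors, , drop = FALSE]
  write_candidate_table(genes, file.path(config$out_dir, "candidates.tsv"))

  if (!is.null(config$paths$genome_hits)) {
    ghits <- read_blast_tab(config$paths$genome_hits,
                            subject_is_genomic = TRUE)
    loci <- join_split_loci(ghits, config$thresholds, scaf_len)
    write_locus_bed(loci, file.path(config$out_dir, "loci.bed"))
    report$n_merged_loci <- nrow(loci)
  }

  if (!is.null(config$outgroup))
    tree <- root_with_outgroup(tree, config$outgroup)
  clades <- withCallingHandlers(
    extract_clades(tree, survivors, min_size = config$min_size,
                   min_support = config$min_support),
    warning = function(w) { note(conditionMessage(w))
                            invokeRestart("muffleWarning") })
  write.table(data.frame(gene_id = names(clades), clade = unname(clades)),
              file.path(config$out_dir, "clades.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("clades", length(survivors),
            length(unique(clades[clades != "Else"])))

  pairs <- build_pair_table(genes, clades, tree)
  write.table(pairs, file.path(config$out_dir, "pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  prox <- NULL
  if (nrow(pairs) > 0) {
    prox <- withCallingHandlers(
      proximity_summary(pairs, config$threshold_bp),
      warning = function(w) { note(conditionMessage(w))
                              invokeRestart("muffleWarning") })
    write.table(prox, file.path(config$out_dir, "proximity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    note("fewer than two genes; no pair statistics")
  }
  occ <- scaffold_occupancy(genes, scaf_len)
  write.table(occ, file.path(config$out_dir, "scaffold_occupancy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  calls <- NULL
  if (!is.null(config$paths$tpm)) {
    tpm <- read_tpm_matrix(config$paths$tpm)
    tpm <- tpm[rownames(tpm) %in% survivors, , drop = FALSE]
    calls <- classify_specificity(tpm, config$focal_organ,
                                  config$expressed_threshold)
    write.table(calls$calls, file.path(config$out_dir, "expression_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  counts <- summarize_counts(survivors, clades, calls)
  report <- c(report, counts)
  if (!is.null(prox)) {
    report$proximity <- lapply(seq_len(nrow(prox)), function(i) as.list(prox[i, ]))
    report$pair_consistency <- attr(prox, "consistency")
  }
  report$top_scaffold_fraction <- attr(occ, "top_fraction")
  report$warnings <- warnings_log
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report
}
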