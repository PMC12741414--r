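#' Default screening thresholds
#'
#' The homology-search and domain-filter thresholds used for repertoire
#' screening.  E-value cutoffs are strict inequalities ("<"), alignment
#' length and domain coverage non-strict (">=").
#'
#' @param max_evalue_proteome E-value cutoff for protein-vs-proteome searches.
#' @param min_alen minimum alignment length in amino acids.
#' @param max_evalue_genome E-value cutoff for translated genome searches.
#' @param min_domain_coverage_v2r minimum total TM7_3 envelope coverage (AA)
#'   required for V2R candidates.
#' @param max_join_gap maximum inter-hit gap (bp) for joining split loci on
#'   the same scaffold and strand.
#' @param flank flanking sequence (bp) added to each merged locus for
#'   downstream coding prediction.
#' @return a list of class `screen_thresholds`.
#' @export
screen_thresholds <- function(max_evalue_proteome = 1e-3,
                              min_alen = 250L,
                              max_evalue_genome = 1e-10,
                              min_domain_coverage_v2r = 200L,
                              max_join_gap = 100000L,
                              flank = 900L) {
  th <- list(max_evalue_proteome = max_evalue_proteome,
             min_alen = as.integer(min_alen),
             max_evalue_genome = max_evalue_genome,
             min_domain_coverage_v2r = as.integer(min_domain_coverage_v2r),
             max_join_gap = as.integer(max_join_gap),
             flank = as.integer(flank))
  if (any(unlist(th) <= 0)) stop("all screening thresholds must be positive")
  class(th) <- "screen_thresholds"
  th
}

#' Filter forward homology hits
#'
#' A hit passes iff its E-value is strictly below the mode's cutoff AND its
#' alignment length is at least `min_alen`.  A sequence passes iff any of
#' its hits passes (per-HSP evaluation; no coverage summing).
#'
#' @param hits hit table (see [read_blast_tab()]).
#' @param thresholds a [screen_thresholds()] object.
#' @param mode `"proteome"` (cutoff `max_evalue_proteome`) or `"genome"`
#'   (cutoff `max_evalue_genome`).
#' @return list with `hits` (the passing subset), `query_ids` and
#'   `subject_ids` (unique ids with at least one passing hit).
#' @export
filter_forward_hits <- function(hits, thresholds = screen_thresholds(),
                                mode = c("proteome", "genome")) {
  mode <- match.arg(mode)
  validate_hits(hits)
  cutoff <- if (mode == "proteome") thresholds$max_evalue_proteome
            else thresholds$max_evalue_genome
  keep <- hits$evalue < cutoff & hits$align_len >= thresholds$min_alen
  passing <- hits[keep, , drop = FALSE]
  list(hits = passing,
       query_ids = sort(unique(passing$query_id)),
       subject_ids = sort(unique(passing$subject_id)))
}

# Best reverse hit per query: minimum evalue, ties broken by maximum
# bitscore, then lexicographically smallest subject_id.
best_hits_by_query <- function(hits) {
  ord <- order(hits$query_id, hits$evalue, -hits$bitscore, hits$subject_id)
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Confirm candidates by reciprocal search
#'
#' A candidate is confirmed iff the best hit of its reciprocal search (the
#' candidate queried back against reference gene models) belongs to the
#' curated set of known family members.  Candidates whose reciprocal best
#' hit lands elsewhere — e.g. on a non-olfactory GPCR — are rejected, as are
#' candidates with no passing reverse hit at all.
#'
#' @param candidate_ids character vector of candidate ids.
#' @param reverse_hits hit table of the reciprocal search, already filtered
#'   to passing hits (queries are candidates).
#' @param known_family_ids character vector of reference ids belonging to
#'   the target family.
#' @return data.frame with `gene_id`, `best_subject`, `confirmed`.
#' @export
reciprocal_confirm <- function(candidate_ids, reverse_hits, known_family_ids) {
  if (length(known_family_ids) == 0)
    stop("known_family_ids must be non-empty")
  validate_hits(reverse_hits)
  best <- best_hits_by_query(reverse_hits)
  best <- best[best$query_id %in% candidate_ids, , drop = FALSE]
  res <- data.frame(gene_id = candidate_ids, stringsAsFactors = FALSE)
  idx <- match(res$gene_id, best$query_id)
  res$best_subject <- best$subject_id[idx]
  res$confirmed <- !is.na(idx) & res$best_subject %in% known_family_ids
  res
}

# Total length of the union of 1-based inclusive AA intervals.
interval_union_length <- function(starts, ends) {
  if (length(starts) == 0) return(0L)
  ord <- order(starts, ends)
  s <- starts[ord]; e <- ends[ord]
  total <- 0L; cur_s <- s[1]; cur_e <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] <= cur_e + 1L) {
      cur_e <- max(cur_e, e[i])
    } else {
      total <- total + (cur_e - cur_s + 1L)
      cur_s <- s[i]; cur_e <- e[i]
    }
  }
  total + (cur_e - cur_s + 1L)
}

#' Apply the family-specific domain filter
#'
#' OR and V1R candidates are retained iff they carry any seven-transmembrane
#' (7tm-class) domain annotation.  V2R candidates are retained iff the union
#' of their TM7_3 envelopes covers at least `min_domain_coverage_v2r` amino
#' acids (default 200).
#'
#' @param candidate_ids character vector of candidate ids.
#' @param domains domain annotation table (see [read_domain_tab()]).
#' @param family one of `"OR"`, `"V1R"`, `"V2R"`.
#' @param thresholds a [screen_thresholds()] object.
#' @return character vector of retained candidate ids (input order).
#' @export
apply_domain_filter <- function(candidate_ids, domains,
                                family = c("OR", "V1R", "V2R"),
                                thresholds = screen_thresholds()) {
  family <- match.arg(family)
  is_7tm <- grepl("^(7tm|TM7)", domains$domain_name, ignore.case = TRUE)
  if (family %in% c("OR", "V1R")) {
    keep_ids <- unique(domains$seq_id[is_7tm])
    return(candidate_ids[candidate_ids %in% keep_ids])
  }
  tm73 <- domains[domains$domain_name == "TM7_3", , drop = FALSE]
  cov <- vapply(candidate_ids, function(id) {
    d <- tm73[tm73$seq_id == id, , drop = FALSE]
    as.numeric(interval_union_length(d$env_start, d$env_end))
  }, numeric(1))
  candidate_ids[cov >= thresholds$min_domain_coverage_v2r]
}

#' Join split genome hits into merged loci
#'
#' Translated genome searches fragment a multi-exon gene into several hits.
#' Hits on the same scaffold and strand whose inter-hit gap (nearest end to
#' nearest end) is strictly below `max_join_gap` are merged transitively
#' into one locus; each locus is then extended by `flank` bp on both sides,
#' clipped at 0 and at the scaffold length when known.
#'
#' @param genome_hits hit table with genomic subject coordinates.
#' @param thresholds a [screen_thresholds()] object.
#' @param scaffold_lengths optional named vector of scaffold lengths for
#'   upper clipping.
#' @return data.frame of loci: `locus_id`, `scaffold`, `start`, `end`
#'   (0-based half-open, flank applied), `strand`, `n_hits`, `member_hits`
#'   (comma-separated row indices of the input).
#' @export
join_split_loci <- function(genome_hits, thresholds = screen_thresholds(),
                            scaffold_lengths = NULL) {
  h <- genome_hits
  if (any(is.na(h$subject_scaffold) | h$subject_scaffold == "" |
          !(h$subject_strand %in% c("+", "-"))))
    stop("genome hits must carry scaffold and strand")
  h$.row <- seq_len(nrow(h))
  loci <- list()
  for (key in unique(paste(h$subject_scaffold, h$subject_strand))) {
    grp <- h[paste(h$subject_scaffold, h$subject_strand) == key, , drop = FALSE]
    grp <- grp[order(grp$subject_start, grp$subject_end), , drop = FALSE]
    cur <- grp[1, , drop = FALSE]
    cur_start <- cur$subject_start; cur_end <- cur$subject_end
    members <- cur$.row
    flush <- function(start, end, rows, scaffold, strand) {
      loci[[length(loci) + 1]] <<- data.frame(
        scaffold = scaffold, start = start, end = end, strand = strand,
        n_hits = length(rows), member_hits = paste(rows, collapse = ","),
        stringsAsFactors = FALSE)
    }
    if (nrow(grp) > 1) {
      for (i in 2:nrow(grp)) {
        gap <- grp$subject_start[i] - cur_end  # half-open: gap in bp between hits
        if (gap < thresholds$max_join_gap) {
          cur_end <- max(cur_end, grp$subject_end[i])
          members <- c(members, grp$.row[i])
        } else {
          flush(cur_start, cur_end, members,
                grp$subject_scaffold[1], grp$subject_strand[1])
          cur_start <- grp$subject_start[i]; cur_end <- grp$subject_end[i]
          members <- grp$.row[i]
        }
      }
    }
    flush(cur_start, cur_end, members,
          grp$subject_scaffold[1], grp$subject_strand[1])
  }
  out <- do.call(rbind, loci)
  out$start <- pmax(0L, out$start - thresholds$flank)
  out$end <- out$end + thresholds$flank
  if (!is.null(scaffold_lengths)) {
    len <- scaffold_lengths[out$scaffold]
    out$end <- ifelse(is.na(len), out$end, pmin(out$end, len))
  }
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  out$locus_id <- sprintf("locus_%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("locus_id", "scaffold", "start", "end", "strand",
          "n_hits", "member_hits")]
}

#' Reconcile gene-model and genome-predicted candidates
#'
#' A genome-predicted candidate is matched to a gene-model candidate iff
#' their genomic intervals overlap by at least 1 bp on the same strand; when
#' the gene-model entry lacks coordinates, a precomputed peptide identity of
#' at least 99 percent over the shorter sequence substitutes.  Matched pairs
#' collapse to one gene keeping the gene-model id; unmatched entries are
#' kept and flagged.
#'
#' @param model_set gene-model candidates (data.frame, internal coordinates;
#'   `scaffold` may be `NA` for entries without placement).
#' @param genome_set genome-predicted candidates (data.frame).
#' @param peptide_identity optional data.frame `model_id`, `genome_id`,
#'   `identity` used for coordinate-free matching.
#' @return the unified candidate table with a `flag` column in
#'   `matched | model_only | genome_only`, plus attribute `counts`.
#' @export
reconcile_candidates <- function(model_set, genome_set,
                                 peptide_identity = NULL) {
  ids <- c(model_set$gene_id, genome_set$gene_id)
  if (anyDuplicated(ids))
    stop("duplicate gene_ids across model and genome sets: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  matched_model <- character(0)
  matched_genome <- character(0)
  for (i in seq_len(nrow(genome_set))) {
    g <- genome_set[i, ]
    hit <- NA_character_
    has_coord <- !is.na(model_set$scaffold) & model_set$scaffold != ""
    ov <- which(has_coord &
                model_set$scaffold == g$scaffold &
                model_set$strand == g$strand &
                model_set$start < g$end & g$start < model_set$end &
                !(model_set$gene_id %in% matched_model))
    if (length(ov)) {
      hit <- model_set$gene_id[ov[1]]
    } else if (!is.null(peptide_identity)) {
      pid <- peptide_identity[peptide_identity$genome_id == g$gene_id &
                              peptide_identity$identity >= 99 &
                              !(peptide_identity$model_id %in% matched_model), ,
                              drop = FALSE]
      if (nrow(pid)) hit <- pid$model_id[which.max(pid$identity)]
    }
    if (!is.na(hit)) {
      matched_model <- c(matched_model, hit)
      matched_genome <- c(matched_genome, g$gene_id)
    }
  }
  model_out <- model_set
  model_out$flag <- ifelse(model_out$gene_id %in% matched_model,
                           "matched", "model_only")
  genome_out <- genome_set[!(genome_set$gene_id %in% matched_genome), ,
                           drop = FALSE]
  if (nrow(genome_out)) genome_out$flag <- "genome_only"
  common <- intersect(names(model_out), names(genome_out))
  out <- rbind(model_out[, common, drop = FALSE],
               genome_out[, common, drop = FALSE])
  rownames(out) <- NULL
  attr(out, "counts") <- c(matched = length(matched_model),
                           model_only = sum(model_out$flag == "model_only"),
                           genome_only = nrow(genome_out))
  out
}

#' Run the full screening stage for one family
#'
#' Chains forward filtering, reciprocal confirmation and the domain filter
#' over gene-model candidates, and reconciles them with genome-predicted
#' candidates when supplied.
#'
#' @param forward_hits forward search hit table (subjects are candidates).
#' @param reverse_hits reciprocal search hit table (queries are candidates).
#' @param domains domain annotation table.
#' @param known_family_ids curated reference ids of the family.
#' @param family family label.
#' @param thresholds a [screen_thresholds()] object.
#' @param gene_coords optional gene coordinate table used to attach
#'   coordinates to survivors.
#' @return character vector of screened candidate ids, with an `attrition`
#'   attribute recording counts after each filter.
#' @export
screen_family <- function(forward_hits, reverse_hits, domains,
                          known_family_ids, family = "OR",
                          thresholds = screen_thresholds(),
                          gene_coords = NULL) {
  fwd <- filter_forward_hits(forward_hits, thresholds, mode = "proteome")
  cands <- fwd$subject_ids
  rev_pass <- filter_forward_hits(reverse_hits, thresholds,
                                  mode = "proteome")$hits
  conf <- reciprocal_confirm(cands, rev_pass, known_family_ids)
  confirmed <- conf$gene_id[conf$confirmed]
  survivors <- apply_domain_filter(confirmed, domains, family, thresholds)
  attr(survivors, "attrition") <- c(forward = length(cands),
                                    reciprocal = length(confirmed),
                                    domain = length(survivors))
  survivors
}
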