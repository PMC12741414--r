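#' Filter assembly-liftover matches
#'
#' Scaffold regions lifted between assembly versions are accepted only with
#' E-value strictly below 1e-100 and percent identity strictly above 99.
#' When one source interval has several accepted targets, the best (lowest
#' E-value, then highest identity) is kept and the match is flagged
#' ambiguous.
#'
#' @param matches data.frame with `source_id`, `target_id`, `evalue`,
#'   `percent_identity` (additional interval columns are preserved).
#' @param max_evalue strict E-value cutoff.
#' @param min_identity strict identity cutoff (percent).
#' @return accepted matches, one per source, with logical column `ambiguous`.
#' @export
filter_liftover <- function(matches, max_evalue = 1e-100, min_identity = 99) {
  if (any(matches$percent_identity < 0 | matches$percent_identity > 100))
    stop("percent identity must lie in [0, 100]")
  ok <- matches$evalue < max_evalue & matches$percent_identity > min_identity
  acc <- matches[ok, , drop = FALSE]
  if (nrow(acc) == 0) {
    acc$ambiguous <- logical(0)
    return(acc)
  }
  ord <- order(acc$source_id, acc$evalue, -acc$percent_identity)
  acc <- acc[ord, , drop = FALSE]
  dup <- duplicated(acc$source_id)
  ambiguous_sources <- unique(acc$source_id[dup])
  best <- acc[!dup, , drop = FALSE]
  best$ambiguous <- best$source_id %in% ambiguous_sources
  rownames(best) <- NULL
  best
}

#' Compare microsynteny of two landmark-anchored regions
#'
#' Given the ordered flanking genes around a landmark (e.g. Plch1 or
#' Mme/Nep) in two species and a homology map between them, reports how
#' many region-A genes have a homolog in region B, whether the shared genes
#' appear in a conserved order (monotone in either direction, so a whole-
#' block inversion still counts as conserved), and a presence/absence table.
#'
#' @param region_a,region_b data.frames with `gene_id` ordered by
#'   coordinate (one row per flanking gene; the anchor may be included).
#' @param homology_map data.frame `gene_a`, `gene_b` relating genes across
#'   the regions.
#' @return list with `shared` (count), `order_conserved` (logical, `NA`
#'   when fewer than 2 shared genes), and `table` (each A-gene with its
#'   B-partner or `NA`).
#' @export
compare_microsynteny <- function(region_a, region_b, homology_map) {
  if (nrow(region_a) == 0 || nrow(region_b) == 0)
    stop("synteny regions must be non-empty")
  partner <- homology_map$gene_b[match(region_a$gene_id, homology_map$gene_a)]
  partner[!(partner %in% region_b$gene_id)] <- NA
  tab <- data.frame(gene_a = region_a$gene_id, gene_b = partner,
                    stringsAsFactors = FALSE)
  shared <- sum(!is.na(partner))
  order_conserved <- NA
  if (shared >= 2) {
    pos_b <- match(partner[!is.na(partner)], region_b$gene_id)
    d <- diff(pos_b)
    order_conserved <- all(d > 0) || all(d < 0)
  }
  list(shared = shared, order_conserved = order_conserved, table = tab)
}

#' Check distances between landmark genes and family genes
#'
#' For each landmark gene, reports the family genes sharing its scaffold,
#' the nearest midpoint distance, and whether the landmark is "far" from
#' the family: no family gene on the same scaffold within `far_threshold`
#' bp (strictly more than the threshold counts as distant).
#'
#' @param landmark_genes gene table of landmarks.
#' @param family_genes gene table of the receptor family.
#' @param far_threshold distance in bp beyond which a family gene counts as
#'   distant (default 50 Mbp).
#' @return data.frame `landmark`, `scaffold`, `n_co_scaffold`,
#'   `nearest_bp` (`NA` when none share the scaffold), `is_far`.
#' @export
landmark_distance_check <- function(landmark_genes, family_genes,
                                    far_threshold = 50000000) {
  rows <- lapply(seq_len(nrow(landmark_genes)), function(i) {
    lm <- landmark_genes[i, ]
    co <- family_genes[family_genes$scaffold == lm$scaffold, , drop = FALSE]
    nearest <- NA_real_
    if (nrow(co)) {
      mid_lm <- (lm$start + lm$end) / 2
      mid_f <- (co$start + co$end) / 2
      nearest <- round(min(abs(mid_f - mid_lm)))
    }
    data.frame(landmark = lm$gene_id, scaffold = lm$scaffold,
               n_co_scaffold = nrow(co), nearest_bp = nearest,
               is_far = is.na(nearest) || nearest > far_threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
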