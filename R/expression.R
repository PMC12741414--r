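#' Log-transform a TPM matrix
#'
#' Each cell becomes `log10(TPM + pseudocount)`; the default pseudocount of
#' 0.001 maps an unexpressed gene (TPM 0) to -3.
#'
#' @param mat genes x organs TPM matrix (non-negative).
#' @param pseudocount added before taking log10.
#' @return transformed matrix of the same shape.
#' @export
log_transform <- function(mat, pseudocount = 0.001) {
  if (any(mat < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  log10(mat + pseudocount)
}

#' Classify organ specificity of expression
#'
#' A gene is called expressed in the focal organ iff its focal TPM strictly
#' exceeds `expressed_threshold` (default 1 TPM), and highest-in-focal iff
#' its focal TPM strictly exceeds every other organ's TPM (an exact tie,
#' as for a receptor expressed equally in the olfactory organ and brain,
#' does not count as highest).
#'
#' @param mat genes x organs TPM matrix with organ names as colnames.
#' @param focal_organ name of the focal organ column.
#' @param expressed_threshold TPM cutoff (strict `>`).
#' @return list with `calls` (data.frame `gene_id`, `focal_tpm`,
#'   `max_other_tpm`, `expressed_in_focal`, `highest_in_focal`) and
#'   `summary` (`n_expressed`, `n_highest`, `n_total`).
#' @export
classify_specificity <- function(mat, focal_organ = "olfactory_organ",
                                 expressed_threshold = 1) {
  if (!(focal_organ %in% colnames(mat)))
    stop("unknown organ: ", focal_organ)
  focal <- mat[, focal_organ]
  other <- mat[, setdiff(colnames(mat), focal_organ), drop = FALSE]
  max_other <- apply(other, 1, max)
  calls <- data.frame(
    gene_id = rownames(mat),
    focal_tpm = unname(focal),
    max_other_tpm = unname(max_other),
    expressed_in_focal = unname(focal > expressed_threshold),
    highest_in_focal = unname(focal > max_other),
    stringsAsFactors = FALSE
  )
  list(calls = calls,
       summary = c(n_expressed = sum(calls$expressed_in_focal),
                   n_highest = sum(calls$highest_in_focal),
                   n_total = nrow(calls)))
}
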