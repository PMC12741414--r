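#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Parses the standard 12-column BLAST tabular layout
#' (qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore) into a hit table.  Subject coordinates are normalized so
#' that `subject_start <= subject_end`; the subject strand is inferred from
#' the original coordinate orientation (minus when sstart > send), which is
#' how TBLASTN reports hits on the reverse strand.  Coordinates are converted
#' from BLAST's 1-based inclusive convention to the package-internal 0-based
#' half-open convention.
#'
#' @param path path to a tab-separated hit file without header.
#' @param subject_is_genomic logical; when `TRUE` the subject id is treated
#'   as a scaffold and genomic coordinates/strand are retained.
#' @return a data.frame of hit records with columns `query_id`, `subject_id`,
#'   `percent_identity`, `align_len`, `evalue`, `bitscore`,
#'   `subject_scaffold`, `subject_start`, `subject_end`, `subject_strand`.
#' @export
read_blast_tab <- function(path, subject_is_genomic = FALSE) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  x <- read.delim(path, header = FALSE, col.names = cols,
                  stringsAsFactors = FALSE, comment.char = "#")
  strand <- ifelse(x$sstart <= x$send, "+", "-")
  lo <- pmin(x$sstart, x$send)
  hi <- pmax(x$sstart, x$send)
  hits <- data.frame(
    query_id = as.character(x$qseqid),
    subject_id = as.character(x$sseqid),
    percent_identity = as.numeric(x$pident),
    align_len = as.integer(x$length),
    evalue = as.numeric(x$evalue),
    bitscore = as.numeric(x$bitscore),
    subject_scaffold = if (subject_is_genomic) as.character(x$sseqid) else "",
    subject_start = if (subject_is_genomic) as.integer(lo - 1L) else NA_integer_,
    subject_end = if (subject_is_genomic) as.integer(hi) else NA_integer_,
    subject_strand = if (subject_is_genomic) strand else "n/a",
    stringsAsFactors = FALSE
  )
  validate_hits(hits)
  hits
}

validate_hits <- function(hits) {
  stopifnot(is.data.frame(hits))
  need <- c("query_id", "subject_id", "evalue", "align_len")
  missing <- setdiff(need, names(hits))
  if (length(missing))
    stop("hit table lacks columns: ", paste(missing, collapse = ", "))
  if (any(hits$evalue < 0, na.rm = TRUE))
    stop("invalid hit record: negative evalue")
  if (any(hits$align_len < 1, na.rm = TRUE))
    stop("invalid hit record: alignment length < 1")
  invisible(hits)
}

#' Read a domain-hit table
#'
#' Simplified domtblout-style TSV with columns
#' `seq_id`, `domain_name`, `env_start`, `env_end`, `score`
#' (envelope coordinates in amino acids, 1-based inclusive).
#'
#' @param path path to the TSV (header required).
#' @return data.frame of domain annotations.
#' @export
read_domain_tab <- function(path) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("seq_id", "domain_name", "env_start", "env_end", "score")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("domain table lacks columns: ", paste(missing, collapse = ", "))
  if (any(d$env_start > d$env_end))
    stop("invalid domain annotation: env_start > env_end")
  d
}

#' Read a gene coordinate table
#'
#' TSV with header and columns `gene_id`, `family`, `source`, `scaffold`,
#' `start`, `end`, `strand` (coordinates 1-based inclusive on file, converted
#' to 0-based half-open internally).  Extra columns are preserved.
#'
#' @param path path to the TSV.
#' @return data.frame of candidate genes with internal coordinates.
#' @export
read_gene_table <- function(path) {
  g <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("gene_id", "scaffold", "start", "end", "strand")
  missing <- setdiff(need, names(g))
  if (length(missing))
    stop("gene table lacks columns: ", paste(missing, collapse = ", "))
  g$start <- as.integer(g$start) - 1L
  g$end <- as.integer(g$end)
  validate_genes(g)
  g
}

validate_genes <- function(genes) {
  if (any(genes$start >= genes$end))
    stop("invalid gene interval: start >= end")
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in gene set: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  invisible(genes)
}

#' Write a candidate gene table
#'
#' Writes the unified candidate table with 1-based inclusive coordinates
#' (the file convention for plain TSV interchange).
#'
#' @param genes candidate data.frame (internal 0-based half-open coordinates).
#' @param path output path.
#' @export
write_candidate_table <- function(genes, path) {
  out <- genes
  out$start <- out$start + 1L
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write merged loci as BED
#'
#' BED is 0-based half-open, matching the internal convention directly.
#'
#' @param loci data.frame with `scaffold`, `start`, `end`, `locus_id`, `strand`.
#' @param path output path.
#' @export
write_locus_bed <- function(loci, path) {
  bed <- data.frame(chrom = loci$scaffold, chromStart = loci$start,
                    chromEnd = loci$end, name = loci$locus_id,
                    score = 0L, strand = loci$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a scaffold-lengths table
#'
#' Two-column TSV `scaffold`, `length` (header required).
#'
#' @param path path to the TSV.
#' @return named integer vector of scaffold lengths.
#' @export
read_scaffold_lengths <- function(path) {
  s <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  setNames(as.numeric(s$length), s$scaffold)
}

#' Read a TPM expression matrix
#'
#' Rows are genes (first column `gene_id`), remaining columns are organs.
#'
#' @param path path to the TSV (header required).
#' @return numeric matrix, genes x organs, with gene ids as rownames.
#' @export
read_tpm_matrix <- function(path) {
  m <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE)
  ids <- as.character(m[[1]])
  mat <- as.matrix(m[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  validate_tpm(mat)
  mat
}

validate_tpm <- function(mat) {
  if (any(mat < 0, na.rm = TRUE)) stop("TPM values must be non-negative")
  if (anyDuplicated(colnames(mat))) stop("organ names must be unique")
  invisible(mat)
}

#' Write a TPM matrix
#' @param mat genes x organs matrix with rownames.
#' @param path output path.
#' @export
write_tpm_matrix <- function(mat, path) {
  out <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
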