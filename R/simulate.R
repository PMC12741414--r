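#' Simulator configuration
#'
#' Parameters of the gene-family expansion simulator.  The defaults emulate
#' the study conditions of a chemosensory receptor survey: a family grown
#' from a few founders to ~50 genes, overwhelmingly by tandem duplication
#' (copies landing 5-50 kb from the parent), with occasional dispersal to
#' other scaffolds, strong bootstrap support on true founder clades, and
#' focal-organ-biased log-normal TPM expression.
#'
#' @param n_founders number of founder genes, each on its own scaffold.
#' @param n_events number of duplication events.
#' @param p_tandem probability that a copy is tandem (same scaffold, within
#'   `tandem_offset_range` of the parent) rather than dispersed.
#' @param tandem_offset_range bp interval for the gap between parent and
#'   tandem copy.
#' @param n_scaffolds number of scaffolds in the synthetic genome.
#' @param scaffold_len length of each scaffold in bp.
#' @param gene_len length of each gene in bp.
#' @param branch_rate mean waiting time between duplications (branch-length
#'   scale, substitutions/site).
#' @param support_hi integer range (length 2) of bootstrap supports drawn
#'   for true-clade roots.
#' @param support_lo integer range for all other internal nodes.
#' @param expr_mu_hi,expr_mu_lo,expr_sigma log-normal meanlog for the focal
#'   organ / other organs, and common sdlog, of simulated TPM values.
#' @param n_decoys number of decoy (non-family) sequences with failing hits.
#' @param family family label attached to simulated genes.
#' @param seed integer seed driving the single global random stream.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 3L,
                       n_events = 45L,
                       p_tandem = 0.9,
                       tandem_offset_range = c(5000L, 50000L),
                       n_scaffolds = 20L,
                       scaffold_len = 100000000,
                       gene_len = 1000L,
                       branch_rate = 0.05,
                       support_hi = c(90L, 100L),
                       support_lo = c(20L, 70L),
                       expr_mu_hi = log(50),
                       expr_mu_lo = log(0.05),
                       expr_sigma = 1,
                       n_decoys = 20L,
                       family = "V2R",
                       seed = 1L) {
  stopifnot(p_tandem >= 0, p_tandem <= 1,
            tandem_offset_range[1] <= tandem_offset_range[2],
            n_founders >= 1, n_founders <= n_scaffolds,
            support_hi[1] <= support_hi[2], support_lo[1] <= support_lo[2])
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# organs assayed in the reference survey design
sim_organs <- function() {
  c("olfactory_organ", "brain", "pituitary_gland", "gill", "intestine",
    "kidney", "liver", "testis", "ovary")
}

# nearest free interval of length len on a scaffold, gap to the parent
# within [off_min, off_max]; downstream of the parent scanned first.
.find_tandem_slot <- function(parent_start, parent_end, occupied, len,
                              off_min, off_max, scaffold_len) {
  occ <- occupied[order(occupied$start), , drop = FALSE]
  overlaps <- function(s) {
    any(occ$start < s + len & s < occ$end)
  }
  # downstream: smallest start >= parent_end + off_min
  s <- parent_end + off_min
  repeat {
    if (s + len > scaffold_len || s > parent_end + off_max) break
    hit <- which(occ$start < s + len & s < occ$end)
    if (!length(hit)) return(s)
    s <- max(occ$end[hit])
  }
  # upstream: largest end <= parent_start - off_min (scan toward smaller)
  e <- parent_start - off_min
  repeat {
    s <- e - len
    if (s < 0 || e < parent_start - off_max) break
    hit <- which(occ$start < e & s < occ$end)
    if (!length(hit)) return(s)
    e <- min(occ$start[hit])
  }
  NA_real_
}

#' Simulate a gene-family repertoire with ground truth
#'
#' Grows a gene family from `n_founders` founders (each on a distinct
#' scaffold) by `n_events` duplications: with probability `p_tandem` the
#' copy lands on the parent's scaffold at the nearest free position within
#' `tandem_offset_range`, otherwise it is dispersed to a uniformly chosen
#' scaffold and position.  Each duplication is recorded as a bifurcation in
#' the true gene tree with waiting times drawn from an exponential
#' distribution; founder-subtree roots with at least five leaves carry high
#' supports, all other nodes low supports (supports encode the truth, not a
#' bootstrap — the simulator validates clade-extraction logic, not tree
#' inference).  Family members receive passing homology hits and TM7_3
#' domain coverage of at least 200 AA; decoys receive failing hits, best
#' reciprocal hits outside the family, and absent or short domains.  Focal
#' organ TPM is log-normal with `expr_mu_hi`, other organs `expr_mu_lo`.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_truth`: list with `config`, `tree`
#'   (`ape::phylo` with supports), `genes` (coordinates, 0-based
#'   half-open), `truth` (gene -> founder lineage), `forward_hits`,
#'   `reverse_hits`, `genome_hits`, `domains`, `expr` (TPM matrix),
#'   `family_refs`, `decoy_ids`, `scaffold_lengths`.
#' @export
simulate_repertoire <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$gene_len
  scaffolds <- sprintf("scaf%02d", seq_len(config$n_scaffolds))
  n_total <- config$n_founders + config$n_events
  ids <- sprintf("g%03d", seq_len(n_total))

  genes <- data.frame(
    gene_id = ids[seq_len(config$n_founders)],
    founder = seq_len(config$n_founders),
    scaffold = scaffolds[seq_len(config$n_founders)],
    start = NA_real_, end = NA_real_,
    strand = "+", stringsAsFactors = FALSE)
  for (i in seq_len(config$n_founders)) {
    s <- floor(runif(1, 0, config$scaffold_len - L))
    genes$start[i] <- s; genes$end[i] <- s + L
  }

  # duplication history
  times <- cumsum(rexp(config$n_events, rate = 1 / config$branch_rate))
  events <- data.frame(time = times,
                       parent = NA_character_, child = NA_character_,
                       stringsAsFactors = FALSE)
  for (k in seq_len(config$n_events)) {
    parent_row <- sample.int(nrow(genes), 1)
    child_id <- ids[config$n_founders + k]
    p <- genes[parent_row, ]
    tandem <- runif(1) < config$p_tandem
    if (tandem) {
      occ <- genes[genes$scaffold == p$scaffold, c("start", "end")]
      s <- .find_tandem_slot(p$start, p$end, occ, L,
                             config$tandem_offset_range[1],
                             config$tandem_offset_range[2],
                             config$scaffold_len)
      if (is.na(s))
        stop("infeasible tandem placement on ", p$scaffold,
             "; increase scaffold_len or tandem_offset_range")
      scaf <- p$scaffold
    } else {
      scaf <- sample(scaffolds, 1)
      placed <- FALSE
      for (try in 1:1000) {
        s <- floor(runif(1, 0, config$scaffold_len - L))
        occ <- genes[genes$scaffold == scaf, , drop = FALSE]
        if (!any(occ$start < s + L & s < occ$end)) { placed <- TRUE; break }
      }
      if (!placed)
        stop("infeasible dispersed placement; increase scaffold_len")
    }
    genes <- rbind(genes, data.frame(
      gene_id = child_id, founder = p$founder, scaffold = scaf,
      start = s, end = s + L, strand = p$strand,
      stringsAsFactors = FALSE))
    events$parent[k] <- p$gene_id
    events$child[k] <- child_id
  }
  t_end <- if (config$n_events > 0) max(times) + config$branch_rate
           else config$branch_rate

  draw_support <- function(range) sample(range[1]:range[2], 1)
  fmt <- function(x) sprintf("%.8g", max(x, 1e-9))
  # recursive newick builder over the duplication history
  nwk <- function(g, t0) {
    ev <- events[events$parent == g & events$time > t0, , drop = FALSE]
    if (nrow(ev) == 0) return(paste0(g, ":", fmt(t_end - t0)))
    ev <- ev[order(ev$time), , drop = FALSE]
    t1 <- ev$time[1]
    paste0("(", nwk(g, t1), ",", nwk(ev$child[1], t1), ")",
           draw_support(config$support_lo), ":", fmt(t1 - t0))
  }
  n_per_founder <- table(genes$founder)
  subtrees <- character(config$n_founders)
  for (f in seq_len(config$n_founders)) {
    sub <- nwk(ids[f], 0)
    # founder-subtree root carries a truth-encoding high support
    if (n_per_founder[as.character(f)] >= 5 && startsWith(sub, "(")) {
      sub <- sub(")[0-9]+:([0-9.eE+-]+)$",
                 paste0(")", draw_support(config$support_hi), ":\\1"), sub)
    }
    subtrees[f] <- sub
  }
  if (config$n_founders == 1) {
    newick <- paste0(sub(":[0-9.eE+-]+$", "", subtrees[1]), ";")
  } else {
    s <- subtrees[1]
    for (f in 2:config$n_founders) {
      lab <- if (f == config$n_founders) "" else draw_support(config$support_lo)
      s <- paste0("(", s, ",", subtrees[f], ")", lab,
                  if (f < config$n_founders) paste0(":", fmt(rexp(1, 1 / config$branch_rate))))
    }
    newick <- paste0(s, ";")
  }
  tree <- ape::read.tree(text = newick)

  # hit, domain and expression tables ------------------------------------
  decoy_ids <- if (config$n_decoys > 0)
    sprintf("decoy%02d", seq_len(config$n_decoys)) else character(0)
  fam_ref <- sprintf("REF_%s_%d", config$family, 1:3)
  off_ref <- c("HTR4_HOMOLOG", "GABBR_HOMOLOG")
  q_ref <- sprintf("QUERY_%s_%d", config$family, 1:2)

  mk_hit <- function(q, s, ev, alen, scaf = "", sstart = NA, send = NA,
                     strand = "n/a") {
    data.frame(query_id = q, subject_id = s,
               percent_identity = round(runif(1, 40, 90), 1),
               align_len = as.integer(alen), evalue = ev,
               bitscore = round(alen * runif(1, 1.5, 2.1), 1),
               subject_scaffold = scaf, subject_start = sstart,
               subject_end = send, subject_strand = strand,
               stringsAsFactors = FALSE)
  }
  fwd <- list(); rev <- list(); ghits <- list(); doms <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    fwd[[length(fwd) + 1]] <- mk_hit(sample(q_ref, 1), g$gene_id,
                                     10^-runif(1, 55, 150),
                                     sample(300:600, 1))
    rev[[length(rev) + 1]] <- mk_hit(g$gene_id, sample(fam_ref, 1),
                                     10^-runif(1, 60, 120),
                                     sample(300:500, 1))
    rev[[length(rev) + 1]] <- mk_hit(g$gene_id, sample(off_ref, 1),
                                     10^-runif(1, 10, 30),
                                     sample(250:300, 1))
    # translated genome search fragments the gene into 1-3 hits
    k <- sample(1:3, 1)
    cuts <- sort(unique(c(g$start, g$end,
                          if (k > 1)
                            floor(runif(k - 1, g$start + 50, g$end - 50)))))
    k <- length(cuts) - 1
    for (j in seq_len(k)) {
      ghits[[length(ghits) + 1]] <- mk_hit(
        sample(q_ref, 1), g$scaffold, 10^-runif(1, 20, 80),
        sample(300:450, 1), scaf = g$scaffold,
        sstart = cuts[j], send = cuts[j + 1], strand = g$strand)
    }
    doms[[length(doms) + 1]] <- data.frame(
      seq_id = g$gene_id, domain_name = "TM7_3",
      env_start = 21L, env_end = 21L + sample(200:320, 1),
      score = round(runif(1, 150, 400), 1), stringsAsFactors = FALSE)
  }
  for (d in decoy_ids) {
    if (runif(1) < 0.5) {
      fwd[[length(fwd) + 1]] <- mk_hit(sample(q_ref, 1), d,
                                       10^runif(1, -2, 0),
                                       sample(300:500, 1))
    } else {
      fwd[[length(fwd) + 1]] <- mk_hit(sample(q_ref, 1), d,
                                       10^-runif(1, 20, 60),
                                       sample(50:150, 1))
    }
    rev[[length(rev) + 1]] <- mk_hit(d, sample(off_ref, 1),
                                     10^-runif(1, 60, 120),
                                     sample(300:500, 1))
    rev[[length(rev) + 1]] <- mk_hit(d, sample(fam_ref, 1),
                                     10^-runif(1, 5, 20),
                                     sample(250:300, 1))
    if (runif(1) < 0.5)
      doms[[length(doms) + 1]] <- data.frame(
        seq_id = d, domain_name = "TM7_3", env_start = 10L,
        env_end = 10L + sample(20:80, 1),
        score = round(runif(1, 5, 40), 1), stringsAsFactors = FALSE)
  }

  organs <- sim_organs()
  expr <- matrix(rlnorm(nrow(genes) * length(organs),
                        meanlog = config$expr_mu_lo,
                        sdlog = config$expr_sigma),
                 nrow = nrow(genes), ncol = length(organs),
                 dimnames = list(genes$gene_id, organs))
  expr[, "olfactory_organ"] <- rlnorm(nrow(genes),
                                      meanlog = config$expr_mu_hi,
                                      sdlog = config$expr_sigma)

  out <- list(
    config = config,
    tree = tree,
    genes = data.frame(gene_id = genes$gene_id, family = config$family,
                       source = "gene_model", scaffold = genes$scaffold,
                       start = genes$start, end = genes$end,
                       strand = genes$strand, stringsAsFactors = FALSE),
    truth = genes[, c("gene_id", "founder", "scaffold", "start", "end")],
    forward_hits = do.call(rbind, fwd),
    reverse_hits = do.call(rbind, rev),
    genome_hits = do.call(rbind, ghits),
    domains = do.call(rbind, doms),
    expr = expr,
    family_refs = fam_ref,
    decoy_ids = decoy_ids,
    scaffold_lengths = setNames(rep(config$scaffold_len,
                                    config$n_scaffolds), scaffolds)
  )
  class(out) <- "sim_truth"
  out
}

#' True clade labels of a simulation
#'
#' Founder lineages with at least `min_size` members are the true clades
#' (labelled by decreasing size, as in [extract_clades()]); all other
#' genes are `"Else"`.
#'
#' @param sim a `sim_truth`.
#' @param min_size minimum lineage size to count as a clade.
#' @return named character vector gene_id -> label.
#' @export
true_clades <- function(sim, min_size = 5L) {
  counts <- table(sim$truth$founder)
  big <- names(counts)[counts >= min_size]
  ord <- big[order(-counts[big], big)]
  labels <- setNames(paste0("Clade", seq_along(ord)), ord)
  lab <- labels[as.character(sim$truth$founder)]
  lab[is.na(lab)] <- "Else"
  setNames(unname(lab), sim$truth$gene_id)
}

#' Proximity summary from simulation ground truth
#'
#' Same contract as [proximity_summary()], but computed from the true clade
#' labels and true coordinates — closing the loop for parameter-recovery
#' tests.
#'
#' @param sim a `sim_truth`.
#' @param threshold_bp genomic distance cutoff (strict `<`).
#' @return see [proximity_summary()].
#' @export
measure_truth <- function(sim, threshold_bp = 10000000) {
  pairs <- build_pair_table(sim$genes, true_clades(sim), sim$tree)
  proximity_summary(pairs, threshold_bp)
}

#' Write simulator outputs in the pipeline's file formats
#'
#' Emits every format the pipeline reads: newick tree with supports, BLAST
#' tabular hit TSVs (forward, reciprocal, genome), domain TSV, gene
#' coordinate TSV, scaffold-lengths TSV, TPM matrix TSV, a dummy peptide
#' FASTA and a truth TSV.
#'
#' @param sim a `sim_truth`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_sim_truth <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_support_tree(sim$tree, p("tree.nwk"))
  blast_cols <- function(h) {
    minus <- h$subject_strand == "-"
    ss <- ifelse(is.na(h$subject_start), 1L, h$subject_start + 1L)
    se <- ifelse(is.na(h$subject_end), h$align_len, h$subject_end)
    data.frame(h$query_id, h$subject_id, h$percent_identity, h$align_len,
               0L, 0L, 1L, h$align_len,
               ifelse(minus, se, ss), ifelse(minus, ss, se),
               h$evalue, h$bitscore)
  }
  for (nm in c("forward_hits", "reverse_hits", "genome_hits"))
    write.table(blast_cols(sim[[nm]]), p(paste0(nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(sim$domains, p("domains.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_candidate_table(sim$genes, p("genes.tsv"))
  write.table(data.frame(scaffold = names(sim$scaffold_lengths),
                         length = unname(sim$scaffold_lengths)),
              p("scaffold_lengths.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_tpm_matrix(sim$expr, p("tpm.tsv"))
  fasta <- unlist(lapply(sim$genes$gene_id, function(id)
    c(paste0(">", id), strrep("M", 10))))
  writeLines(fasta, p("peptides.fa"))
  tr <- sim$truth
  tr$start <- tr$start + 1L
  write.table(tr, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(vapply(list.files(dir), identity, character(1)))
}
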