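test_that("forward filtering applies strict E-value and non-strict length rules", {
  th <- screen_thresholds()
  hits <- make_hits(
    query_id = c("q1", "q1", "q2", "q2", "q3"),
    subject_id = c("s1", "s2", "s3", "s3", "s4"),
    evalue = c(1e-4, 1e-3, 1e-2, 1e-5, 1e-20),
    align_len = c(260, 300, 400, 249, 250))
  res <- filter_forward_hits(hits, th, mode = "proteome")
  # s1 passes both rules; s2 fails the strict E-value rule at exactly 1e-3;
  # s3's two hits fail one rule each, so the sequence is excluded
  expect_setequal(res$subject_ids, c("s1", "s4"))
  # genome mode swaps in the stricter cutoff
  resg <- filter_forward_hits(hits, th, mode = "genome")
  expect_setequal(resg$subject_ids, "s4")
  # every survivor has a witnessing hit satisfying both thresholds
  expect_true(all(res$hits$evalue < th$max_evalue_proteome &
                  res$hits$align_len >= th$min_alen))
})

test_that("forward filtering is idempotent and order-independent", {
  set.seed(42)
  hits <- make_hits(
    query_id = paste0("q", 1:50),
    subject_id = sample(paste0("s", 1:20), 50, replace = TRUE),
    evalue = 10^runif(50, -20, 0),
    align_len = sample(100:500, 50, replace = TRUE))
  res1 <- filter_forward_hits(hits)
  res2 <- filter_forward_hits(res1$hits)
  expect_equal(res1$subject_ids, res2$subject_ids)
  shuf <- hits[sample(nrow(hits)), ]
  expect_equal(filter_forward_hits(shuf)$subject_ids, res1$subject_ids)
})

test_that("invalid hit records are rejected", {
  bad <- make_hits("q", "s", evalue = -1, align_len = 100)
  expect_error(filter_forward_hits(bad), "negative evalue")
  bad2 <- make_hits("q", "s", evalue = 1e-5, align_len = 0)
  expect_error(filter_forward_hits(bad2), "alignment length")
})

test_that("reciprocal confirmation keys on the best reverse hit", {
  known <- c("OR_ref1", "OR_ref2")
  rev <- rbind(
    make_hits("c1", "OR_ref1", 1e-50, 300, bitscore = 400),
    make_hits("c1", "HTR4_h", 1e-20, 300, bitscore = 200),
    make_hits("c2", "HTR4_h", 1e-60, 300, bitscore = 500),
    make_hits("c2", "OR_ref1", 1e-40, 300, bitscore = 300),
    # equal E-values: bitscore 310 beats 290, and only that subject is known
    make_hits("c3", "OR_ref2", 1e-30, 300, bitscore = 310),
    make_hits("c3", "HTR4_h", 1e-30, 300, bitscore = 290))
  res <- reciprocal_confirm(c("c1", "c2", "c3", "c4"), rev, known)
  expect_equal(res$confirmed, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(res$best_subject[1:3], c("OR_ref1", "HTR4_h", "OR_ref2"))
  expect_error(reciprocal_confirm("c1", rev, character(0)), "non-empty")
})

test_that("domain filter uses any-7tm for OR/V1R and union coverage for V2R", {
  doms <- data.frame(
    seq_id = c("a", "b", "b", "c", "d"),
    domain_name = c("TM7_3", "TM7_3", "TM7_3", "TM7_3", "7tm_1"),
    env_start = c(30, 1, 100, 100, 10),
    env_end = c(250, 120, 220, 250, 60),
    score = 100)
  # V2R: a covers 221, b's union of 1-120 and 100-220 covers 220, c only 151
  expect_equal(apply_domain_filter(c("a", "b", "c"), doms, "V2R"),
               c("a", "b"))
  # OR: any 7tm-class annotation suffices, even a short one
  expect_equal(apply_domain_filter(c("a", "d", "e"), doms, "OR"),
               c("a", "d"))
})

test_that("split loci join transitively on strand and gap, with flank", {
  th <- screen_thresholds()
  hits <- make_hits(
    query_id = "q", subject_id = "scafA",
    evalue = 1e-20, align_len = 300,
    scaffold = "scafA",
    sstart = c(10000, 61000, 300000, 500000),
    send =   c(11000, 62000, 301000, 501000),
    strand = c("+", "+", "+", "-"))
  loci <- join_split_loci(hits, th)
  # 50 kb gap joins, 238 kb gap splits, opposite strand always splits
  expect_equal(nrow(loci), 3)
  expect_equal(sum(loci$n_hits), nrow(hits))
  plus <- loci[loci$strand == "+", ]
  expect_equal(plus$start[1], 10000 - th$flank)
  expect_equal(plus$end[1], 62000 + th$flank)
  # output loci are pairwise non-mergeable under the same rule
  for (i in seq_len(nrow(loci)))
    for (j in seq_len(nrow(loci)))
      if (i < j && loci$scaffold[i] == loci$scaffold[j] &&
          loci$strand[i] == loci$strand[j]) {
        gap <- max(loci$start[j], loci$start[i]) -
          min(loci$end[i], loci$end[j])
        expect_gte(gap + 2 * th$flank, th$max_join_gap)
      }
  expect_error(join_split_loci(make_hits("q", "s", 1e-5, 300)),
               "scaffold and strand")
})

test_that("flank is clipped at scaffold bounds", {
  hits <- make_hits("q", "scafA", 1e-20, 300, scaffold = "scafA",
                    sstart = 100, send = 1100, strand = "+")
  loci <- join_split_loci(hits, scaffold_lengths = c(scafA = 1500))
  expect_equal(loci$start, 0)
  expect_equal(loci$end, 1500)
})

test_that("reconciliation matches by overlap and reports provenance counts", {
  model <- make_genes(paste0("m", 1:5), "scafA",
                      start = c(0, 10000, 20000, 30000, 40000),
                      end = c(1000, 11000, 21000, 31000, 41000))
  genome <- make_genes(paste0("loc", 1:4),
                       scaffold = c("scafA", "scafA", "scafA", "scafB"),
                       start = c(500, 10500, 20500, 0),
                       end = c(1500, 11500, 21500, 1000),
                       source = "genome_predicted")
  res <- reconcile_candidates(model, genome)
  expect_equal(nrow(res), 6)  # 5 model + 1 genome_only
  expect_equal(as.vector(attr(res, "counts")),
               c(3, 2, 1))
  expect_equal(sum(res$flag == "matched"), 3)
  expect_equal(res$gene_id[res$flag == "genome_only"], "loc4")
  # matched pairs keep the gene-model id
  expect_true(all(grepl("^m", res$gene_id[res$flag == "matched"])))
  expect_error(reconcile_candidates(model, model), "duplicate gene_ids")
})

test_that("reconciliation falls back to peptide identity without coordinates", {
  model <- make_genes("m1", NA_character_, 0, 1000)
  genome <- make_genes("loc1", "scafA", 100, 1100, source = "genome_predicted")
  pid <- data.frame(model_id = "m1", genome_id = "loc1", identity = 99.5)
  res <- reconcile_candidates(model, genome, peptide_identity = pid)
  expect_equal(attr(res, "counts")[["matched"]], 1)
  pid_low <- data.frame(model_id = "m1", genome_id = "loc1", identity = 98)
  res2 <- reconcile_candidates(model, genome, peptide_identity = pid_low)
  expect_equal(attr(res2, "counts")[["matched"]], 0)
})

test_that("blast tabular round-trips with strand inference and coordinates", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\tscafA\t88.5\t300\t10\t2\t1\t300\t5000\t4101\t1e-50\t400",
               "q2\tscafA\t90.0\t250\t5\t1\t1\t250\t100\t849\t1e-20\t300"),
             tmp)
  h <- read_blast_tab(tmp, subject_is_genomic = TRUE)
  expect_equal(h$subject_strand, c("-", "+"))
  expect_equal(h$subject_start, c(4100L, 99L))  # 0-based half-open
  expect_equal(h$subject_end, c(5000L, 849L))
})
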