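test_that("genomic distance is midpoint-based and undefined across scaffolds", {
  a <- make_genes("a", "s1", 0, 200)
  b <- make_genes("b", "s1", 1000, 1200)
  expect_equal(genomic_distance(a, b), 1000)
  expect_equal(genomic_distance(a, a), 0)
  c <- make_genes("c", "s2", 0, 200)
  expect_true(is.na(genomic_distance(a, c)))
})

test_that("pair table enumerates C(n,2) records with correct classes", {
  genes <- make_genes(c("g1", "g2", "g3", "g4"),
                      scaffold = c("s1", "s1", "s2", "s2"),
                      start = c(0, 5000, 0, 2000),
                      end = c(1000, 6000, 1000, 3000))
  tr <- ape::read.tree(
    text = "((g1:1,g2:1)90:1,(g3:1,(g4:1,o:1)50:1)80:1);")
  clades <- c(g1 = "Clade1", g2 = "Clade1", g3 = "Clade2", g4 = "Else")
  pairs <- build_pair_table(genes, clades, tr)
  expect_equal(nrow(pairs), choose(4, 2))
  p12 <- pairs[pairs$gene_a == "g1" & pairs$gene_b == "g2", ]
  expect_equal(p12$clade_class, "intraclade")
  expect_equal(p12$genomic_dist, 5000)
  expect_equal(p12$phylo_dist, 2)
  # undefined genomic distance iff interscaffold
  expect_equal(is.na(pairs$genomic_dist),
               pairs$scaffold_class == "interscaffold")
  # pairs involving an Else gene are interclade, as are cross-clade pairs
  expect_equal(pairs$clade_class[pairs$gene_a == "g3" & pairs$gene_b == "g4"],
               "interclade")
  expect_equal(pairs$clade_class[pairs$gene_a == "g1" & pairs$gene_b == "g3"],
               "interclade")
  expect_error(build_pair_table(make_genes("zz", "s1", 0, 10), clades, tr),
               "missing")
})

test_that("pairs of Else genes count as interclade", {
  genes <- make_genes(c("e1", "e2"), "s1", c(0, 5000), c(1000, 6000))
  tr <- ape::read.tree(text = "(e1:1,e2:1);")
  pairs <- build_pair_table(genes, c(e1 = "Else", e2 = "Else"), tr)
  expect_equal(pairs$clade_class, "interclade")
})

test_that("proximity summary counts strict sub-threshold fractions", {
  # Clade1 = {g1,g2} 1 kb apart; Else = {g3} on another scaffold
  genes <- make_genes(c("g1", "g2", "g3"),
                      scaffold = c("s1", "s1", "s2"),
                      start = c(0, 1000, 0), end = c(500, 1500, 500))
  tr <- ape::read.tree(text = "((g1:1,g2:1)90:1,g3:2);")
  clades <- c(g1 = "Clade1", g2 = "Clade1", g3 = "Else")
  pairs <- build_pair_table(genes, clades, tr)
  prox <- proximity_summary(pairs)
  expect_equal(prox$numerator, c(1, 0))
  expect_equal(prox$denominator, c(1, 2))
  expect_equal(prox$fraction, c(1, 0))
  expect_true(attr(prox, "consistency")$consistent)
  # the boundary is strict: a pair exactly at the threshold is excluded
  at <- proximity_summary(pairs, threshold_bp = 1000)
  expect_equal(at$numerator[1], 0)
  expect_error(proximity_summary(pairs[0, ]), "empty")
  # an externally reported total that does not add up is flagged
  expect_warning(proximity_summary(pairs, expected_pairs = 2),
                 "differs from computed")
})

test_that("proximity fractions are monotone in the threshold and converge
           to the intrascaffold share", {
  set.seed(11)
  sim <- simulate_repertoire(sim_config(seed = 11, n_events = 30))
  pairs <- build_pair_table(sim$genes, true_clades(sim), sim$tree)
  ths <- c(1e4, 1e5, 1e6, 1e7, 1e8, Inf)
  fr <- sapply(ths, function(t) proximity_summary(pairs, t)$fraction)
  expect_true(all(diff(fr[1, ]) >= 0))
  expect_true(all(diff(fr[2, ]) >= 0))
  intra_share <- tapply(pairs$scaffold_class == "intrascaffold",
                        pairs$clade_class, mean)
  expect_equal(fr[1, length(ths)], unname(intra_share["intraclade"]))
  expect_equal(fr[2, length(ths)], unname(intra_share["interclade"]))
})

test_that("pair statistics are invariant to gene input order", {
  sim <- simulate_repertoire(sim_config(seed = 3, n_events = 25))
  pairs <- build_pair_table(sim$genes, true_clades(sim), sim$tree)
  set.seed(1)
  shuf <- sim$genes[sample(nrow(sim$genes)), ]
  pairs2 <- build_pair_table(shuf, true_clades(sim), sim$tree)
  expect_equal(pairs, pairs2)
})

test_that("scaffold occupancy orders by length and reports the top fraction", {
  genes <- make_genes(paste0("g", 1:10),
                      scaffold = c(rep("big", 7), rep("small", 3)),
                      start = (0:9) * 10000, end = (0:9) * 10000 + 1000)
  occ <- scaffold_occupancy(genes, c(big = 5e6, small = 2e5, tiny = 5e4))
  expect_equal(occ$scaffold, c("big", "small"))
  expect_equal(attr(occ, "top_fraction"), 0.7)
  expect_true(all(occ$shown))
  # short scaffolds are counted but flagged as below the display cutoff
  genes2 <- rbind(genes, make_genes("g11", "tiny", 0, 1000))
  occ2 <- scaffold_occupancy(genes2, c(big = 5e6, small = 2e5, tiny = 5e4))
  expect_false(occ2$shown[occ2$scaffold == "tiny"])
  expect_equal(sum(occ2$n_genes), 11)
})
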