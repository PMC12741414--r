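test_that("cophenetic distances match hand-computed path sums", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:3);")
  d <- cophenetic_distances(tr)
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 5)
  expect_equal(diag(d), setNames(rep(0, 3), c("A", "B", "C")))
  tr2 <- ape::read.tree(text = "(A:1.0,B:2.0);")
  expect_equal(cophenetic_distances(tr2)["A", "B"], 3)
  no_bl <- ape::read.tree(text = "((A,B),C);")
  expect_error(cophenetic_distances(no_bl), "branch length")
})

test_that("cophenetic distances satisfy the triangle inequality", {
  set.seed(7)
  for (i in 1:20) {
    tr <- ape::rtree(sample(4:20, 1))
    d <- cophenetic_distances(tr)
    n <- nrow(d)
    for (k in 1:5) {
      ijk <- sample(n, 3)
      expect_lte(d[ijk[1], ijk[3]],
                 d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-9)
    }
  }
})

test_that("rooting on an outgroup places it at the base and keeps supports", {
  tr <- ape::read.tree(text = "((A:1,B:1)90:1,(C:1,O:2)80:1);")
  rooted <- root_with_outgroup(tr, "O")
  expect_true(ape::is.rooted(rooted))
  # O's sister group is everything else
  d <- cophenetic_distances(rooted)
  expect_equal(sort(rownames(d)), c("A", "B", "C", "O"))
  # two-leaf monophyletic outgroup
  tr2 <- ape::read.tree(text = "((A:1,B:1)95:1,((O1:1,O2:1)99:1,C:1)70:1);")
  r2 <- root_with_outgroup(tr2, c("O1", "O2"))
  og_mrca <- ape::getMRCA(r2, c("O1", "O2"))
  expect_setequal(ape::extract.clade(r2, og_mrca)$tip.label, c("O1", "O2"))
  expect_true("99" %in% r2$node.label)
})

test_that("a non-monophyletic outgroup is an error naming the leaves", {
  tr <- ape::read.tree(text = "((A:1,O1:1):1,(O2:1,B:1):1,C:1);")
  expect_error(root_with_outgroup(tr, c("O1", "O2")), "not monophyletic")
  expect_error(root_with_outgroup(tr, c("O1", "ZZ")), "absent")
})

test_that("fractional supports are rejected unless declared", {
  tr <- ape::read.tree(text = "((A:1,B:1)0.95:1,(C:1,D:1)0.80:1);")
  expect_error(validate_tree(tr), "fractional")
  expect_equal(node_supports(tr, fractional_ok = TRUE), c(NA, 95, 80))
})

test_that("clade extraction selects maximal supported all-focal nodes", {
  tr <- planted_tree()
  focal <- paste0("f", 1:8)
  expect_warning(cl <- extract_clades(tr, focal), "only 1 clade")
  # the 6-leaf support-95 node is selected over its nested 4-leaf
  # support-95 descendant; f7/f8 sit under an unsupported node
  expect_equal(sum(cl == "Clade1"), 6)
  expect_setequal(names(cl)[cl == "Clade1"], paste0("f", 1:6))
  expect_setequal(names(cl)[cl == "Else"], c("f7", "f8"))
})

test_that("clades containing non-focal leaves never qualify", {
  tr <- ape::read.tree(
    text = "(((f1:1,f2:1)99:1,((f3:1,x9:1)99:1,(f4:1,f5:1)99:1)99:1)99:1,o:1);")
  cl <- suppressWarnings(extract_clades(tr, paste0("f", 1:5)))
  expect_true(all(cl == "Else"))
})

test_that("no qualifying node means all Else plus a warning", {
  tr <- ape::read.tree(text = "(((f1:1,f2:1)50:1,(f3:1,f4:1)60:1)40:1,o:1);")
  expect_warning(cl <- extract_clades(tr, paste0("f", 1:4)),
                 "0 clade")
  expect_true(all(cl == "Else"))
  expect_error(extract_clades(tr, paste0("f", 1:4), min_size = 1),
               "min_size")
})

test_that("clade labels order by decreasing size then first leaf", {
  tr <- ape::read.tree(text = paste0(
    "(((b1:1,(b2:1,(b3:1,(b4:1,b5:1)90:1)90:1)90:1)95:1,",
    "(a1:1,(a2:1,(a3:1,(a4:1,(a5:1,a6:1)90:1)90:1)90:1)90:1)95:1)50:1,o:1);"))
  cl <- suppressWarnings(extract_clades(tr, c(paste0("a", 1:6),
                                              paste0("b", 1:5))))
  expect_equal(unname(cl["a1"]), "Clade1")  # larger clade first
  expect_equal(unname(cl["b1"]), "Clade2")
})

test_that("reference-clade classification assigns by smallest defining clade", {
  # hagA falls inside the MRCA clade of the three V2R references; hagB
  # inside the CaSR reference clade; hagC is sister to every reference
  # panel and stays unclassified
  tr <- ape::read.tree(text = paste0(
    "(((((hagA:1,(V2Rref1:1,V2Rref2:1)95:1)90:1,V2Rref3:1)90:1,",
    "((hagB:1,CASRref1:1)90:1,CASRref2:1)99:1)80:1,hagC:1)70:1,",
    "(out1:1,out2:1)99:1);"))
  refs <- list(V2R = c("V2Rref1", "V2Rref2", "V2Rref3"),
               CaSR = c("CASRref1", "CASRref2"))
  cls <- classify_by_reference_clade(tr, refs, c("hagA", "hagB", "hagC"))
  expect_equal(unname(cls["hagA"]), "V2R")
  expect_equal(unname(cls["hagB"]), "CaSR")
  expect_equal(unname(cls["hagC"]), "unclassified")
  expect_error(classify_by_reference_clade(tr, list(g = "nope"), "hagA"),
               "absent")
  expect_error(
    classify_by_reference_clade(tr, list(a = "hagA", b = "hagA"), "hagB"),
    "disjoint")
})

test_that("classification is invariant to node rotations", {
  tr <- ape::read.tree(text = paste0(
    "(((hagA:1,(R1:1,R2:1)95:1)90:1,(S1:1,S2:1)99:1)80:1,out:1);"))
  refs <- list(G1 = c("R1", "R2", "hagA"), G2 = c("S1", "S2"))
  base <- classify_by_reference_clade(tr, refs, "hagA")
  rot <- ape::rotate(tr, ape::getMRCA(tr, c("hagA", "R1")))
  rot2 <- ape::rotate(tr, ape::getMRCA(tr, c("S1", "S2")))
  expect_equal(classify_by_reference_clade(rot, refs, "hagA"), base)
  expect_equal(classify_by_reference_clade(rot2, refs, "hagA"), base)
})
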