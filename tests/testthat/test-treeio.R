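test_that("read_tree parses minimal Newick trees and validates structure", {
  t2 <- read_tree("(A:1,B:1);")
  expect_s3_class(t2, "phylo")
  expect_setequal(t2$tip.label, c("A", "B"))
  expect_equal(unname(diag(unclass(vcv_matrix(t2)))), c(1, 1))

  t3 <- read_tree("(A:1,(B:0.5,C:0.5):0.5);")
  C <- unclass(vcv_matrix(t3))
  expect_equal(C["B", "C"], 0.5)   # B,C share history down to depth 0.5
  expect_equal(C["A", "B"], 0)
})

test_that("read_tree rejects malformed or incomplete input", {
  expect_error(read_tree("(A:1,(B:1,C:1):1;"), "parse")
  expect_error(read_tree("(A:1,B:1,A:1);"), "duplicate tip")
  expect_error(read_tree("(A,B);"), "branch length")
  expect_error(read_tree("(A:1,B:-1);"), "negative")
  expect_warning(read_tree("(A:1,B:1):0.3;"), "root edge")
  expect_error(read_tree(text = "(A:1,B:1);", file = "x"), "exactly one")
})

test_that("a tree without branch lengths can opt in to Grafen depths", {
  expect_message(tr <- read_tree("((A,B),C);", grafen = TRUE), "Grafen")
  expect_true(all(tr$edge.length > 0))
})

test_that("Nexus input with a TRANSLATE table resolves labels", {
  nex <- paste(
    "#NEXUS",
    "BEGIN TREES;",
    "\tTRANSLATE",
    "\t\t1 Tyrannosaurus,",
    "\t\t2 Allosaurus,",
    "\t\t3 Archaeopteryx;",
    "\tTREE t1 = ((1:1.0,2:1.0):0.5,3:1.5);",
    "END;", sep = "\n")
  tr <- read_tree(nex)
  expect_setequal(tr$tip.label,
                  c("Tyrannosaurus", "Allosaurus", "Archaeopteryx"))
  expect_equal(unclass(vcv_matrix(tr))["Tyrannosaurus", "Allosaurus"], 0.5)
})

test_that("write -> read round-trips topology and branch lengths", {
  for (i in 1:100) {
    tr <- simulate_yule(sample(4:40, 1), birth_rate = 1, seed = 1000 + i)
    # full-precision serialization preserves path lengths to 1e-12
    tr2 <- read_tree(write_tree(tr, digits = 16))
    expect_equal(sort(tr2$tip.label), sort(tr$tip.label))
    d1 <- ape::cophenetic.phylo(tr)
    d2 <- ape::cophenetic.phylo(tr2)[rownames(d1), colnames(d1)]
    expect_lt(max(abs(d1 - d2)), 1e-12)
  }
  # idempotence: a second round-trip is a fixed point
  tr <- simulate_yule(15, 1, seed = 77)
  s1 <- write_tree(read_tree(write_tree(tr)))
  expect_identical(write_tree(read_tree(s1)), s1)
})

test_that("prune_to_taxa keeps induced path lengths and collapses chains", {
  t3 <- read_tree("(A:1,(B:0.5,C:0.5):0.5);")
  p <- prune_to_taxa(t3, c("B", "C"))
  expect_setequal(p$tip.label, c("B", "C"))
  expect_equal(ape::cophenetic.phylo(p)["B", "C"], 1)

  full <- prune_to_taxa(t3, c("A", "B", "C"))
  expect_equal(ape::cophenetic.phylo(full), ape::cophenetic.phylo(t3))

  expect_error(prune_to_taxa(t3, c("B", "Zzz")), "Zzz")

  for (i in 1:50) {
    tr <- random_tree(sample(6:20, 1), seed = 4000 + i)
    keep <- sample(tr$tip.label, sample(3:5, 1))
    pr <- prune_to_taxa(tr, keep)
    d_full <- ape::cophenetic.phylo(tr)[keep, keep]
    d_sub <- ape::cophenetic.phylo(pr)[keep, keep]
    expect_lt(max(abs(d_full - d_sub)), 1e-12)
  }
})

test_that("vcv_matrix matches path-summation oracle and is PSD", {
  for (i in 1:100) {
    tr <- random_tree(sample(3:10, 1), seed = 2000 + i)
    C <- unclass(vcv_matrix(tr))
    expect_lt(max(abs(C - oracle_vcv(tr))), 1e-12)
    expect_gt(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("vcv_matrix is invariant to child order at any node", {
  tr <- read_tree("((A:1,B:2):0.5,(C:0.7,D:0.3):1.5);")
  sw <- read_tree("((D:0.3,C:0.7):1.5,(B:2,A:1):0.5);")
  lab <- tr$tip.label
  expect_equal(unclass(vcv_matrix(tr))[lab, lab],
               unclass(vcv_matrix(sw))[lab, lab])
})

test_that("pruning commutes with restriction of the covariance", {
  # the pruned tree is re-rooted at the kept taxa's MRCA (the stem above
  # it is absorbed per the root-edge convention), so the original
  # submatrix equals the pruned covariance plus that constant stem depth
  for (i in 1:20) {
    tr <- random_tree(10, seed = 3000 + i)
    keep <- sample(tr$tip.label, 4)
    Cs <- unclass(vcv_matrix(prune_to_taxa(tr, keep)))[keep, keep]
    Cr <- unclass(vcv_matrix(tr))[keep, keep]
    stem <- ape::node.depth.edgelength(tr)[ape::getMRCA(tr, keep)]
    expect_lt(max(abs(Cs + stem - Cr)), 1e-12)
  }
})

test_that("match_taxa reports mismatches side by side and can prune", {
  tr <- read_tree("((A_x:1,B:1):1,(C:1,D:1):1);")
  expect_error(match_taxa(tr, c("A x", "B", "C", "Q")), "mismatch")
  expect_message(m <- match_taxa(tr, c("A x", "B", "C", "Q"), prune = TRUE),
                 "dropped")
  expect_setequal(m$tree$tip.label, c("A_x", "B", "C"))
  # underscore/space normalization is symmetric
  ok <- match_taxa(tr, c("A x", "B", "C", "D"))
  expect_equal(length(ok$taxa), 4)
})
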