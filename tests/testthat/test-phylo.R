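test_that("cophenetic distances are path sums", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  d <- cophenetic_distance(tr)
  expect_equal(d["a", "b"], 2)
  expect_equal(d["a", "c"], 4)
  expect_equal(d["b", "c"], 4)
  expect_equal(diag(d), setNames(rep(0, 3), c("a", "b", "c")))
})

test_that("cophenetic distances match brute-force path enumeration", {
  tr <- random_tree(20, seed = 7)
  expect_equal(cophenetic_distance(tr), brute_cophenetic(tr),
               tolerance = 1e-10)
})

test_that("phylogenetic covariance is MRCA depth", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  rel <- phylo_covariance(tr)
  A <- rel$A
  expect_equal(unname(diag(A)), c(2, 2, 2))
  expect_equal(A["a", "b"], 1)
  expect_equal(A["a", "c"], 0)
  expect_true(rel$ultrametric)

  star <- ape::read.tree(text = "(a:3,b:3,c:3,d:3);")
  expect_equal(unname(phylo_covariance(star)$A), diag(3, 4))
})

test_that("cophenetic and covariance satisfy d(a,b) = A_aa + A_bb - 2 A_ab", {
  for (s in c(2, 9)) {
    tr <- random_tree(20, seed = s)
    A <- phylo_covariance(tr)$A
    d <- cophenetic_distance(tr)
    pred <- outer(diag(A), diag(A), "+") - 2 * A
    expect_equal(d, pred, tolerance = 1e-10)
  }
})

test_that("inverse relatedness matches dense inversion and the star closed form", {
  star <- ape::read.tree(text = "(a:3,b:3,c:3,d:3);")
  rel <- inverse_relatedness(phylo_covariance(star))
  expect_equal(unname(rel$A_inv), diag(1 / 3, 4), tolerance = 1e-12)

  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  rel <- inverse_relatedness(phylo_covariance(tr))
  expect_equal(rel$A_inv, solve(rel$A), tolerance = 1e-9)

  tr <- random_tree(50, seed = 3)
  rel <- inverse_relatedness(phylo_covariance(tr))
  resid <- max(abs(rel$A %*% rel$A_inv - diag(50)))
  expect_lt(resid, 1e-8)
})

test_that("dyad variance statistics reproduce the trivial cases", {
  # two tips splitting at the root, depth 1, one genus: variance 1 + 1 + 0
  tr <- ape::read.tree(text = "(a:1,b:1);")
  st <- dyad_variance_stats(phylo_covariance(tr), c(a = "G", b = "G"))
  expect_equal(st$B_bar_S, 2)
  expect_equal(st$B_bar, 2)

  # star tree of depth T: B_bar_S = 2T exactly
  star <- ape::read.tree(text = "(a:5,b:5,c:5,d:5);")
  st <- dyad_variance_stats(phylo_covariance(star),
                            setNames(rep("G", 4), c("a", "b", "c", "d")))
  expect_equal(st$B_bar_S, 10)
  expect_identical(unname(st$n_ci), 6)
})

test_that("B_bar_S equals the brute-force congeneric dyad mean", {
  tr <- random_tree(25, seed = 11)
  genus <- setNames(paste0("G", rep(1:5, each = 5)), tr$tip.label)
  rel <- phylo_covariance(tr)
  st <- dyad_variance_stats(rel, genus)
  expect_equal(st$B_bar_S, brute_B_bar_S(rel$A, genus[rel$species]),
               tolerance = 1e-10)
  # B_bar likewise equals the all-pairs dyad mean
  allg <- setNames(rep("G", 25), tr$tip.label)
  expect_equal(st$B_bar,
               brute_B_bar_S(rel$A, allg[rel$species]), tolerance = 1e-10)
})

test_that("dyad variance statistics are invariant to ordering and labels", {
  tr <- random_tree(15, seed = 5)
  genus <- setNames(paste0("G", rep(1:3, each = 5)), tr$tip.label)
  rel <- phylo_covariance(tr)
  st1 <- dyad_variance_stats(rel, genus)
  st2 <- dyad_variance_stats(rel, rev(genus))           # reordered map
  genus3 <- setNames(paste0("Clade_", genus), names(genus))
  st3 <- dyad_variance_stats(rel, genus3)               # renamed genera
  expect_equal(st1$B_bar_S, st2$B_bar_S, tolerance = 1e-12)
  expect_equal(st1$B_bar_S, st3$B_bar_S, tolerance = 1e-12)
})

test_that("B_bar_S errors without any multi-species genus", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  expect_error(dyad_variance_stats(phylo_covariance(tr),
                                   c(a = "G1", b = "G2")),
               "B_bar_S undefined")
})

test_that("sequence distances follow sqrt(1 - identity) with pairwise deletion", {
  expect_equal(sequence_distance(c(x = "ACGT", y = "ACGT"))["x", "y"], 0)
  expect_equal(sequence_distance(c(x = "ACGT", y = "ACGA"))["x", "y"], 0.5)
  # gap column removed pairwise: 3 compared positions, all matching
  expect_equal(sequence_distance(c(x = "AC-T", y = "ACGT"))["x", "y"], 0)
  # N treated as gap
  expect_equal(sequence_distance(c(x = "ACNT", y = "ACGA"))["x", "y"],
               sqrt(1 - 2 / 3))
  expect_error(sequence_distance(c(x = "ACG", y = "AC")), "equal length")
  expect_true(is.nan(sequence_distance(c(x = "--", y = "AA"))["x", "y"]))
})

test_that("sequence distances agree with seqinr on gap-free alignments", {
  skip_if_not_installed("seqinr")
  set.seed(4)
  seqs <- vapply(1:5, function(i)
    paste(sample(c("a", "c", "g", "t"), 60, TRUE), collapse = ""),
    character(1))
  names(seqs) <- paste0("s", 1:5)
  ours <- sequence_distance(toupper(seqs))
  aln <- seqinr::as.alignment(nb = 5, nam = names(seqs), seq = unname(seqs))
  ref <- as.matrix(seqinr::dist.alignment(aln, matrix = "identity"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})
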