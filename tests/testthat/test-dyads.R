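test_that("exclusion filters remove records in the documented order", {
  fx <- fixture_flora()
  hy <- make_hybrids(list(c("a1", "a2"), c("a1", "a3"), c("a2", "a3"),
                          c("b1", "b2"), c("b1", "b3"), c("c1", "c2")),
                     origin_flag = c("formed-abroad", rep("native-formed", 5)),
                     parent_count = c(3L, 3L, 2L, 2L, 2L, 2L),
                     certainty_flag = c("accepted", "accepted", "dubious",
                                        "accepted", "accepted", "accepted"),
                     rank_flag = c(rep("species", 3), "infraspecific",
                                   "species", "species"),
                     intergeneric = c(rep(FALSE, 4), TRUE, FALSE))
  res <- apply_exclusion_filters(hy, fx$species)
  # first record hits formed_abroad before the triple-hybrid filter
  expect_equal(unname(res$audit["formed_abroad"]), 1L)
  expect_equal(unname(res$audit["triple_hybrid"]), 1L)
  expect_equal(unname(res$audit["dubious"]), 1L)
  expect_equal(unname(res$audit["infraspecific"]), 1L)
  expect_equal(unname(res$audit["intergeneric"]), 1L)
  expect_equal(unname(res$audit["retained"]), 1L)
  expect_equal(res$hybrids$parent1, "c1")
  expect_equal(sum(res$audit[names(res$audit) != "retained"]) +
                 res$audit[["retained"]], nrow(hy))
})

test_that("parents without barcodes are filtered", {
  sp <- make_species(c("x1", "x2", "x3"), "GenX",
                     barcode = c(TRUE, TRUE, FALSE))
  hy <- make_hybrids(list(c("x1", "x2"), c("x1", "x3")))
  res <- apply_exclusion_filters(hy, sp)
  expect_equal(unname(res$audit["no_barcode"]), 1L)
  expect_equal(res$hybrids$parent2, "x2")
})

test_that("hybrids naming unknown species raise an error", {
  sp <- make_species(c("x1", "x2"), "GenX")
  hy <- make_hybrids(list(c("x1", "zz")))
  expect_error(apply_exclusion_filters(hy, sp), "zz")
})

test_that("ploidy assignment resolves cytotypes per the annotation rule", {
  sp <- make_species(c("p1", "p2", "p3"), "GenP",
                     ploidy = list(2L, c(2L, 4L), integer(0)))
  pa <- ploidy_assignment(sp)
  expect_equal(unname(pa$species_ploidy), c(2L, NA, NA))

  hy <- make_hybrids(list(c("p1", "p2")), cytotype2 = "4")
  pa <- ploidy_assignment(sp, hy)
  expect_equal(pa$pair_ploidy$ploidy1, 2L)
  expect_equal(pa$pair_ploidy$ploidy2, 4L)   # annotation resolves the dyad

  # annotation outside the recorded pool does not resolve
  hy2 <- make_hybrids(list(c("p1", "p2")), cytotype2 = "6")
  expect_true(is.na(ploidy_assignment(sp, hy2)$pair_ploidy$ploidy2))

  sp_bad <- make_species("q1", "GenQ")
  sp_bad$ploidy <- list(-2L)
  expect_error(ploidy_assignment(sp_bad), "ploidy")
})

test_that("build_dyads enumerates within-genus pairs with covariates", {
  fx <- fixture_flora()
  dy <- build_dyads(fx$species, fx$hybrids, fx$tree, hectad_policy = "zero")
  # genera of sizes 4, 3, 2, 1 -> 6 + 3 + 1 + 0 rows
  expect_equal(nrow(dy), 10)
  expect_equal(as.integer(table(dy$genus)[c("GenA", "GenB", "GenC")]),
               c(6L, 3L, 1L))
  # row count matches the independent genus census
  sizes <- table(fx$species$genus)
  expect_equal(nrow(dy), sum(sizes * (sizes - 1) / 2))

  r <- dy[dy$species_a == "a1" & dy$species_b == "a2", ]
  expect_equal(r$hybridizes, 1L)
  expect_equal(r$branch_length, 2)
  expect_equal(r$hectad_overlap, 2L)     # {H1,H2,H3} n {H2,H3,H4}
  expect_equal(r$genus_size, 4L)
  expect_equal(r$life_history_pair, "annual-annual")
  expect_equal(r$ploidy_match, "homoploid")

  r <- dy[dy$species_a == "b1" & dy$species_b == "b3", ]
  expect_equal(r$hybridizes, 0L)
  expect_equal(r$ploidy_match, "heteroploid")
  r <- dy[dy$species_a == "c1" & dy$species_b == "c2", ]
  expect_equal(r$life_history_pair, "annual-perennial")
  expect_equal(r$ploidy_match, "unknown")   # c2 ploidy unrecorded
  # hybridizes column sums to surviving congeneric hybrid records
  expect_equal(sum(dy$hybridizes), 2)
})

test_that("dyad table is invariant to row order and parent swaps", {
  fx <- fixture_flora()
  dy1 <- build_dyads(fx$species, fx$hybrids, fx$tree, hectad_policy = "zero")
  sp2 <- fx$species[rev(seq_len(nrow(fx$species))), ]
  class(sp2) <- class(fx$species)
  hy2 <- fx$hybrids
  hy2[, c("parent1", "parent2")] <- hy2[, c("parent2", "parent1")]
  dy2 <- build_dyads(sp2, hy2, fx$tree, hectad_policy = "zero")
  expect_equal(as.data.frame(dy1), as.data.frame(dy2))
})

test_that("hectad policy controls dyads with missing distribution data", {
  sp <- make_species(c("m1", "m2", "m3"), "GenM",
                     hectads = list(c("H1", "H2"), c("H2"), character(0)))
  tr <- ape::read.tree(text = "((m1:1,m2:1):1,m3:2);")
  dy_drop <- build_dyads(sp, empty_hybrid_table(), tr,
                         hectad_policy = "drop")
  expect_equal(nrow(dy_drop), 1)         # only m1-m2 survives
  dy_zero <- build_dyads(sp, empty_hybrid_table(), tr,
                         hectad_policy = "zero")
  expect_equal(nrow(dy_zero), 3)
  expect_equal(dy_zero$hectad_overlap[dy_zero$species_b == "m3"], c(0L, 0L))
})

test_that("species missing from the tree are reported", {
  sp <- make_species(c("m1", "m2"), "GenM")
  tr <- ape::read.tree(text = "(m1:1,x9:1);")
  expect_error(build_dyads(sp, empty_hybrid_table(), tr), "m2")
})
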