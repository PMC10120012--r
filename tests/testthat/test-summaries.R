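test_that("HPD intervals shrink with the level and span the range at 1", {
  set.seed(2)
  x <- rgamma(2000, 2)
  h95 <- hpd_interval(x, 0.95)
  h50 <- hpd_interval(x, 0.50)
  h100 <- hpd_interval(x, 1.0)
  expect_equal(unname(h100), range(x))
  expect_lt(diff(h50), diff(h95))
  expect_true(h95[1] >= h100[1] && h95[2] <= h100[2])
  # at least 95% of draws inside
  expect_gte(mean(x >= h95[1] & x <= h95[2]), 0.95)
})

test_that("pMCMC follows the two-sided tail definition", {
  expect_equal(pmcmc(c(-1, 1, 2, 3)), 0.5)
  expect_equal(pmcmc(rep(1, 50)), 2 / 50)       # floored at 1/n scale
  set.seed(1)
  x <- rnorm(4000)
  expect_gt(pmcmc(x), 0.9)
})

test_that("phylogenetic signal is the liability variance ratio", {
  sm <- cbind(sigma2_species = 0.5, sigma2_phylo = 1)
  sig <- phylo_signal(sm, B_bar_S = 2)
  expect_equal(sig$draws, 2 / (1 + 1 + 2))
  sm0 <- cbind(sigma2_species = rep(0.3, 10), sigma2_phylo = rep(0, 10))
  expect_equal(phylo_signal(sm0, B_bar_S = 2)$draws, rep(0, 10))
  expect_error(phylo_signal(sm[0, , drop = FALSE], B_bar_S = 2), "empty")
})

test_that("signal is monotone in the variance components", {
  s2p <- seq(0.1, 2, length.out = 10)
  lam <- phylo_signal(cbind(sigma2_species = 0.5, sigma2_phylo = s2p),
                      B_bar_S = 3)$draws
  expect_true(all(diff(lam) > 0))
  s2s <- seq(0.1, 2, length.out = 10)
  lam2 <- phylo_signal(cbind(sigma2_species = s2s, sigma2_phylo = 1),
                       B_bar_S = 3)$draws
  expect_true(all(diff(lam2) < 0))
  expect_true(all(lam > 0 & lam < 1))
})

test_that("marginal predictions collapse to the plain probit without variances", {
  fit <- small_fit_cache()$fit
  # zero out the variance draws: prediction must equal pnorm(x beta)
  fake <- fit
  fake$samples[, c("sigma2_species", "sigma2_phylo")] <- 0
  nd <- data.frame(branch_length = 1, hectad_overlap = 10, genus_size = 4,
                   life_history_pair = "perennial-perennial")
  draws <- predict(fake, newdata = nd, type = "draws")[, 1]
  X <- cbind(1, 1, 10, 4, 0, 1)
  eta <- fake$samples[, fake$fixed_names] %*% t(X)
  expect_equal(draws, drop(pnorm(eta)), tolerance = 1e-12)
  # symmetry: zero linear predictor gives probability one half
  expect_equal(mean(pnorm(0)), 0.5)
})

test_that("marginal predictions divide by the total liability SD", {
  sm <- cbind(`(Intercept)` = 1, sigma2_species = 0.5, sigma2_phylo = 0.25)
  fit <- structure(list(samples = sm, fixed_names = "(Intercept)",
                        stats = list(B_bar_S = 4),
                        design = list(X = matrix(1, 1, 1,
                          dimnames = list(NULL, "(Intercept)"))),
                        include_ploidy = FALSE,
                        config = list(standardize = FALSE)),
                   class = "dyad_probit")
  p <- predict(fit, type = "draws")[1, 1]
  expect_equal(p, pnorm(1 / sqrt(1 + 2 * 0.5 + 0.25 * 4)))
})

test_that("calibration: marginal probit probability tracks outcome frequency", {
  # in expectation over floras the observed hybridization frequency matches
  # the marginal prediction at the generative parameters; per-flora values
  # scatter with the realized global phylogenetic effect (see vignette)
  res <- vapply(1:8, function(s) {
    fl <- simulate_flora(flora_config(n_species = 100), seed = s)
    dy <- build_dyads(fl$species, empty_hybrid_table(), fl$tree,
                      hectad_policy = "zero")
    sim <- simulate_hybridization(fl, dy, seed = s + 50)
    sp <- sort(unique(c(dy$species_a, dy$species_b)))
    rel <- phylo_covariance(ape::keep.tip(fl$tree, sp))
    st <- dyad_variance_stats(rel, setNames(fl$truth$genus[sp], sp))
    cfg <- fl$truth$config
    p <- pnorm(sim$truth$linear_predictor /
                 sqrt(1 + 2 * cfg$sigma2_species +
                        cfg$sigma2_phylo * st$B_bar_S))
    c(obs = mean(sim$dyads$hybridizes), marg = mean(p))
  }, numeric(2))
  expect_lt(abs(mean(res["obs", ]) - mean(res["marg", ])), 0.03)
})

test_that("Wald test matches its closed form and degenerate case", {
  set.seed(9)
  draws <- matrix(rnorm(2000), ncol = 2,
                  dimnames = list(NULL, c("c1", "c2")))
  w <- wald_joint_test(draws, c("c1", "c2"))
  m <- colMeans(draws); S <- cov(draws)
  expect_equal(w$statistic, drop(t(m) %*% solve(S) %*% m))
  expect_equal(w$df, 2)
  expect_equal(w$p.value, exp(-w$statistic / 2), tolerance = 1e-12)

  # exactly zero posterior mean: W = 0, p = 1
  d0 <- rbind(c(-1, -2), c(1, 2), c(-2, 1), c(2, -1))
  colnames(d0) <- c("c1", "c2")
  w0 <- wald_joint_test(d0, c("c1", "c2"))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p.value, 1)
  expect_error(wald_joint_test(draws, "c1"), "two")
  expect_error(wald_joint_test(draws, c("c1", "zz")), "zz")
})

test_that("ploidy effect arithmetic reproduces the worked ratio", {
  # single draw engineered so p_homo and p_hetero hit chosen values
  b0 <- qnorm(0.20)
  b_homo <- qnorm(0.27) - qnorm(0.20)
  sm <- cbind(`(Intercept)` = b0, branch_length = 0, hectad_overlap = 0,
              genus_size = 0, `life_history_pairannual-perennial` = 0,
              `life_history_pairperennial-perennial` = 0,
              ploidy_matchhomoploid = b_homo,
              sigma2_species = 0, sigma2_phylo = 0)
  dyads <- data.frame(branch_length = 0, hectad_overlap = 0, genus_size = 0)
  fit <- structure(list(samples = sm, fixed_names = colnames(sm)[1:7],
                        stats = list(B_bar_S = 1),
                        design = list(dyads = dyads),
                        include_ploidy = TRUE,
                        config = list(standardize = FALSE)),
                   class = "dyad_probit")
  eff <- ploidy_effect(fit, dyads)
  expect_equal(eff$relative$draws, 0.27 / 0.20 - 1, tolerance = 1e-10)
  expect_equal(eff$absolute$draws, 0.07, tolerance = 1e-10)
  # zero coefficient: zero relative increase
  sm0 <- sm; sm0[, "ploidy_matchhomoploid"] <- 0
  fit0 <- fit; fit0$samples <- sm0
  expect_equal(ploidy_effect(fit0, dyads)$relative$draws, 0)
  # model-1 fit refuses
  fit1 <- fit; fit1$fixed_names <- colnames(sm)[1:6]
  expect_error(ploidy_effect(fit1, dyads), "model-2")
})

test_that("species BLUPs aggregate to genus totals and rank clades", {
  fit <- small_fit_cache()$fit
  bl <- species_blups(fit, top_k = 3)
  expect_equal(bl$species$propensity,
               bl$species$u_species + bl$species$u_phylo)
  for (g in bl$genera$genus[1:2]) {
    expect_equal(bl$genera$propensity[bl$genera$genus == g],
                 sum(bl$species$propensity[bl$species$genus == g]))
  }
  expect_equal(sum(bl$genera$top), 3)
  expect_true(all(diff(bl$genera$propensity) <= 0))
})
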