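#' One parameter-recovery replicate for the signal calibration harness
#'
#' Simulates a flora, sets the true phylogenetic variance so the generative
#' phylogenetic signal equals `lambda_true` given the simulated tree's
#' genus-constrained dyad variance multiplier (`sigma2_phylo =
#' lambda_true * (1 + 2 sigma2_species) / ((1 - lambda_true) * B_bar_S)`),
#' draws outcomes under null fixed effects, refits the model and summarizes
#' recovery. Null fixed effects keep the outcome rate near one half, the
#' regime in which the dyad variance components are identifiable; with rare
#' outcomes (as in real floras) most genera carry no hybrid and the variance
#' likelihood develops a long flat right ridge (see the package vignette).
#'
#' @param seed integer seed for this replicate (flora, outcomes and chain).
#' @param n_species simulated flora size.
#' @param sigma2_species true species variance.
#' @param lambda_true generative phylogenetic signal.
#' @param n_iter,burnin,thin MCMC settings for the refit.
#' @return list: `lambda_mode`, `lambda_hpd`, `sigma2_phylo_true`,
#'   `sigma2_phylo_hpd`, `covers` (does the 95% HPD cover the truth),
#'   `freq` (outcome rate), `n_dyads`.
#' @export
recovery_replicate <- function(seed, n_species = 200, sigma2_species = 0.5,
                               lambda_true = 0.5, n_iter = 10000,
                               burnin = 2000, thin = 10) {
  beta0 <- c(intercept = 0, branch_length = 0, hectad_overlap = 0,
             genus_size = 0, lh_annual_perennial = 0,
             lh_perennial_perennial = 0, ploidy_homoploid = 0)
  fl <- simulate_flora(flora_config(n_species = n_species), seed = seed)
  dy <- build_dyads(fl$species, .empty_hybrids(), fl$tree,
                    hectad_policy = "zero")
  sp <- sort(unique(c(dy$species_a, dy$species_b)))
  rel <- phylo_covariance(ape::keep.tip(fl$tree, sp))
  st <- dyad_variance_stats(rel, stats::setNames(fl$truth$genus[sp], sp))
  s2p <- lambda_true * (1 + 2 * sigma2_species) /
    ((1 - lambda_true) * st$B_bar_S)
  fl$truth$config <- flora_config(n_species = n_species, beta = beta0,
                                  sigma2_species = sigma2_species,
                                  sigma2_phylo = s2p)
  sim <- simulate_hybridization(fl, dy, seed = seed + 500L)
  fit <- suppressWarnings(
    dyad_probit(sim$dyads, fl$tree, n_iter = n_iter, burnin = burnin,
                thin = thin, seed = seed + 900L))
  sig <- phylo_signal(fit)
  hp <- hpd_interval(fit$samples[, "sigma2_phylo"])
  list(lambda_mode = sig$mode, lambda_hpd = sig$hpd,
       sigma2_phylo_true = s2p, sigma2_phylo_hpd = hp,
       covers = unname(s2p >= hp[1] & s2p <= hp[2]),
       freq = mean(sim$dyads$hybridizes), n_dyads = nrow(dy))
}

# internal empty hybrid table (no surviving records)
.empty_hybrids <- function() {
  df <- data.frame(parent1 = character(0), parent2 = character(0),
                   origin_flag = character(0), rank_flag = character(0),
                   certainty_flag = character(0), parent_count = integer(0),
                   intergeneric = logical(0), cytotype1 = character(0),
                   cytotype2 = character(0), stringsAsFactors = FALSE)
  class(df) <- c("hybrid_table", "data.frame")
  df
}
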