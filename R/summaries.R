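#' Highest posterior density interval
#'
#' Shortest interval containing `prob` of the draws (empirical
#' shortest-interval algorithm on sorted samples).
#'
#' @param x numeric draws.
#' @param prob interval mass in (0, 1]; `prob = 1` spans the sample range.
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  stopifnot(length(x) > 0, prob > 0, prob <= 1)
  xs <- sort(x)
  n <- length(xs)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = xs[1], upper = xs[n]))
  width <- xs[(m + 1):n] - xs[1:(n - m)]
  i <- which.min(width)
  c(lower = xs[i], upper = xs[i + m])
}

#' Kernel-density posterior mode
#'
#' Mode of a Gaussian kernel density estimate with Silverman's
#' rule-of-thumb bandwidth.
#'
#' @param x numeric draws.
#' @export
posterior_mode <- function(x) {
  stopifnot(length(x) > 0)
  if (length(unique(x)) == 1L) return(x[1])
  d <- stats::density(x, bw = "nrd0")
  d$x[which.max(d$y)]
}

#' Two-sided MCMC p-value
#'
#' `2 * min(P(theta > 0), P(theta < 0))`, floored at 1/(number of draws) and
#' capped at 1.
#'
#' @param x numeric vector of posterior draws of one coefficient.
#' @export
pmcmc <- function(x) {
  n <- length(x)
  stopifnot(n > 0)
  # tail fraction floored at 1/n so no coefficient reports exactly zero
  min(1, 2 * max(min(mean(x > 0), mean(x < 0)), 1 / n))
}

#' Phylogenetic signal of hybridization
#'
#' Per posterior draw, the fraction of dyad liability variance attributable
#' to phylogeny:
#' lambda = sigma2_p * B_bar_S / (sigma2_u + 2 sigma2_s + sigma2_p * B_bar_S),
#' with the residual sigma2_u fixed at 1 and B_bar_S the genus-constrained
#' dyad variance multiplier. Summarized by the kernel-density posterior mode
#' and the 95% HPD interval.
#'
#' @param fit a `dyad_probit` fit with the phylogenetic term, or a matrix /
#'   data.frame of draws with columns `sigma2_species` and `sigma2_phylo`
#'   (then `B_bar_S` must be given).
#' @param B_bar_S override for the dyad variance multiplier.
#' @param prob HPD mass.
#' @return list with `draws`, `mode`, `hpd`, `B_bar_S`.
#' @export
phylo_signal <- function(fit, B_bar_S = NULL, prob = 0.95) {
  if (inherits(fit, "dyad_probit")) {
    sm <- fit$samples
    if (is.null(B_bar_S)) {
      if (is.null(fit$stats)) stop("fit carries no dyad variance statistics")
      B_bar_S <- fit$stats$B_bar_S
    }
  } else sm <- as.matrix(fit)
  if (is.null(B_bar_S) || B_bar_S <= 0)
    stop("B_bar_S must be a positive scalar")
  if (!nrow(sm)) stop("empty sample set")
  if (!"sigma2_phylo" %in% colnames(sm))
    stop("samples lack a sigma2_phylo column")
  s2s <- if ("sigma2_species" %in% colnames(sm)) sm[, "sigma2_species"] else 0
  s2p <- sm[, "sigma2_phylo"]
  lam <- unname(s2p * B_bar_S / (1 + 2 * s2s + s2p * B_bar_S))
  list(draws = lam, mode = posterior_mode(lam),
       hpd = hpd_interval(lam, prob), B_bar_S = B_bar_S)
}

#' Marginal prediction at explicit covariate values
#'
#' Convenience wrapper around [predict.dyad_probit()] returning the posterior
#' draws and mode/HPD summary of the marginal hybridization probability for
#' one covariate row.
#'
#' @param fit a `dyad_probit` fit.
#' @param covariate_row one-row data.frame of covariates.
#' @param prob HPD mass.
#' @export
marginal_prediction <- function(fit, covariate_row, prob = 0.95) {
  draws <- predict(fit, newdata = covariate_row, type = "draws")[, 1]
  list(draws = draws, mode = posterior_mode(draws), mean = mean(draws),
       hpd = hpd_interval(draws, prob))
}

#' Relative effect of shared ploidy on hybridization probability
#'
#' For each posterior draw of a model-2 fit, the marginal hybridization
#' probability is computed at the mean branch length, mean hectad overlap and
#' mean genus size of the fitted dyads, at the reference life-history level,
#' for a homoploid and a heteroploid pair; reported as the posterior of the
#' relative increase `p_homo / p_hetero - 1` (and the absolute difference).
#'
#' @param fit a `dyad_probit` model-2 fit (ploidy contrast present).
#' @param dyads dyad table used to take covariate means; defaults to the
#'   fitted dyads.
#' @param prob HPD mass.
#' @return list with `relative` and `absolute` summaries (draws, mode, HPD).
#' @export
ploidy_effect <- function(fit, dyads = NULL, prob = 0.95) {
  if (!"ploidy_matchhomoploid" %in% fit$fixed_names)
    stop("ploidy effect requires a model-2 fit (ploidy contrast present)")
  if (is.null(dyads)) dyads <- fit$design$dyads
  base <- data.frame(branch_length = mean(dyads$branch_length),
                     hectad_overlap = mean(dyads$hectad_overlap),
                     genus_size = mean(dyads$genus_size),
                     life_history_pair = "annual-annual",
                     stringsAsFactors = FALSE)
  homo <- cbind(base, ploidy_match = "homoploid")
  hetero <- cbind(base, ploidy_match = "heteroploid")
  p_homo <- predict(fit, newdata = homo, type = "draws")[, 1]
  p_het <- predict(fit, newdata = hetero, type = "draws")[, 1]
  rel <- p_homo / p_het - 1
  abs_d <- p_homo - p_het
  list(relative = list(draws = rel, mode = posterior_mode(rel),
                       mean = mean(rel), hpd = hpd_interval(rel, prob)),
       absolute = list(draws = abs_d, mode = posterior_mode(abs_d),
                       mean = mean(abs_d), hpd = hpd_interval(abs_d, prob)))
}

#' Joint Wald test of a coefficient subset
#'
#' `W = m' S^{-1} m` with `m` the posterior mean vector and `S` the posterior
#' covariance of the named coefficients; `W` is referred to a chi-square
#' distribution with df = subset size.
#'
#' @param fit a `dyad_probit` fit or a draw matrix with named columns.
#' @param coefficients character vector (length >= 2) of coefficient names.
#' @return list `statistic`, `df`, `p.value`.
#' @export
wald_joint_test <- function(fit, coefficients) {
  sm <- if (inherits(fit, "dyad_probit")) fit$samples else as.matrix(fit)
  miss <- setdiff(coefficients, colnames(sm))
  if (length(miss)) stop("coefficients not in samples: ",
                         paste(miss, collapse = ", "))
  if (length(coefficients) < 2L) stop("need at least two coefficients")
  sub <- sm[, coefficients, drop = FALSE]
  m <- colMeans(sub)
  S <- stats::cov(sub)
  Si <- tryCatch(solve(S), error = function(e)
    stop("posterior covariance of the subset is singular"))
  W <- drop(t(m) %*% Si %*% m)
  df <- length(coefficients)
  list(statistic = W, df = df,
       p.value = stats::pchisq(W, df, lower.tail = FALSE))
}

#' Species-level hybridization propensities (BLUPs)
#'
#' Posterior means of the species and phylogenetic effects per species on the
#' probit liability scale, their sum (the propensity), and genus totals
#' ranked for a top-k listing.
#'
#' @param fit a `dyad_probit` fit with random effects.
#' @param genus_map optional named genus lookup; defaults to the genera of
#'   the fitted dyad table.
#' @param top_k genera to flag in the ranking.
#' @return list with `species` (data.frame: species, u_species, u_phylo,
#'   propensity, genus) and `genera` (genus, total propensity, rank),
#'   ordered by decreasing genus total.
#' @export
species_blups <- function(fit, genus_map = NULL, top_k = 5) {
  if (is.null(fit$blups)) stop("fit has no random effects")
  sp <- fit$blups
  if (is.null(genus_map)) {
    dd <- fit$design$dyads
    genus_map <- stats::setNames(c(dd$genus, dd$genus),
                                 c(dd$species_a, dd$species_b))
    genus_map <- genus_map[!duplicated(names(genus_map))]
  }
  sp$genus <- unname(genus_map[sp$species])
  gen <- stats::aggregate(propensity ~ genus, data = sp, FUN = sum)
  gen <- gen[order(-gen$propensity), , drop = FALSE]
  gen$rank <- seq_len(nrow(gen))
  gen$top <- gen$rank <= top_k
  rownames(gen) <- NULL
  list(species = sp, genera = gen)
}
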