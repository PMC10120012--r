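#' Prior specification for [dyad_probit()]
#'
#' Fixed effects get independent zero-mean Gaussian priors with variance
#' `v_B` (effectively flat at the default). Each variance component uses a
#' parameter-expanded prior: the effect is `alpha * eta` with
#' `eta ~ N(0, s2_eta K)`, `alpha ~ N(alpha_mu, alpha_V)` and
#' `s2_eta ~ IW(V, nu)` (univariate); the reported component is
#' `alpha^2 * s2_eta`. The residual variance is fixed at 1 and never sampled.
#'
#' @param v_B fixed-effect prior variance.
#' @param nu,V inverse-Wishart degrees of freedom and scale for the working
#'   variance (recycled to both components if length 1).
#' @param alpha_mu,alpha_V mean and variance of the working scale parameter.
#' @return list of class `dyad_prior`.
#' @export
dyad_prior <- function(v_B = 1e10, nu = 1, V = 1, alpha_mu = 0,
                       alpha_V = 1000) {
  stopifnot(v_B > 0, all(nu > 0), all(V > 0), all(alpha_V > 0))
  r2 <- function(x) rep_len(x, 2L)
  structure(list(v_B = v_B, nu = r2(nu), V = r2(V),
                 alpha_mu = r2(alpha_mu), alpha_V = r2(alpha_V)),
            class = "dyad_prior")
}

#' Build design matrices for the dyadic probit model
#'
#' Fixed effects: intercept, branch length, hectad overlap, genus size, two
#' life-history contrasts against the annual-annual baseline and (model 2
#' only) a homoploid contrast against the heteroploid baseline. The
#' multimembership incidence is returned as the two parental species column
#' indices per dyad, each with weight 1.
#'
#' @param dyads a `dyad_table`.
#' @param species_index character vector fixing the species column order;
#'   defaults to the sorted species appearing in `dyads`.
#' @param include_ploidy add the ploidy-match contrast (model 2); requires
#'   that no `unknown` ploidy rows remain.
#' @param standardize z-scale the three continuous covariates.
#' @return list with `y`, `X`, `ia`/`ib` (1-based parental indices into
#'   `species_index`), `species_index`, and `baselines` metadata.
#' @export
build_design <- function(dyads, species_index = NULL, include_ploidy = FALSE,
                         standardize = FALSE) {
  dyads <- as.data.frame(dyads)
  if (include_ploidy) {
    if (any(dyads$ploidy_match == "unknown"))
      stop("include_ploidy = TRUE but ", sum(dyads$ploidy_match == "unknown"),
           " dyads have unknown ploidy match; drop them first ",
           "(see subset_known_ploidy)")
  }
  # canonical row order so chains are invariant to input row order
  dyads <- dyads[order(dyads$genus, dyads$species_a, dyads$species_b), ,
                 drop = FALSE]
  if (is.null(species_index))
    species_index <- sort(unique(c(dyads$species_a, dyads$species_b)))
  ia <- match(dyads$species_a, species_index)
  ib <- match(dyads$species_b, species_index)
  if (anyNA(ia) || anyNA(ib))
    stop("dyads contain species absent from species_index")

  lh <- dyads$life_history_pair
  bad <- setdiff(unique(lh),
                 c("annual-annual", "annual-perennial", "perennial-perennial"))
  if (length(bad)) stop("unknown life_history_pair level: ",
                        paste(bad, collapse = ", "))
  zsc <- function(x) if (standardize) as.numeric(scale(x)) else x
  X <- cbind(
    `(Intercept)` = 1,
    branch_length = zsc(dyads$branch_length),
    hectad_overlap = zsc(dyads$hectad_overlap),
    genus_size = zsc(dyads$genus_size),
    `life_history_pairannual-perennial` = as.numeric(lh == "annual-perennial"),
    `life_history_pairperennial-perennial` =
      as.numeric(lh == "perennial-perennial"))
  if (include_ploidy)
    X <- cbind(X, ploidy_matchhomoploid =
                 as.numeric(dyads$ploidy_match == "homoploid"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix rank-deficient; offending column(s): ",
         paste(dropped, collapse = ", "),
         " (a factor level may be absent from the data)")
  }
  list(y = as.integer(dyads$hybridizes), X = X, ia = ia, ib = ib,
       species_index = species_index, dyads = dyads,
       baselines = c(life_history_pair = "annual-annual",
                     ploidy_match = "heteroploid"))
}

#' Run the Gibbs sampler on an explicit design
#'
#' Low-level fitting interface: latent-liability data augmentation for the
#' probit threshold model, a joint Gaussian block update of all location
#' effects from the mixed-model equations, and parameter-expanded variance
#' updates. [dyad_probit()] is the high-level wrapper; call this directly
#' for hand-built designs (e.g. a fixed-effects-only probit regression).
#'
#' @param y binary response vector.
#' @param X fixed-effect design matrix (named columns).
#' @param ia,ib 1-based parental species indices per row (both `NULL` for a
#'   fixed-effects-only model).
#' @param A phylogenetic covariance over the species index (required when
#'   `"phylo"` is in `random`).
#' @param random any of `"species"`, `"phylo"`; `character(0)` for none.
#' @param prior a [dyad_prior()].
#' @param n_iter,burnin,thin run length, burn-in, thinning.
#' @param seed integer seed.
#' @return list: `samples` (retained draws, fixed effects then variance
#'   components), `u_species`, `u_phylo` (posterior-mean effects),
#'   `n_kept`, `diverged`.
#' @export
gibbs_fit <- function(y, X, ia = NULL, ib = NULL, A = NULL,
                      random = character(0), prior = dyad_prior(),
                      n_iter = 10000, burnin = 2000, thin = 10, seed = 1L) {
  stopifnot(burnin < n_iter, thin >= 1, length(y) == nrow(X))
  use_s <- "species" %in% random
  use_p <- "phylo" %in% random
  S <- 0L
  Ainv <- matrix(0, 1, 1)
  if (use_s || use_p) {
    stopifnot(!is.null(ia), !is.null(ib), length(ia) == length(y),
              length(ib) == length(y))
    S <- max(ia, ib)
    if (use_p) {
      stopifnot(!is.null(A), nrow(A) >= S)
      Ainv <- chol2inv(chol(A[seq_len(S), seq_len(S), drop = FALSE]))
    }
  } else { ia <- ib <- rep(1L, length(y)); S <- 1L }
  set.seed(as.integer(seed))
  res <- .gibbs_probit_mm(
    as.integer(y), X, as.integer(ia - 1L), as.integer(ib - 1L),
    Ainv, S, use_s, use_p, prior$v_B,
    prior$nu[1], prior$V[1], prior$alpha_mu[1], prior$alpha_V[1],
    prior$nu[2], prior$V[2], prior$alpha_mu[2], prior$alpha_V[2],
    as.integer(n_iter), as.integer(burnin), as.integer(thin))
  if (isTRUE(res$diverged))
    warning("liability means exceeded 50 in absolute value: possible ",
            "complete separation; inspect trace plots")
  draws <- res$beta
  colnames(draws) <- colnames(X)
  vc <- NULL
  if (use_s) vc <- cbind(vc, sigma2_species = res$sigma2[, 1])
  if (use_p) vc <- cbind(vc, sigma2_phylo = res$sigma2[, 2])
  list(samples = cbind(draws, vc),
       u_species = if (use_s) as.numeric(res$u_species) else NULL,
       u_phylo = if (use_p) as.numeric(res$u_phylo) else NULL,
       n_kept = res$n_kept, diverged = isTRUE(res$diverged))
}

#' Drop dyads with unknown ploidy match
#' @param dyads a `dyad_table`.
#' @export
subset_known_ploidy <- function(dyads) {
  out <- dyads[dyads$ploidy_match != "unknown", , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(dyads)
  out
}

#' Fit the dyadic phylogenetic probit mixed model
#'
#' Bayesian probit ("threshold") regression of hybrid formation over
#' congeneric species pairs, with multimembership random effects: each dyad
#' receives the sum of its two parental species effects, once from an iid
#' species term (variance `sigma2_species`) and once from a phylogenetic term
#' (variance `sigma2_phylo`, covariance proportional to the tree covariance
#' A). Fitted by Gibbs sampling with latent-liability data augmentation,
#' joint block updates of all location effects through the mixed-model
#' equations, and parameter-expanded variance updates. The residual liability
#' variance is fixed at 1.
#'
#' @param dyads a `dyad_table` (see [build_dyads()]); rows are canonically
#'   re-sorted by (genus, species_a, species_b) before any random draw.
#' @param tree a `phylo` tree containing every dyad species (may be omitted
#'   when `random` excludes `"phylo"`).
#' @param include_ploidy fit model 2 (adds the homoploid contrast).
#' @param random random-effect terms to include; default both `"species"`
#'   and `"phylo"`. Use `character(0)` for a fixed-effects-only probit.
#' @param prior a [dyad_prior()].
#' @param n_iter,burnin,thin MCMC run length, burn-in and thinning. Defaults
#'   are test-scale; full-scale analyses use `n_iter = 1.3e6,
#'   burnin = 3e5, thin = 1e3`.
#' @param seed integer; fully determines the chain.
#' @param standardize z-scale the continuous covariates.
#' @param verbose print progress.
#' @return an object of class `dyad_probit`: posterior draw matrix
#'   (`samples`, columns = fixed effects then variance components), species
#'   BLUPs (`blups`), the genus-constrained dyad variance statistics
#'   (`stats`), design metadata and the run configuration.
#' @export
dyad_probit <- function(dyads, tree = NULL, include_ploidy = FALSE,
                        random = c("species", "phylo"),
                        prior = dyad_prior(),
                        n_iter = 10000, burnin = 2000, thin = 10,
                        seed = 1L, standardize = FALSE, verbose = FALSE) {
  stopifnot(inherits(prior, "dyad_prior"), burnin < n_iter,
            thin >= 1, n_iter >= 1)
  use_s <- "species" %in% random
  use_p <- "phylo" %in% random
  if (include_ploidy) dyads <- subset_known_ploidy(dyads)
  design <- build_design(dyads, include_ploidy = include_ploidy,
                         standardize = standardize)
  S <- length(design$species_index)

  stats <- NULL
  Ainv <- matrix(0, 1, 1)
  if (use_p) {
    if (is.null(tree)) stop("phylogenetic random effect requires a tree")
    rel <- phylo_covariance(tree)
    miss <- setdiff(design$species_index, rel$species)
    if (length(miss)) stop("dyad species absent from tree: ",
                           paste(miss, collapse = ", "))
    # marginal prior over the analysed species: invert the submatrix of A
    Asub <- rel$A[design$species_index, design$species_index, drop = FALSE]
    Ainv <- tryCatch(chol2inv(chol(Asub)), error = function(e) {
      warning("relatedness submatrix near-singular; adding 1e-10 jitter")
      chol2inv(chol(Asub + diag(1e-10, nrow(Asub))))
    })
    gm <- stats::setNames(design$dyads$genus, design$dyads$species_a)
    gm <- c(gm, stats::setNames(design$dyads$genus, design$dyads$species_b))
    gm <- gm[!duplicated(names(gm))]
    sub <- structure(list(A = Asub, species = design$species_index,
                          depth = max(diag(Asub)),
                          ultrametric = NA, A_inv = NULL),
                     class = "relatedness")
    stats <- dyad_variance_stats(sub, gm)
  }

  set.seed(as.integer(seed))
  t0 <- proc.time()[["elapsed"]]
  res <- .gibbs_probit_mm(
    as.integer(design$y), design$X,
    as.integer(design$ia - 1L), as.integer(design$ib - 1L),
    Ainv, S, use_s, use_p, prior$v_B,
    prior$nu[1], prior$V[1], prior$alpha_mu[1], prior$alpha_V[1],
    prior$nu[2], prior$V[2], prior$alpha_mu[2], prior$alpha_V[2],
    as.integer(n_iter), as.integer(burnin), as.integer(thin))
  elapsed <- proc.time()[["elapsed"]] - t0
  if (isTRUE(res$diverged))
    warning("liability means exceeded 50 in absolute value: possible ",
            "complete separation; inspect trace plots")

  draws <- res$beta
  colnames(draws) <- colnames(design$X)
  vc <- NULL
  if (use_s) vc <- cbind(vc, sigma2_species = res$sigma2[, 1])
  if (use_p) vc <- cbind(vc, sigma2_phylo = res$sigma2[, 2])
  samples <- cbind(draws, vc)

  blups <- NULL
  if (use_s || use_p) {
    blups <- data.frame(
      species = design$species_index,
      u_species = if (use_s) as.numeric(res$u_species) else 0,
      u_phylo = if (use_p) as.numeric(res$u_phylo) else 0,
      stringsAsFactors = FALSE)
    blups$propensity <- blups$u_species + blups$u_phylo
  }

  out <- structure(
    list(samples = samples, fixed_names = colnames(design$X),
         random = c(if (use_s) "species", if (use_p) "phylo"),
         blups = blups, stats = stats, design = design,
         include_ploidy = include_ploidy, prior = prior,
         config = list(n_iter = n_iter, burnin = burnin, thin = thin,
                       seed = seed, standardize = standardize),
         n_kept = res$n_kept, diverged = isTRUE(res$diverged),
         elapsed = elapsed, call = match.call()),
    class = "dyad_probit")
  if (verbose) print(out)
  out
}

#' @export
print.dyad_probit <- function(x, ...) {
  cat("Dyadic phylogenetic probit mixed model (threshold MCMC)\n")
  cat(sprintf("  %d dyads, %d species, model %s; random: %s\n",
              length(x$design$y), length(x$design$species_index),
              if (x$include_ploidy) "2 (with ploidy)" else "1",
              if (length(x$random)) paste(x$random, collapse = " + ")
              else "none"))
  cat(sprintf("  %d retained draws (n_iter %g, burn-in %g, thin %g, seed %s)\n",
              x$n_kept, x$config$n_iter, x$config$burnin, x$config$thin,
              x$config$seed))
  cat("  posterior means:\n")
  print(round(colMeans(x$samples), 4))
  invisible(x)
}

#' Summarize a fitted dyadic probit model
#'
#' Kernel-density posterior modes, means, 95% HPD intervals and pMCMC values
#' per fixed effect; variance-component summaries; the phylogenetic signal
#' (when the phylogenetic term is present); and the joint Wald test of the
#' two life-history contrasts.
#'
#' @param object a `dyad_probit` fit.
#' @param prob HPD mass.
#' @param ... unused.
#' @export
summary.dyad_probit <- function(object, prob = 0.95, ...) {
  sm <- object$samples
  fx <- object$fixed_names
  tab <- t(vapply(fx, function(cn) {
    x <- sm[, cn]
    h <- unname(hpd_interval(x, prob))
    c(post.mean = mean(x), post.mode = posterior_mode(x),
      lower = h[1], upper = h[2], pMCMC = pmcmc(x))
  }, numeric(5)))
  vcn <- setdiff(colnames(sm), fx)
  vtab <- NULL
  if (length(vcn))
    vtab <- t(vapply(vcn, function(cn) {
      x <- sm[, cn]
      h <- unname(hpd_interval(x, prob))
      c(post.mean = mean(x), post.mode = posterior_mode(x),
        lower = h[1], upper = h[2])
    }, numeric(4)))
  sig <- if ("sigma2_phylo" %in% colnames(sm) && !is.null(object$stats))
    phylo_signal(object) else NULL
  wald <- tryCatch(
    wald_joint_test(object, c("life_history_pairannual-perennial",
                              "life_history_pairperennial-perennial")),
    error = function(e) NULL)
  structure(list(coefficients = tab, variances = vtab, signal = sig,
                 wald_life_history = wald, prob = prob,
                 n_kept = object$n_kept, model = object),
            class = "summary.dyad_probit")
}

#' @export
print.summary.dyad_probit <- function(x, digits = 4, ...) {
  cat("Fixed effects (posterior mode, ", round(100 * x$prob),
      "% HPD, pMCMC):\n", sep = "")
  print(round(x$coefficients, digits))
  if (!is.null(x$variances)) {
    cat("\nVariance components (residual liability variance fixed at 1):\n")
    print(round(x$variances, digits))
  }
  if (!is.null(x$signal)) {
    cat(sprintf("\nPhylogenetic signal: mode %.3f (%.2f to %.2f %d%% HPD), B_bar_S = %.4g\n",
                x$signal$mode, x$signal$hpd[1], x$signal$hpd[2],
                round(100 * x$prob), x$signal$B_bar_S))
  }
  if (!is.null(x$wald_life_history)) {
    w <- x$wald_life_history
    cat(sprintf("\nJoint Wald test, life-history contrasts: chi2 = %.3f, df = %d, p = %.4g\n",
                w$statistic, w$df, w$p.value))
  }
  invisible(x)
}

#' @export
coef.dyad_probit <- function(object, type = c("mean", "mode"), ...) {
  type <- match.arg(type)
  sm <- object$samples[, object$fixed_names, drop = FALSE]
  if (type == "mean") colMeans(sm)
  else apply(sm, 2, posterior_mode)
}

#' @export
vcov.dyad_probit <- function(object, ...) {
  stats::cov(object$samples[, object$fixed_names, drop = FALSE])
}

#' Marginal posterior predictions of hybridization probability
#'
#' For each posterior draw the liability-scale linear predictor is divided by
#' the total liability standard deviation
#' sqrt(sigma2_u + 2 sigma2_s + sigma2_p * B_bar_S) (sigma2_u = 1) and mapped
#' through the standard normal CDF, marginalizing over the random effects.
#'
#' @param object a `dyad_probit` fit.
#' @param newdata data.frame with the covariate columns of the dyad table
#'   (`branch_length`, `hectad_overlap`, `genus_size`, `life_history_pair`,
#'   and `ploidy_match` for model 2). Defaults to the fitted dyads.
#' @param type `"response"` returns mode/mean/HPD summaries per row;
#'   `"draws"` the full draw-by-row matrix.
#' @param ... unused.
#' @export
predict.dyad_probit <- function(object, newdata = NULL,
                                type = c("response", "draws"), ...) {
  type <- match.arg(type)
  X <- if (is.null(newdata)) object$design$X
       else .row_design(object, newdata)
  sm <- object$samples
  beta <- sm[, object$fixed_names, drop = FALSE]
  s2s <- if ("sigma2_species" %in% colnames(sm)) sm[, "sigma2_species"] else 0
  s2p <- if ("sigma2_phylo" %in% colnames(sm)) sm[, "sigma2_phylo"] else 0
  Bs <- if (!is.null(object$stats)) object$stats$B_bar_S else 0
  sdtot <- sqrt(1 + 2 * s2s + s2p * Bs)
  eta <- beta %*% t(X)                      # draws x rows
  p <- stats::pnorm(eta / sdtot)
  if (type == "draws") return(p)
  t(apply(p, 2, function(col)
    c(mean = mean(col), mode = posterior_mode(col),
      hpd_interval(col, 0.95))))
}

# design row(s) for new covariate values, matching the fitted columns
.row_design <- function(object, newdata) {
  need <- c("branch_length", "hectad_overlap", "genus_size",
            "life_history_pair")
  if (object$include_ploidy) need <- c(need, "ploidy_match")
  miss <- setdiff(need, names(newdata))
  if (length(miss)) stop("newdata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (object$config$standardize)
    stop("predict with newdata is not supported for standardized fits")
  lh <- newdata$life_history_pair
  X <- cbind(`(Intercept)` = 1,
             branch_length = newdata$branch_length,
             hectad_overlap = newdata$hectad_overlap,
             genus_size = newdata$genus_size,
             `life_history_pairannual-perennial` =
               as.numeric(lh == "annual-perennial"),
             `life_history_pairperennial-perennial` =
               as.numeric(lh == "perennial-perennial"))
  if (object$include_ploidy)
    X <- cbind(X, ploidy_matchhomoploid =
                 as.numeric(newdata$ploidy_match == "homoploid"))
  X[, object$fixed_names, drop = FALSE]
}

#' @export
fitted.dyad_probit <- function(object, ...) {
  pr <- predict(object, type = "draws")
  colMeans(pr)
}

#' @export
residuals.dyad_probit <- function(object, ...) {
  object$design$y - fitted(object)
}

#' Simulate binary dyad outcomes from the posterior
#'
#' Each simulation picks a posterior draw and generates outcomes from the
#' marginal probit probability of every fitted dyad.
#'
#' @param object a `dyad_probit` fit.
#' @param nsim number of replicate outcome vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @export
simulate.dyad_probit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict(object, type = "draws")
  idx <- sample.int(nrow(p), nsim, replace = TRUE)
  out <- vapply(idx, function(i)
    as.integer(stats::runif(ncol(p)) < p[i, ]), integer(ncol(p)))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Trace and density plots for a fitted model
#' @param x a `dyad_probit` fit.
#' @param pars parameter names (default: all fixed effects and variances).
#' @param ... passed to [graphics::plot()].
#' @export
plot.dyad_probit <- function(x, pars = colnames(x$samples), ...) {
  pars <- intersect(pars, colnames(x$samples))
  old <- graphics::par(mfrow = c(length(pars), 2),
                       mar = c(2.5, 4, 1.5, 0.5))
  on.exit(graphics::par(old))
  for (pn in pars) {
    v <- x$samples[, pn]
    graphics::plot(v, type = "l", ylab = pn, xlab = "", ...)
    graphics::plot(stats::density(v), main = "", xlab = "")
  }
  invisible(x)
}
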