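#' Configuration for the synthetic flora generator
#'
#' Defaults describe a flora with the statistical structure the dyadic
#' analysis assumes: a pure-birth ultrametric phylogeny rescaled to unit
#' depth and cut into monophyletic genera at a fixed clade age, a
#' perennial-dominated life-history mix, genus-level ploidy pools with
#' occasional alternative cytotypes and partially missing ploidy records,
#' and hectad occupancies biased toward a per-genus home region so congeners
#' co-occur more than random species do.
#'
#' @param n_species tips of the simulated tree.
#' @param birth,death birth-death rates of the tree simulation.
#' @param genus_cut clade age (fraction of tree depth) below which a clade
#'   becomes a genus.
#' @param p_annual probability a species is annual.
#' @param ploidy_levels per-genus pool of cytotypes (base level first).
#' @param ploidy_mix probability a species takes the genus's alternative
#'   cytotype.
#' @param p_ploidy_known probability a species' ploidy is recorded.
#' @param n_hectads size of the hectad universe (cells of a square grid).
#' @param occupancy_meanlog,occupancy_sdlog log-normal occupancy (cells per
#'   species), capped at `n_hectads`.
#' @param home_bandwidth spatial decay (in grid cells) of the genus home
#'   region bias.
#' @param beta true fixed effects, named: intercept, branch_length,
#'   hectad_overlap, genus_size, the two life-history contrasts
#'   (annual-annual baseline) and the homoploid contrast (heteroploid
#'   baseline).
#' @param sigma2_species,sigma2_phylo true variance components of the
#'   liability model.
#' @return list of class `flora_config`.
#' @export
flora_config <- function(n_species = 200, birth = 1, death = 0,
                         genus_cut = 0.22,
                         p_annual = 0.3,
                         ploidy_levels = c(2L, 4L), ploidy_mix = 0.25,
                         p_ploidy_known = 0.7,
                         n_hectads = 2500,
                         occupancy_meanlog = log(300), occupancy_sdlog = 0.8,
                         home_bandwidth = 10,
                         beta = c(intercept = -2.4, branch_length = -1.0,
                                  hectad_overlap = 0.002, genus_size = 0,
                                  lh_annual_perennial = -0.4,
                                  lh_perennial_perennial = -0.2,
                                  ploidy_homoploid = 0.5),
                         sigma2_species = 0.5, sigma2_phylo = 0.3) {
  stopifnot(n_species >= 4, birth > 0, death >= 0, genus_cut >= 0,
            genus_cut < 1, length(beta) == 7, sigma2_species >= 0,
            sigma2_phylo >= 0)
  structure(as.list(environment()), class = "flora_config")
}

# Cut an ultrametric tree at a clade age: every edge spanning the cut roots
# a genus and the tips below it are its members. With cut_age < depth each
# tip lies under exactly one spanning edge.
.assign_genera <- function(tree, cut_age) {
  n_tip <- length(tree$tip.label)
  dist_root <- ape::node.depth.edgelength(tree)
  age <- max(dist_root[seq_len(n_tip)]) - dist_root   # time before present
  age[seq_len(n_tip)] <- 0                            # clamp fp noise at tips
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  span <- which(age[parent] > cut_age & age[child] <= cut_age)
  kids <- split(child, parent)
  genus <- integer(n_tip)
  gid <- 0L
  for (e in span) {
    gid <- gid + 1L
    stack <- child[e]
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v <= n_tip) genus[v] <- gid
      else stack <- c(stack, kids[[as.character(v)]])
    }
  }
  genus
}

#' Simulate a synthetic flora
#'
#' Generates an ultrametric birth-death phylogeny conditioned on
#' `n_species` tips (rescaled to unit depth), assigns monophyletic genera by
#' clade-age cutting, and draws species traits: life history, true ploidy
#' (with an observed version that may be missing), and hectad occupancy
#' biased toward a genus home region. Ground truth needed for parameter
#' recovery is returned alongside the data.
#'
#' @param config a [flora_config()].
#' @param seed integer seed; fully determines the flora.
#' @return list of class `synthetic_flora`: `tree` (`phylo`), `species`
#'   (`species_table`), `truth` (true ploidy per species, config echo).
#' @export
simulate_flora <- function(config = flora_config(), seed = 1L) {
  stopifnot(inherits(config, "flora_config"))
  set.seed(as.integer(seed))
  for (attempt in seq_len(100L)) {
    tree <- ape::rphylo(config$n_species, config$birth, config$death)
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length / depth
    tree$tip.label <- sprintf("sp%03d", seq_len(config$n_species))
    gid <- .assign_genera(tree, config$genus_cut)
    sizes <- table(gid)
    # genus_cut = 0 is the all-singleton boundary case; accept it as asked
    if (config$genus_cut == 0 || sum(sizes >= 2) >= 2) break
    if (attempt == 100L)
      stop("could not produce >= 2 multi-species genera in 100 attempts; ",
           "increase genus_cut or n_species")
  }
  genus <- sprintf("Gen%03d", gid)

  n <- config$n_species
  life <- ifelse(stats::runif(n) < config$p_annual, "annual", "perennial")

  # genus-level ploidy pools: base cytotype per genus, species may take the
  # alternative one
  glev <- unique(genus)
  base_pl <- stats::setNames(
    sample(config$ploidy_levels, length(glev), replace = TRUE), glev)
  alt_pl <- vapply(glev, function(g) {
    pool <- setdiff(config$ploidy_levels, base_pl[[g]])
    if (length(pool)) sample(pool, 1) else base_pl[[g]]
  }, numeric(1))
  true_ploidy <- ifelse(stats::runif(n) < config$ploidy_mix,
                        alt_pl[genus], base_pl[genus])
  known <- stats::runif(n) < config$p_ploidy_known

  # hectads on a square grid; genus home region biases occupancy
  side <- ceiling(sqrt(config$n_hectads))
  cells <- seq_len(config$n_hectads)
  cx <- (cells - 1) %% side; cy <- (cells - 1) %/% side
  home <- lapply(glev, function(g)
    c(stats::runif(1, 0, side), stats::runif(1, 0, side)))
  names(home) <- glev
  occ <- pmin(config$n_hectads,
              pmax(1, round(stats::rlnorm(n, config$occupancy_meanlog,
                                          config$occupancy_sdlog))))
  hectads <- vector("list", n)
  for (i in seq_len(n)) {
    h <- home[[genus[i]]]
    w <- exp(-sqrt((cx - h[1])^2 + (cy - h[2])^2) / config$home_bandwidth)
    hectads[[i]] <- sprintf("H%04d",
                            sample(cells, occ[i], prob = w))
  }

  species <- data.frame(species_id = tree$tip.label, genus = genus,
                        life_history = life,
                        has_barcode = TRUE, stringsAsFactors = FALSE)
  species$ploidy <- lapply(seq_len(n), function(i)
    if (known[i]) as.integer(true_ploidy[i]) else integer(0))
  species$hectads <- hectads
  class(species) <- c("species_table", "data.frame")

  structure(list(tree = tree, species = species,
                 truth = list(true_ploidy = stats::setNames(
                                as.integer(true_ploidy), tree$tip.label),
                              genus = stats::setNames(genus, tree$tip.label),
                              config = config, seed = seed)),
            class = "synthetic_flora")
}

#' @export
print.synthetic_flora <- function(x, ...) {
  gs <- table(x$species$genus)
  cat(sprintf("Synthetic flora: %d species, %d genera (%d with >= 2 species), max genus %d\n",
              nrow(x$species), length(gs), sum(gs >= 2), max(gs)))
  invisible(x)
}

#' Simulate hybridization outcomes on a dyad table
#'
#' Generative mirror of the fitted model: draws phylogenetic effects
#' `u_p ~ N(0, sigma2_phylo * A)` and species effects
#' `u_s ~ N(0, sigma2_species * I)`, builds each dyad's liability as
#' `x beta + u_s[a] + u_s[b] + u_p[a] + u_p[b] + e`, `e ~ N(0, 1)`, and
#' scores a hybrid where the liability exceeds 0. The ploidy covariate uses
#' the true cytotypes of the flora (the generative process knows them even
#' where the observed record is missing).
#'
#' @param flora a `synthetic_flora`.
#' @param dyads a `dyad_table` built from the flora.
#' @param seed integer seed for the outcome draw.
#' @return list: `dyads` (the table with `hybridizes` filled),
#'   `hybrids` (a `hybrid_table` of the positive dyads), `truth`
#'   (u_species, u_phylo, liabilities, beta, variance components).
#' @export
simulate_hybridization <- function(flora, dyads, seed = 1L) {
  stopifnot(inherits(flora, "synthetic_flora"))
  config <- flora$truth$config
  beta <- config$beta
  if (length(beta) != 7)
    stop("config beta must have 7 entries (intercept, 4 covariate terms, ",
         "2 contrasts)")
  set.seed(as.integer(seed))
  dyads <- dyads[order(dyads$genus, dyads$species_a, dyads$species_b), ,
                 drop = FALSE]
  rownames(dyads) <- NULL

  sp <- sort(unique(c(dyads$species_a, dyads$species_b)))
  keep <- ape::keep.tip(flora$tree, sp)
  A <- ape::vcv.phylo(keep)[sp, sp]
  S <- length(sp)
  u_p <- if (config$sigma2_phylo > 0)
    drop(crossprod(chol(A), stats::rnorm(S))) * sqrt(config$sigma2_phylo)
  else rep(0, S)
  u_s <- stats::rnorm(S, 0, sqrt(config$sigma2_species))
  names(u_p) <- names(u_s) <- sp

  tp <- flora$truth$true_ploidy
  homo <- as.numeric(tp[dyads$species_a] == tp[dyads$species_b])
  lh <- dyads$life_history_pair
  eta <- beta[["intercept"]] +
    beta[["branch_length"]] * dyads$branch_length +
    beta[["hectad_overlap"]] * dyads$hectad_overlap +
    beta[["genus_size"]] * dyads$genus_size +
    beta[["lh_annual_perennial"]] * (lh == "annual-perennial") +
    beta[["lh_perennial_perennial"]] * (lh == "perennial-perennial") +
    beta[["ploidy_homoploid"]] * homo
  liab <- eta + u_s[dyads$species_a] + u_s[dyads$species_b] +
    u_p[dyads$species_a] + u_p[dyads$species_b] +
    stats::rnorm(nrow(dyads))
  dyads$hybridizes <- as.integer(liab > 0)

  pos <- dyads[dyads$hybridizes == 1, , drop = FALSE]
  k <- nrow(pos)
  hybrids <- data.frame(
    parent1 = pos$species_a, parent2 = pos$species_b,
    origin_flag = rep("native-formed", k), rank_flag = rep("species", k),
    certainty_flag = rep("accepted", k), parent_count = rep(2L, k),
    intergeneric = rep(FALSE, k), cytotype1 = rep("", k),
    cytotype2 = rep("", k), stringsAsFactors = FALSE)
  class(hybrids) <- c("hybrid_table", "data.frame")

  list(dyads = dyads, hybrids = hybrids,
       truth = list(u_species = u_s, u_phylo = u_p, liability = liab,
                    linear_predictor = eta, beta = beta,
                    sigma2_species = config$sigma2_species,
                    sigma2_phylo = config$sigma2_phylo))
}
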