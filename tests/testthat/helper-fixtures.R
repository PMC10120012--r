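# Shared fixtures, all built in code.

empty_hybrid_table <- function() {
  df <- data.frame(parent1 = character(0), parent2 = character(0),
                   origin_flag = character(0), rank_flag = character(0),
                   certainty_flag = character(0), parent_count = integer(0),
                   intergeneric = logical(0), cytotype1 = character(0),
                   cytotype2 = character(0), stringsAsFactors = FALSE)
  class(df) <- c("hybrid_table", "data.frame")
  df
}

make_hybrids <- function(pairs, ...) {
  n <- length(pairs)
  df <- data.frame(parent1 = vapply(pairs, `[`, "", 1),
                   parent2 = vapply(pairs, `[`, "", 2),
                   origin_flag = "native-formed", rank_flag = "species",
                   certainty_flag = "accepted", parent_count = 2L,
                   intergeneric = FALSE, cytotype1 = "", cytotype2 = "",
                   stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  class(df) <- c("hybrid_table", "data.frame")
  df
}

make_species <- function(ids, genus, life = "perennial", ploidy = 2L,
                         hectads = NULL, barcode = TRUE) {
  n <- length(ids)
  df <- data.frame(species_id = ids, genus = rep_len(genus, n),
                   life_history = rep_len(life, n),
                   has_barcode = rep_len(barcode, n),
                   stringsAsFactors = FALSE)
  if (is.null(ploidy)) ploidy <- rep(list(integer(0)), n)
  if (!is.list(ploidy)) ploidy <- as.list(rep_len(as.integer(ploidy), n))
  df$ploidy <- ploidy
  if (is.null(hectads)) hectads <- rep(list("H1"), n)
  df$hectads <- hectads
  class(df) <- c("species_table", "data.frame")
  df
}

# 10-species / 3-genus fixture used by the dyad-builder and descriptives
# hand checks: GenA (4 annuals), GenB (3 perennials), GenC (2 mixed),
# GenD (1 singleton).  Two accepted hybrids: a1 x a2, b1 x b2.
fixture_flora <- function() {
  tree <- ape::read.tree(text = paste0(
    "(((a1:1,a2:1):1,(a3:1.5,a4:1.5):0.5):3,",
    "(((b1:0.5,b2:0.5):1,b3:1.5):2.5,((c1:1,c2:1):2,d1:3):1):1);"))
  species <- rbind(
    make_species(c("a1", "a2", "a3", "a4"), "GenA", life = "annual",
                 hectads = list(c("H1", "H2", "H3"), c("H2", "H3", "H4"),
                                c("H1"), c("H5"))),
    make_species(c("b1", "b2", "b3"), "GenB", life = "perennial",
                 ploidy = list(2L, 2L, 4L),
                 hectads = list(c("H1", "H2"), c("H1", "H2"), c("H9"))),
    make_species(c("c1", "c2"), "GenC", life = c("annual", "perennial"),
                 ploidy = list(2L, integer(0)),
                 hectads = list(c("H1"), c("H2"))),
    make_species("d1", "GenD", hectads = list("H1")))
  class(species) <- c("species_table", "data.frame")
  hybrids <- make_hybrids(list(c("a1", "a2"), c("b1", "b2")))
  list(tree = tree, species = species, hybrids = hybrids)
}

# fixture_flora plus a mixed-life-history genus GenE, sized so that
# genus_size is not collinear with the life-history contrasts
fixture_flora2 <- function() {
  fx <- fixture_flora()
  tree <- ape::read.tree(text = paste0(
    "((((a1:1,a2:1):1,(a3:1.5,a4:1.5):0.5):3,",
    "(((b1:0.5,b2:0.5):1,b3:1.5):2.5,((c1:1,c2:1):2,d1:3):1):1):0.5,",
    "((e1:1,e2:1):1,e3:2):3.5);"))
  species <- rbind(fx$species,
                   make_species(c("e1", "e2", "e3"), "GenE",
                                life = c("annual", "perennial", "perennial"),
                                hectads = list("H1", "H2", "H3")))
  class(species) <- c("species_table", "data.frame")
  list(tree = tree, species = species, hybrids = fx$hybrids)
}

# small simulated flora + outcomes + fit, computed once per test run
small_fit_cache <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    # moderate outcome rate keeps the variance components identifiable
    # (rare outcomes leave most genera all-zero; see vignette)
    cfg <- flora_config(n_species = 120)
    cfg$beta["intercept"] <- -1
    fl <- simulate_flora(cfg, seed = 104)
    dy <- build_dyads(fl$species, empty_hybrid_table(), fl$tree,
                      hectad_policy = "zero")
    sim <- simulate_hybridization(fl, dy, seed = 105)
    fit <- dyad_probit(sim$dyads, fl$tree, n_iter = 4000, burnin = 1000,
                       thin = 5, seed = 103)
    cache <<- list(flora = fl, dyads = sim$dyads, sim = sim, fit = fit)
    cache
  }
})

# random coalescent-style ultrametric tree with labelled tips
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rphylo(n, 1, 0)
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr
}

# brute-force cophenetic distance via root-to-tip path enumeration
brute_cophenetic <- function(tree) {
  n <- length(tree$tip.label)
  paths <- lapply(seq_len(n), function(tip) {
    # edges on the root-to-tip path
    e <- integer(0)
    node <- tip
    repeat {
      row <- which(tree$edge[, 2] == node)
      if (!length(row)) break
      e <- c(e, row)
      node <- tree$edge[row, 1]
    }
    e
  })
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- intersect(paths[[i]], paths[[j]])
    uniq <- c(setdiff(paths[[i]], shared), setdiff(paths[[j]], shared))
    d[i, j] <- d[j, i] <- sum(tree$edge.length[uniq])
  }
  d
}

# brute-force mean over enumerated within-genus dyads of A_aa + A_bb + 2 A_ab
brute_B_bar_S <- function(A, genus) {
  sp <- rownames(A)
  vals <- c()
  for (g in unique(genus)) {
    ids <- sp[genus == g]
    if (length(ids) < 2) next
    cmb <- utils::combn(ids, 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      vals <- c(vals, A[a, a] + A[b, b] + 2 * A[a, b])
    }
  }
  mean(vals)
}
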