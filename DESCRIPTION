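Package: phylodyad
Title: Dyadic Phylogenetic Mixed Models for Hybrid Formation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hybrid formation between congeneric species
    pairs (dyads) in a flora. Fits a probit ("threshold") generalized linear
    mixed model by MCMC with multimembership species and phylogenetic random
    effects, computes the dyad phylogenetic variance statistics (B-bar and its
    genus-constrained form) and the phylogenetic signal of hybridization on the
    liability scale, builds dyad tables from species, hybrid and phylogeny
    inputs with auditable exclusion filters, produces descriptive summaries
    (hybridization rates, life-history cross-tabulations, hybrid load,
    rank-sum distance comparisons), and simulates complete synthetic floras
    from the same generative model for testing and calibration.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
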