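# phylodyad

Dyadic phylogenetic mixed models for hybrid formation in floras.

Natural hybridization is recorded between particular pairs of congeneric
species, and whether a pair hybridizes depends jointly on pair-level factors
(genetic distance, range overlap, ploidy match, life histories) and on where
the parents sit in the phylogeny. `phylodyad` is for evolutionary botanists
and phylogenetic comparative biologists who want to analyse such data at the
scale of a whole flora: every unordered congeneric species pair (*dyad*)
becomes one observation, and the package fits a Bayesian probit
("threshold") mixed model with *multimembership* random effects — each dyad
receives the sum of its two parental species effects, once from an iid
species term and once from a phylogenetic term whose covariance is the tree
covariance matrix $A$.

The liability model for dyad $(a,b)$ is

$$\ell_{ab} = \mathbf{x}_{ab}'\boldsymbol\beta + u^{(s)}_a + u^{(s)}_b
  + u^{(p)}_a + u^{(p)}_b + \varepsilon_{ab},\qquad
  \varepsilon_{ab}\sim N(0,1),\qquad y_{ab} = \mathbb 1\{\ell_{ab} > 0\},$$

with $u^{(s)}\sim N(0,\sigma^2_s I)$ and $u^{(p)}\sim N(0,\sigma^2_p A)$,
fitted by Gibbs sampling with latent-liability data augmentation and
parameter-expanded priors. The phylogenetic signal of hybridization on the
liability scale is

$$\lambda=\frac{\sigma_p^2\bar B_S}{\sigma_u^2+2\sigma_s^2+\sigma_p^2\bar B_S},$$

where $\bar B_S$ — the genus-constrained mean over dyads of
$(A_{aa}+A_{bb}+2A_{ab})$ — rescales the species-level phylogenetic variance
onto the dyad scale. The package also builds the dyad table from species,
hybrid-record and phylogeny inputs (with the auditable exclusion filters a
hybrid flora needs), computes descriptive statistics (hybridization rates,
life-history cross-tabs, per-species hybrid load, Wilcoxon comparisons of
parental genetic distances), and simulates complete synthetic floras from
the same generative model.

## A worked example

Simulate a 200-species flora, build its congeneric dyad table, draw
hybridization outcomes from the generative model, and refit:

```r
library(phylodyad)

cfg <- flora_config(n_species = 200)
cfg$beta["intercept"] <- -1              # moderate hybridization rate
fl  <- simulate_flora(cfg, seed = 7)
dy  <- build_dyads(fl$species, hybrids = NULL, tree = fl$tree,
                   hectad_policy = "zero")
sim <- simulate_hybridization(fl, dy, seed = 8)
cat(sprintf("%d congeneric dyads, %.1f%% hybridizing\n",
            nrow(dy), 100 * mean(sim$dyads$hybridizes)))
fit <- dyad_probit(sim$dyads, fl$tree, n_iter = 10000, burnin = 2000,
                   thin = 10, seed = 9)
summary(fit)
```

```
556 congeneric dyads, 12.6% hybridizing
Fixed effects (posterior mode, 95% HPD, pMCMC):
                                     post.mean post.mode   lower  upper  pMCMC
(Intercept)                            -1.1027   -1.0129 -2.3747 0.0568 0.0650
branch_length                          -1.6099   -1.6445 -3.4308 0.1246 0.0750
hectad_overlap                          0.0022    0.0022  0.0009 0.0039 0.0025
genus_size                             -0.0321   -0.0336 -0.1108 0.0534 0.4425
life_history_pairannual-perennial      -0.1297   -0.2388 -0.8593 0.6780 0.7175
life_history_pairperennial-perennial    0.0191    0.0460 -0.8615 0.9486 0.9675

Variance components (residual liability variance fixed at 1):
               post.mean post.mode  lower  upper
sigma2_species    0.5879    0.4672 0.0987 1.1904
sigma2_phylo      0.1406    0.0257 0.0000 0.4797

Phylogenetic signal: mode 0.037 (0.00 to 0.49 95% HPD), B_bar_S = 3.716

Joint Wald test, life-history contrasts: chi2 = 0.467, df = 2, p = 0.7918
```

Reading the output: hybridization declines with parental branch length
(posterior mode −1.64 per unit of tree depth) and increases with range
overlap (+0.0022 per shared hectad, pMCMC 0.0025 — significant but tiny per
cell, as expected when overlaps run into the hundreds). The species variance
(0.47 at the mode, truth 0.5 in this simulation) and the phylogenetic signal
carry wide HPD intervals: a few hundred binary dyads say little about
variance components, a limitation discussed in the vignette. `coef()`,
`predict()` (marginal probabilities), `species_blups()` (probit-scale
propensities and genus rankings), `phylo_signal()`, `ploidy_effect()` (model
2), `pmcmc()` and `wald_joint_test()` expose the individual summaries;
`plot(fit)` draws traces.

A command-line interface wraps the same pipeline
(`exec/phylodyad simulate | build-dyads | fit | summarize | describe`),
reading/writing CSV, newick and JSON.

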