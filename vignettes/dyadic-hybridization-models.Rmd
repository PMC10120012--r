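---
title: "Dyadic phylogenetic mixed models for hybrid formation"
author: "phylodyad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dyadic phylogenetic mixed models for hybrid formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

The unit of analysis is the *dyad*: an unordered pair of congeneric species.
The response is binary — does a recorded hybrid exist with these two species
as parents? `phylodyad` models this with a probit ("threshold") generalized
linear mixed model. Each dyad $(a, b)$ has a latent Gaussian liability

$$
\ell_{ab} = \mathbf{x}_{ab}'\boldsymbol\beta
  + u^{(s)}_a + u^{(s)}_b + u^{(p)}_a + u^{(p)}_b + \varepsilon_{ab},
\qquad \varepsilon_{ab} \sim N(0, \sigma^2_u),
$$

and the pair hybridizes when $\ell_{ab} > 0$. The residual variance
$\sigma^2_u$ is fixed at 1 — with binary data only the scale-relative
parameters are identified, and fixing the residual anchors the probit scale.
The fixed effects are an intercept plus five covariates: pairwise branch
length (cophenetic distance on the dated phylogeny), hectad range overlap
(shared 10 km grid cells), genus size, the life-history combination of the
parents (three-level factor, annual–annual baseline) and — in model 2 only —
whether the parents share a ploidy level (homoploid vs the heteroploid
baseline).

The random structure is *multimembership*: every dyad receives the sum of
its two parental species effects, with incidence weight 1 for each parent.
There are two such terms per species:

* an iid species effect $u^{(s)} \sim N(0, \sigma^2_s I)$, capturing
  species-level hybridization propensity unrelated to the tree, and
* a phylogenetic effect $u^{(p)} \sim N(0, \sigma^2_p A)$, where
  $A_{ij}$ is the shared root-to-MRCA path length of tips $i$ and $j$ on
  the unscaled phylogeny. The model actually uses $A^{-1}$, the inverse
  relatedness matrix, as the prior precision (computed on the analysed
  species subset, so species outside the dyad table are marginalized out
  exactly).

## Dyad variance multipliers and the phylogenetic signal

Because each dyad sums two correlated species effects, the phylogenetic
variance reaching the dyad scale is
$\sigma^2_p\,(A_{aa} + A_{bb} + 2A_{ab})$. Averaging the bracket over a dyad
set gives a single multiplier: $\bar B$ over all species pairs
(equivalently $2\bar d + 2\bar o$ with $\bar d$ the mean diagonal and
$\bar o$ the mean pairwise covariance), and $\bar B_S$ over within-genus
pairs only — the set the model is actually fitted to. `dyad_variance_stats()`
computes both operationally as the mean of $(A_{aa}+A_{bb}+2A_{ab})$ over
the enumerated dyads, which is verified against brute-force enumeration in
the test suite; a species-count-weighted variant is reported as a diagnostic
only, because pooling per-genus means must weight by pair counts for the
pooled value to equal the dyad mean.

The phylogenetic signal of hybridization on the liability scale is

$$
\lambda = \frac{\sigma^2_p \bar B_S}
               {\sigma^2_u + 2\sigma^2_s + \sigma^2_p \bar B_S},
$$

computed per posterior draw and summarized by its kernel-density mode
(Gaussian kernel, Silverman bandwidth) and 95% highest-posterior-density
interval, the summary convention used throughout the package.

## Estimation

`dyad_probit()` runs a Gibbs sampler with latent-liability data
augmentation:

1. each liability is drawn from a normal with mean equal to the current
   linear predictor and variance 1, truncated below or above zero according
   to the outcome (inverse-CDF sampling, with an exponential-rejection
   fallback when the truncation point is more than five standard deviations
   into the tail);
2. all location effects $(\boldsymbol\beta, u^{(s)}, u^{(p)})$ are updated
   jointly from the mixed-model equations via a dense Cholesky
   factorization;
3. each variance component is updated through a parameter-expanded working
   parameterization $u = \alpha\eta$ with $\alpha \sim N(0, \alpha_V)$ and
   a conjugate scaled inverse-chi-square step for the working variance
   (defaults $V = 1$, $\nu = 1$, $\alpha_V = 1000$); the reported component
   is $\alpha^2\sigma^2_\eta$.

Fixed effects get zero-mean Gaussian priors with variance $10^{10}$,
effectively flat. Dyad rows are canonically sorted by
(genus, species_a, species_b) before any random number is drawn, so chains
are reproducible from the seed and invariant to input row order. The
default run length (10,000 iterations, burn-in 2,000, thinning 10) is the
test and exploration scale; full analyses of real floras use the
documented full-scale settings (1.3 million iterations, burn-in 300,000,
thinning 1,000), which are the defaults of the command-line `fit`
subcommand.

Summaries follow the conventions of the model class: kernel-density
posterior modes with 95% HPD intervals, two-sided `pmcmc()` values
$2\min\{P(\theta > 0), P(\theta < 0)\}$ (tail fraction floored at one draw),
a joint Wald test of the two life-history contrasts
($W = \mathbf m' S^{-1}\mathbf m$ against $\chi^2_2$, with $\mathbf m$ and
$S$ the posterior mean and covariance of the subset), and species-level
BLUPs — the posterior means of $u^{(s)}$ and $u^{(p)}$ — whose per-species
sum is the probit-scale hybridization propensity; `species_blups()` also
aggregates them to genus totals for top-k rankings. Both the phylogenetic
effect alone and the sum are reported, since either can be plotted as a
species-level propensity.

Marginal predictions divide the fixed-effect predictor by the total
liability standard deviation,
$p = \Phi\!\left(\mathbf{x}'\boldsymbol\beta \big/
\sqrt{\sigma^2_u + 2\sigma^2_s + \sigma^2_p \bar B_S}\right)$, using the
genus-constrained $\bar B_S$ throughout because only congeneric dyads enter
the model. The ploidy effect of model 2 is reported as the posterior of the
relative increase $p_\text{homo}/p_\text{hetero} - 1$ at mean branch
length, mean overlap, mean genus size and the reference life-history level;
the absolute difference is also returned because "more likely" is ambiguous
between the two.

## The synthetic flora generator

`simulate_flora()` emulates the data structure the analysis assumes: a
pure-birth ultrametric phylogeny conditioned on the species number and
rescaled to unit depth; monophyletic genera obtained by cutting the tree at
a fixed clade age (default 0.22 of tree depth, chosen so a 200-species
flora yields on the order of 600 congeneric dyads, the package's design
scale); a perennial-dominated life-history mix (30% annuals); genus-level
ploidy pools with occasional alternative cytotypes (25% mixing) and 70% of
species with recorded ploidy, which reproduces the model-1 to model-2
species reduction; and hectad occupancies (log-normal around 300 of 2,500
cells) biased toward a per-genus home region so congeners co-occur more
than random species pairs, as in real floras. `simulate_hybridization()` is
the exact generative mirror of the fitted model and returns the drawn
effects and liabilities as ground truth. The default fixed effects (a
negative branch-length coefficient, a weak positive overlap effect, a
positive homoploid contrast, intercept set for a hybridization rate near
8%) produce floras that resemble published national-flora hybrid surveys.

What the generator does not emulate: non-monophyletic genera (the dyad
builder tolerates them; the generator never produces them), sequence-level
variation (distances come from the tree), spatially explicit range
dynamics, and taxonomic error. Passing tests therefore demonstrate
correctness of the machinery under the model's own assumptions, not
robustness to violations of them.

## Calibration and the limits of identifiability

The recovery harness (`recovery_replicate()`) simulates at a generative
signal of $\lambda = 0.5$ ($\sigma^2_s = 0.5$,
$\sigma^2_p = 2/\bar B_S$ from each simulated tree) and refits the model.
Two empirical findings shaped its design, and both are worth knowing before
interpreting real-data fits:

* **Rare outcomes leave variance components weakly identified.** At
  hybridization rates below ~10%, most genera contain no hybridizing dyad.
  An all-zero genus is equally compatible with a moderately negative and an
  extremely negative group effect, so the likelihood for the variance
  components develops a long flat right ridge; posterior modes (and even
  maximum-likelihood estimates from an independent Laplace fit) inflate by
  an order of magnitude. This is a property of sparse binary mixed models,
  not of the sampler — the sampler reproduces its prior exactly in
  successive-conditional (Geweke-style) tests. The harness therefore
  simulates under null fixed effects, giving balanced outcomes, the regime
  in which $\lambda$ is identifiable at the 200-species scale. Real-flora
  analyses buy identification with an order of magnitude more dyads.
A related design note: because only within-genus pairs are analysed, branch
lengths span just a fraction of tree depth, so the generative-monotonicity
check (outcomes decline with parental branch length) is run with a strongly
negative coefficient (−4 per unit depth) — the flora default (−1) is too
weak to detect at a thousand dyads.

* **One flora is one draw of the phylogenetic effect.** The global
  component of $u^{(p)}$ shared by the whole flora is absorbed by the
  intercept, so marginal predictions centred on $E[u] = 0$ are biased for
  any single realization; they are calibrated in expectation over floras,
  which is how the package's calibration test asserts them. Conditional
  predictions that include the BLUPs track observed frequencies within a
  single flora.

## Numerical choices and degenerate inputs

Relatedness matrices are inverted by Cholesky; near-singular matrices
(duplicated tips, zero-length terminal branches) raise an error unless a
documented $10^{-10}$ diagonal jitter is requested. Liability means beyond
$\pm 50$ trigger a divergence warning (possible complete separation), and
non-finite means abort with the iteration index. Rank-deficient fixed-effect
designs are refused with the offending column named — with few genera,
genus size can be exactly collinear with the life-history contrasts.
Sequence distances use $\sqrt{1 - \text{identity}}$ with pairwise deletion
of gap and N positions, and return NaN when a pair shares no comparable
position. Rank-sum distance comparisons use exact enumeration when both
groups have at most 12 observations without ties, and the tie-corrected
normal approximation otherwise; the two branches agree to within 0.02 at
the boundary. Wilcoxon comparisons, not t-tests, are used for distances
because their distributions are strongly skewed. Divergence time between a
dyad is half the cophenetic distance, i.e. the MRCA node height on an
ultrametric tree.

## Problem sizes

The packaged tests run the full model at 120–200 species (roughly 200–600
dyads) with 10,000-iteration chains, and the recovery harness at 20
replicates of 200 species; these sizes were chosen as the smallest at which
the variance components are meaningfully identified while a complete run
stays in the minutes range on a single core. The same code paths scale to
full floras (a thousand species, several thousand dyads) by raising the
run-length settings to the full-scale defaults.
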