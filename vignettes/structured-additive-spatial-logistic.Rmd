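---
title: "Methods: Bayesian spatially structured additive logistic regression"
author: "spatstar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian spatially structured additive logistic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatstar)
```

## The problem

Surveys such as the Demographic and Health Surveys (DHS) record binary
health outcomes — here the running example is intimate partner violence
(IPV), "ever experienced emotional, physical or sexual violence by a
partner" — for individuals nested in small administrative areas
(districts). Two questions arise together: *which individual, partner and
household factors are associated with the outcome*, and *how does risk
vary over the map after adjusting for those factors*. Ignoring the spatial
dependence biases the covariate effects; ignoring the covariates confounds
the map. The structured additive regression (STAR) framework answers both
at once.

## The model

For individual $i$ in district $j$, $y_{ij}\mid p_{ij}\sim
\mathrm{Bernoulli}(p_{ij})$ with

$$\operatorname{logit}(p_{ij}) \;=\; \beta_0 + Z_{ij}'\theta +
f(x_{ij}) + f_{\mathrm{str}}(s_j) + f_{\mathrm{unstr}}(s_j),$$

where

* $Z_{ij}$ are dummy-coded categorical covariates (treatment contrasts,
  first level = reference) with coefficients $\theta$ reported as adjusted
  odds ratios $e^{\theta}$;
* $f(\cdot)$ is a penalised B-spline (P-spline) smooth of a continuous
  covariate (age in the running example): a cubic B-spline basis on
  equally spaced knots with a second-order difference penalty
  $\lambda^{-1} D_2'D_2$ acting as a random-walk prior on the basis
  coefficients. The `knots` argument counts equal-width segments of the
  data range, giving `knots + degree` basis functions;
* $f_{\mathrm{str}}$ is the spatially *structured* district effect with an
  intrinsic CAR (Besag) prior: precision $\tau_{\mathrm{str}}^{-2} K$,
  where $K = \mathrm{diag}(d) - A$ is the adjacency Laplacian of the
  district graph. Neighbouring districts are encouraged to have similar
  effects;
* $f_{\mathrm{unstr}}$ is the *unstructured* district effect,
  iid $N(0, \tau_{\mathrm{unstr}}^2)$, capturing district heterogeneity
  with no spatial organisation. The sum
  $f_{\mathrm{str}} + f_{\mathrm{unstr}}$ is the Besag–York–Mollié
  convolution.

Every variance component ($\tau^2_{\mathrm{spline}}$,
$\tau^2_{\mathrm{str}}$, $\tau^2_{\mathrm{unstr}}$) carries an
inverse-gamma $IG(a, b)$ hyperprior with $a = b = 0.001$, the historical
default of the structured additive regression software family; the
intercept and fixed effects get $N(0, 100)$ priors on the log-odds scale.
All of these are exposed in `star_spec()`.

The *structured share*
$\phi = \tau^2_{\mathrm{str}} / (\tau^2_{\mathrm{str}} +
\tau^2_{\mathrm{unstr}})$ summarises how much of the spatial variation is
spatially organised; `variance_decomposition()` reports it from the
posterior mean components (rounded to 0.1 of a percent) together with a
per-draw credible interval.

## Inference: Polya-Gamma Gibbs sampling

`fit_star()` samples the exact posterior by Gibbs with Polya-Gamma data
augmentation: given the linear predictor $\eta_i$, latent
$\omega_i \sim PG(1, \eta_i)$ renders the Bernoulli-logit likelihood
conditionally Gaussian, so all location parameters (fixed, spline, both
spatial blocks) are updated *jointly* from one multivariate normal full
conditional, followed by conjugate inverse-gamma updates of the variance
components. The PG(1, z) sampler is the exact alternating-series rejection
method; `rpg()` exposes it. This sampler targets the same posterior as the
iteratively-weighted-least-squares Metropolis scheme used by classical
STAR software but has rejection-free conditionals; the choice is a
deliberate implementation divergence.

Numerical and identifiability choices:

* **Centring.** The CAR field and each spline block are centred after
  every sweep (the spline via its fitted values, valid because the basis
  is a partition of unity) with offsets absorbed into the intercept. Every
  retained draw of $f_{\mathrm{str}}$ therefore sums to zero to machine
  precision. The unstructured effect keeps its proper prior and is not
  centred.
* **Ridge on improper blocks.** The intrinsic CAR and the difference
  penalty are rank deficient, and their null-space modes (e.g. the spline
  constant against the CAR constant) cancel exactly in the predictor. A
  fixed ridge of $10^{-6}$ on those prior blocks keeps the joint precision
  numerically nonsingular; the affected modes are re-centred out each
  sweep, so the ridge has no practical effect on identified quantities.
* **Canonical row order.** Records are sorted before sampling, so
  posterior summaries are exactly invariant to input row permutation
  under a fixed seed.
* **Divergence guard.** Draws with $|\eta| > 40$ are counted and reported
  as a warning but retained.
* **Defaults.** 12000 iterations, 2000 burn-in, thinning 10, 2 chains;
  convergence is summarised by split-$\widehat R$ and an
  autocorrelation-based effective sample size per parameter. These
  settings are this package's own defaults.
* **Survey weights** are *not* used in the Bayesian fit by default,
  matching the common practice of fitting the structured model to the
  survey-set sample unweighted; `use_weights = TRUE` switches to a
  weighted pseudo-likelihood, with non-integer-shape PG draws taken from a
  truncated (200-term, tail-mean-corrected) sum-of-gammas representation.

Model comparison uses the deviance information criterion,
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\bar\eta)$ evaluated
at the posterior mean linear predictor (`compute_dic()`).

## Survey descriptives

* `weighted_prevalence()`: Hajek ratio with Taylor-linearised variance
  over strata/PSUs and a **logit-transformed Wald** interval
  back-transformed to the proportion scale — the convention of DHS-style
  design-based software, and it keeps intervals inside $[0,1]$. Wilson or
  Clopper–Pearson intervals were deliberately not used; the method tag is
  recorded in the result. A stratum with a single PSU is an error naming
  the stratum unless the documented certainty-unit fallback is requested.
* `design_chisq()`: Pearson chi-square on the weighted table with the
  **first-order Rao–Scott** correction (a generalized design effect built
  from linearised cell/marginal design effects, with the
  simple-random-sampling reference variance $p(1-p)/(n-1)$ so that a
  trivial design gives exactly the classical statistic). The second-order
  correction was judged unnecessary for screening-level inference; this
  is a documented limitation.
* `screen_covariates()`: fits the *multivariable* conventional logistic
  model (base R `glm`, IRLS) on all candidates and keeps terms whose
  minimum Wald p across dummy levels is at most 0.2, plus an
  `always_keep` forcing list for literature-informed variables.
  Univariate p-values are computed alongside for transparency.

## Spatial statistics

`global_moran()` implements
$I = (n/S_0)\,\sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2$ with binary or
row-standardised weights and permutation inference; the two-sided
permutation p-value $(1 + \#\{|I^\ast| \ge |I|\})/(B+1)$ is the default
and both one-sided variants are always reported, because published Moran
p-values often do not state their sidedness. `local_moran()` gives the
LISA decomposition with conditional permutation (unit held fixed, the
rest shuffled over its neighbours) and HH/LL/HL/LH labels at a
configurable $\alpha$; no multiple-testing correction is applied by
default, with `p.adjust`-style correction left to the caller on the
returned p-values. Isolated districts get zero lag, $I_i = 0$ and label
NS by convention.

## The synthetic-data generator

Because the motivating microdata are restricted-access, every stage is
exercised on `simulate_survey()` output with known ground truth. The
ready-made `rwanda_like_config()` emulates the *structure* of the
2019/2020 Rwanda DHS domestic-violence subsamples:

* sample sizes 1947 (women) and 1371 (men); a 5 x 6 rook lattice standing
  in for the 30 districts nested in 5 regions (the real adjacency is not
  distributed with the survey; any `district_graph` can be supplied);
* categorical covariate marginals matching the published baseline table
  (e.g. 83.5% rural, 52.4% controlling partner for women);
* true effects equal to the log of the published adjusted odds ratios
  (women: controlling log 5.80, partner alcohol log 3.11, joint financial
  decisions log 0.52, wealth-quintile effects; men analogously);
* structured/unstructured district variances 0.132/0.074 (women) and
  0.130/0.211 (men), the published variance components; the structured
  field is drawn exactly from the intrinsic CAR density via the
  eigendecomposition of $K$ restricted to its row space, so it sums to
  zero by construction;
* an intercept calibrated deterministically (covariate-mixture
  enumeration plus quadrature over uniform age, `uniroot`) so the
  *expected* prevalence equals the published 45.9% / 18.4%; the small
  Jensen attenuation from the spatial field is ignored, so realised
  prevalence varies by a percentage point or two around the target;
* a mild quadratic age curve centred mid-range, amplitude 0.3 on the
  log-odds scale — an explicit stand-in, since the source analysis
  reports only a near-flat linearised age summary;
* equal survey weights by default, with an optional Gamma(4,4) weight
  model to exercise the weighted estimators; 5 strata of districts with
  10 PSUs each, and an optional completely-at-random missingness rate
  (downstream functions apply listwise deletion with a logged count).

What the generator does **not** emulate: the DHS two-stage cluster
sampling probabilities (strata/PSU columns exist to exercise design-based
variance code, not to mimic the real frame), informative missingness, the
real district adjacency, and any within-PSU correlation beyond what the
district effects induce. Passing tests on this generator therefore
demonstrate correctness of the estimators and sampler, not agreement with
the restricted data.

## Known limitations

* **CAR/iid weak identifiability.** The convolution prior identifies the
  *total* district effect much more strongly than its split: in internal
  checks at very large $n$ the fitted total spatial field correlates
  above 0.99 with truth while the component fields correlate around 0.7,
  and the posterior structured share $\phi$ can sit far from the
  generating share. This is a well-known property of the BYM
  parameterisation (scaled reparameterisations mitigate it but were out
  of scope); treat $\phi$ point estimates, here and in published
  analyses using this model family, with its per-draw interval.
* The Rao–Scott correction is first-order only; the weighted
  pseudo-likelihood PG draws are a truncated-series approximation.
* Quantile choropleth breaks follow `stats::quantile` type 7 with ties
  assigned to the lower bin; published maps with unknown binning can be
  matched only when their breaks are known.

## Problem sizes used by the test suite

The suite validates the sampler against dense-grid quadrature on 1- and
2-parameter models, recovers the women-configuration fixed effects over
10 replicate fits of 4000 iterations, checks DIC ordering over 20
replicates at $n = 500$, and checks permutation type-I error over 500
replicates on an 8 x 8 lattice — sizes chosen to give stable Monte Carlo
checks at interactive runtimes.
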