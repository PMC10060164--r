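---
title: "Model, sampler and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model, sampler and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`growthmeta` estimates mean height and BMI of children and adolescents
(ages 5–19) by country, year, sex, age and urban/rural residence from
heterogeneous study-level summary statistics. This vignette documents the
model, the numerical and design choices the package makes where more than
one reasonable option existed, what the synthetic-data generator does and
does not emulate, and the known limitations.

## The observation model

Each input row is a study × sex × single-year-age × stratum summary: a
mean `y`, its sample SD and size (or directly a design-based SE), the
study's coverage (national / subnational / community) and its stratum
(urban / rural / mixed with a known urban population fraction). The
likelihood is

$$ y \sim N\!\big(a_j + b_j \tilde t + u_{j,t} + \gamma_j(z) + X\beta +
   e_i + I_s\,[\,p_j + q_j \tilde t + r_j \tilde z + d_i\,],\;
   \mathrm{SD}^2/n + \tau^2\big). $$

The sampling variance enters as `SE²` (`= SD²/n` under simple random
sampling); when only SD and n are given the SE is computed, and when only
the SE is given the SD is back-filled for bookkeeping — the likelihood
needs the variance only.

**Timescales.** BMI is indexed by observation year. Height is indexed by
birth cohort (`year − age`), so trends follow successive cohorts;
participants measured at ages 20–30 inform age 19 of their own birth
cohort (adult height is non-decreasing relative to age 19 until the third
decade). The model time grid for height is therefore a grid of cohorts,
and a prediction cell (calendar year, age) maps to cohort `year − age`;
cells whose cohort falls outside the fitted grid are refused rather than
extrapolated.

**Centring.** Time is centred at the grid midpoint and expressed in
years; age at 12 years. The source model is only defined up to these
conventions (its intercepts absorb them); the package applies the same
constants in the generator, the fit and prediction so that truth and
estimate compare like with like.

## Time trends: linear + RW2

Nonlinear change is a second-order random walk: penalty `P = D2'D2`
with `D2` the second-difference operator, so the prior density is
proportional to `λ^{(T−2)/2} exp(−λ u'Pu/2)`. `P` has rank `T−2`; its
null space (constant and linear ramp) is exactly the part carried by the
hierarchical intercepts and slopes, so every `u` is constrained to zero
mean and zero least-squares slope. Smoothing precisions are ordered
`λ_c < λ_r < λ_s < λ_g` (countries may wiggle more than the globe) with
flat priors on the SD scale `1/√λ` truncated at `log λ ≤ 20`, at which
point the smooth is numerically indistinguishable from zero.

In the sampler the constraint is imposed by exact conditioning by
kriging, not by ad-hoc projection: after drawing from the unconstrained
Gaussian full conditional, the draw is corrected using the conditional
distribution given the two constraint functionals. Units with no data
use the Moore–Penrose pseudoinverse of `λP` (sampling in the row space
already satisfies both constraints); units observed at a single time
point have a rank-`T−1` conditional — the generalized inverse zeroes the
unidentified slope direction and the one-dimensional kriging correction
restores the mean constraint.

## Age curves

Truncated-power cubic bases ({z, z², z³, (z−k)₊³}) with sex/outcome
knots: girls' height 8, 10, 12, 14; boys' height 10, 12, 14, 16 (the
growth spurt comes roughly two years earlier in girls); BMI 10 and 15.
Two numerical choices matter:

* columns are scaled to unit maximum absolute value on the reference
  grid (ages 5–19) for conditioning;
* columns are then centred to zero mean on that grid. Without this the
  basis can approximate a constant to within 0.03, leaving the split of
  the overall level between intercepts and spline coefficients on a
  near-flat likelihood ridge; with it the level is identified and
  carried by the intercepts alone. This is the same sum-to-zero
  identifiability constraint smoothing packages apply. It is a pure
  reparameterization: fitted curves are unchanged.

The basis needs more distinct ages in the data than coefficients
(7 for height, 5 for BMI, plus the constant); with fewer, the global
spline block is reported as unidentified rather than silently
regularized.

## Urban and rural strata

The centred indicator `I = −1 + 2X_urb` makes an unstratified (mixed)
observation the urban-fraction-weighted sum of the two stratum means, so
mixed data inform the level while stratified data (and the hierarchy)
inform the gap. The urban–rural difference at a cell is
`2(p_j + q_j t̃ + r_j z̃)`. The study-level deviations `d_i` share a
single SD hyperparameter (flat on SD): the source describes `d` as
analogous to `e` without stratifying its variance by coverage, and a
single class keeps the parameter identified at realistic study counts.

## Sampler design

The update scheme is Metropolis-within-Gibbs with a fixed scan
(location blocks top-down, RW2 smooths, coverage effects, study effects,
recentring moves, variance updates); a shuffled-scan mode exists for
sensitivity checks. Choices that were genuinely open:

* **Exact Gaussian block conditionals** for all location parameters
  maximize testability: each block is checkable against closed forms,
  and with all variance hyperparameters fixed the entire model is linear
  Gaussian, so the whole sampler is checkable against a dense exact
  posterior (this is one of the tests).
* **Joint per-unit blocks.** Each hierarchy unit's intercept, slope,
  urban-offset terms and spline deviations are drawn as one block.
  Mixed-stratum data make a country's intercept and urban offset
  strongly correlated (only `a + Ī p` is well identified when most of
  its data are mixed); partial age coverage correlates intercept and
  spline. One-at-a-time blocks random-walk along these ridges.
* **Recentring sweeps.** The additive hierarchy `x_j = x^c + x^r + x^s +
  x^g` is translation-redundant; a constant moved between a parent and
  its children leaves the likelihood unchanged, so its full conditional
  is a cheap priors-only Gaussian. These moves (including global level
  vs study effects, and global urban offset vs `d`) are exact Gibbs
  updates on the redundant directions.
* **Funnel handling for variances.** The study-effect SDs are updated
  with the effects integrated out analytically (then the effects are
  redrawn — a valid blocked update); the hierarchical SDs additionally
  get ASIS interweaving (a non-centred rescaling proposal accepted by
  likelihood ratio). Without these, chains stall in low-SD/low-effect
  corners of the funnel.
* **Constraints by rejection.** The orderings (`λ`'s, `v`'s) and the
  `log λ ≤ 20` truncation are enforced by rejecting violating proposals
  — simple, and it respects the a-priori orderings exactly.
* **Burn-in and chain selection.** The original workflow judged burn-in
  visually; the package discards a fixed fraction (default: first half)
  and provides an automated stationarity screen of the log-likelihood
  trace (first- vs second-half mean difference below `tol = 0.2` SDs,
  configurable) to drop chains that converged late, plus split R-hat
  for quantities of interest.
* **Priors not stated in the source:** flat on `τ` (same Metropolis
  machinery); flat on the global location parameters. The flat-on-SD
  hierarchical priors are improper and need at least two children per
  hierarchy level for a proper posterior; the fit refuses to run
  otherwise, and coverage classes with fewer than two studies keep
  their initial study-effect SD (with a warning) instead of sampling an
  improper conditional.
* **Starting values** are deterministic pooled least squares for the
  locations and overdispersed random draws for the SDs, so chains start
  from distinct hyperparameter states as a convergence stress test.

## The synthetic world

`gmr_world_spec()` / `generate_world()` draw every parameter of the
model from its prior at configurable SDs/precisions, giving a ground
truth against which recovery can be scored exactly. Defaults and why:

* **Scale:** 3 super-regions × 2 regions × 3 countries (18 countries),
  31 time points, ages 5–19 — the smallest scale at which every level
  has at least three children (so the improper flat-SD priors are
  comfortably proper) while a full fit still runs in minutes.
* **Study composition:** 21% of studies mixed (unstratified), the share
  reported for the real database; the remainder split evenly between
  urban-only and rural-only. Coverage defaults 60/25/15%
  national/subnational/community.
* **Noise:** study-effect SDs 0.2 / 0.5 / 1.0 (national < subnational <
  community), urban-offset study SD 0.2, residual age-by-study SD 0.3,
  within-age sample SD ≈ 6.5 cm (height) or 3 kg/m² (BMI) — plausible
  magnitudes for anthropometric surveys.
* **Age curves:** global coefficients are fitted to a stylized growth
  curve whose pubertal spurt peaks about two years earlier for girls,
  with small hierarchical deviations; all configurable.
* **Timescale:** the generator works directly on the model timescale
  (one time index per study). The measurement-year → birth-cohort
  mapping is exercised separately by `assign_time_index()` and by
  cohort-indexed prediction, so the generator does not re-derive it.
* **RNG:** one root seed with per-purpose child streams (world, studies,
  sampler), so regenerating one layer never perturbs another.

The generator deliberately does **not** emulate survey non-response,
self-report bias, migration, or urban reclassification — features of
real data the source excludes or does not model. Passing recovery tests
therefore demonstrates that the estimation machinery is correct and
well calibrated under the model's own assumptions, not that the model is
robust to violations of them.

## Validation strategy and problem sizes

All tests run on synthetic data built in code. The main suites:

* analytic checks of the penalty matrix against the printed construction
  and a brute-force crossproduct;
* oracle equivalences: weighted PAVA vs exhaustive partition enumeration
  (all sequences of length ≤ 6 with values in {0..3}) and `isoreg`;
  RW2 log density vs a dense eigenbasis normal; Gaussian conditionals vs
  weighted least squares and the normal-normal closed form (conditional
  means extracted exactly via RNG-matched linearity); the flat-on-SD
  Metropolis vs a 10⁶-point quadrature (KS < 0.02); Taylor-linearized
  SEs vs the SRS closed form and a 10⁴-replicate Rao–Wu cluster
  bootstrap;
* an exact dense linear-Gaussian posterior comparison of the full
  sampler with all hyperparameters fixed (8 countries, 30 studies);
* parameter recovery on the default 18-country world with 120 studies,
  3 chains × 3,000 iterations: pooled 95% CrI coverage of the country
  intercepts, slopes and urban offsets within binomial tolerance of
  nominal, and posterior-mean urban–rural gaps correlating with truth
  at r > 0.9;
* simulation-based calibration (40 replicates on an 8-country BMI world,
  hyperparameters fixed at truth): the flat improper SD priors cannot be
  sampled, so SBC conditions on the variance hyperparameters and
  validates the Gaussian machinery; rank uniformity is tested at
  α = 0.01. The variance updates are covered by the quadrature and
  dense-posterior oracles instead.

Problem sizes (18 countries, 120 studies, 3 × 3,000 iterations; 40 SBC
replicates at 8 countries × 25 studies × 360 iterations) were chosen so
the full suite completes in minutes on a single core while leaving the
statistical assertions well powered; they are scaled-down analogues, not
reproductions, of the production-scale campaign (35 chains × 75,000
iterations on ~2,300 studies), which the package supports but does not
test.

## Known limitations

* Estimation of the hierarchical SDs at 18 countries is weakly
  informed; data-poor countries' urban offsets are shrunk accordingly,
  and their credible intervals depend on how well those SDs are
  estimated.
* The conversion from BMI-category prevalences to mean BMI is an
  interface with user-supplied coefficients; the validated regression
  coefficients live outside the package and no default is shipped.
* Real-database features (duplicate resolution, manual data checks,
  WHO standard-population weights, UN urban-fraction shares) are
  consumed as inputs, not reproduced; uniform age weights are the
  testing default.
* The interval estimates are conditional on the model: monotonized
  (PAVA) height trajectories are computed per posterior draw so CrIs
  remain coherent with the monotonized quantity (a posterior-mean-only
  mode exists via `apply_pava` on summaries), but no allowance is made
  for model misspecification.
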