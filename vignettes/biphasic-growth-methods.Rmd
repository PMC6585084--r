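---
title: "Methods: biphasic growth and zero-inflated behaviour models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: biphasic growth and zero-inflated behaviour models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the growth and
behaviour models it implements, the estimation machinery behind them, the
synthetic-data generator used to validate everything, and the numerical
and design choices a maintainer should know about.

## The biphasic growth model

The model describes standard length (mm) against age (days post-hatch,
dph) in two phases joined continuously at the age at maturation `a_mat`.
Its premise is energetic: the maximal potential growth rate scales
allometrically with wet weight, dW/dt = c W^β, and weight scales with
length as W = b L^α. Before maturation all surplus energy goes to soma;
integrating the weight ODE and converting through the allometry gives the
juvenile curve

L_a = (L0^k + H a)^(1/k),  k = (1 − β) α,  H = c (1 − β) b^−(1−β).

After maturation a constant fraction of surplus energy is allocated to
reproduction at rate `r` per day, which discounts each day's growth on the
transformed scale x = L^k by the factor R = 1 / (1 + (1 − β) r); iterating
x(a+1) = R (x(a) + H) from x(a_mat) yields the closed-form adult curve and
its asymptote (R H / (1 − R))^(1/k). The somatic–gonadic conversion factor
is fixed at 1 and not exposed. Two analytic facts are exploited in code
and checked in the tests: the two phases meet exactly at `a_mat`, and as
r → 0 the adult curve degenerates to the juvenile one. The r = 0 case is
evaluated by the analytic limit (the geometric sum (1 − R^d)/(1 − R) → d),
switching when 1 − R < 1e−12, never through the 1/(1 − R) singularity.

One caveat documented rather than "fixed": the model only grows
monotonically while length at maturation lies below the adult asymptote.
For parameter combinations with large `r`, low `β` and late `a_mat` —
far outside the region the data occupy — the adult phase approaches its
asymptote from above, i.e. predicts shrinkage. The monotonicity test
therefore probes the published parameter region, not arbitrary parameter
space.

### Parameters, units, defaults

| Parameter | Meaning | Unit | Default/fixed |
|---|---|---|---|
| `a_mat` | age at maturation | dph | estimated |
| `r` | reproductive investment rate | day⁻¹ | estimated |
| `beta` | exponent of dW/dt = c W^β | — | estimated, in (0, 1) |
| `c` | coefficient of dW/dt = c W^β | mg^(1−β) day⁻¹ | fixed 0.15 |
| `L0` | hatch length | mm | fixed 4.0 |
| `alpha`, `b` | W = b L^α allometry | —, mg mm^−α | pre-estimated (2.7, 0.04) |

`c` is held fixed because it is nearly confounded with `β` in this design;
0.15 is the species-appropriate value for medaka. `fit_growth()` exposes
`c` so sensitivity runs (±10%) are one-liner loops. The allometry is
estimated by OLS of log W on log L pooled over sexes and treatments
(`fit_allometry()`), before and independently of the growth fit, with no
retransformation bias correction on b = exp(intercept). The hatch length
is pre-estimated from the 0-dph photograph subsample (`estimate_L0()`,
with one-way F-tests for sex and line differences); the model constant
defaults to 4.0 mm and is a configuration value, deliberately not wired to
the raw pooled mean.

## Nonlinear mixed-effects estimation

`fit_growth()` fits the curve by maximum likelihood (not REML, since AIC
comparisons vary the fixed effects) via `nlme::nlme`. Design choices:

* **Treatment effects on the natural scale.** Line, food and their
  interaction enter additively on `a_mat`, `r`, `β` themselves, with
  treatment contrasts referenced to large-selected × high food. This makes
  the coefficient table directly interpretable as day/rate/exponent
  differences and group values simple coefficient sums. The optimiser is
  unconstrained; with sane starting values the estimates stay inside the
  scientifically valid region, and the per-group parameter table is
  invariant-checked in the tests.
* **Random effects.** Individual Gaussian intercepts on β (females) or on
  r and β (males), diagonal covariance (`pdDiag`) — per-parameter SDs,
  no cross-correlation parameter.
* **Residual correlation.** ARMA(0,2) over consecutive measurement
  occasions within fish, positional rather than calendar-gap-based (so the
  female 14-day and male 21-day schedules are treated alike). The reported
  `sigma` is the marginal residual SD: the covariance is the banded
  Toeplitz matrix with lag-0 σ², lag-1 σ²s(θ₁ + θ₁θ₂), lag-2 σ²sθ₂,
  s = 1/(1 + θ₁² + θ₂²), implemented in `ma2_covariance()` and
  cross-checked against `nlme::corARMA` and brute simulation.
* **Starting values.** Two stages per treatment group: crude values from
  the group mean trajectory (β from the juvenile log–log slope of growth
  rate on weight, `a_mat` from the sharpest drop in length increments,
  r = 0.01), refined by a Levenberg–Marquardt fit of the curve to the
  group's data; group values are then mapped to the coefficient basis by
  group-size-weighted least squares. This makes the mixed-model fit start
  within a few percent of the optimum and converge in seconds.
* **Inference surface.** Coefficient SEs, df, t and p values are taken
  from the `nlme` machinery; AIC = −2 logLik + 2k is asserted exactly in
  the tests.

With an empty random-effect spec the same interface drops to `nlme::gnls`
(and, with the correlation also disabled, to plain nonlinear least
squares), which is used as a collapse check against an independent
`minpack.lm` fit.

The package additionally ships `marginal_loglik()`, a deterministic
Laplace evaluator of the marginal likelihood (per-fish conditional mode by
bounded quasi-Newton search, finite-difference curvature). It is the
validation tool — tested against 50-node Gauss–Hermite quadrature and
adaptive numerical integration on single-fish problems, and against the
exact Gaussian log-likelihood when the random-effect SDs are zero — not
the production optimiser. The quadrature toy uses a small random-effect SD
(τ = 0.01) and a moderate residual SD so that the posterior is
near-Gaussian and the prior-scaled quadrature grid resolves it; with a
sharply likelihood-dominated posterior a fixed 50-node grid is itself the
larger error source.

### Structure selection

`aic_select()` fits any candidate set — `growth_spec_lattice()` generates
the full 5 × 5 × 5 = 125 combinations of {1, line, food, line + food,
line × food} on the three parameters — and returns the minimum-AIC fit;
failed fits are kept in the table with infinite AIC, and ties closer than
1e−6 break towards fewer parameters. `backward_eliminate()` then drops
non-significant terms (p ≥ 0.05) one at a time, largest p first,
respecting marginality (interactions before their main effects), refitting
after each removal — the published workflow applies this to the male
model.

## Zero-inflated behaviour models

Bite counts and freezing seconds (integer counts within a 300-s assay) are
modelled with `glmmTMB` as NB2 zero-inflated mixed models: a logit-linear
zero part (treatment effects only) and a log-linear count part with
treatment effects plus three Gaussian random intercepts — fish identity,
test session within fish, and assay condition. Decisions worth recording:

* "Session within fish" interprets the nested measurement effect as the
  replicate assay day (two per fish, three observations each). An
  observation-level intercept would be unidentifiable next to the NB
  dispersion; the session level is identifiable and matches the
  replicated-condition design.
* Zero-part random effects are deliberately omitted; the zero part is
  fixed-effects only.
* The condition intercept has only three levels, so its SD is estimated
  with little information; it is retained for structural fidelity, and
  boundary collapses (SD ≈ 0) are flagged, not treated as errors.
* Freezing is bounded at 300 s by the assay window, but the NB is not
  truncated — matching the analysis convention, and with the default
  generator settings P(Y > 300) ≈ 0.3%, so the mismatch is negligible.
* Dispersion uses the mean/dispersion (NB2) parameterisation,
  Var = μ + μ²/k.

`zinb_pmf()` implements the mixture pmf directly (tested for
normalisation and its Poisson and point-mass limits — the Poisson-limit
check runs at k = 1e8, where the O(y²/k) deviation is inside a 1e−6
tolerance). `aic_select_zinb()` mirrors the growth selection over the
25-candidate count × zero lattice. `zero_fraction_check()` is a
posterior-predictive diagnostic: the fraction of model simulations whose
zero count falls within ±2% of observations of the observed zero count.
`repeatability_icc()` reports latent-scale repeatability,
fish variance / (fish + session + condition + distribution variance),
with the lognormal approximation log(1 + 1/μ̄ + 1/k) for the
distribution-level term.

## The synthetic-data generator

`synth_config()` encodes the study design as defaults: 143 female growth
trajectories (39/36/28/40 across large/small line × high/low food)
measured every 14 d from 14 dph plus a final occasion at 180 dph; 116
males (19/41/20/36) every 21 d; hatch subsamples of 25/22 fish at 0 dph
drawn N(3.9, 0.4²) mm; behaviour assays (3 conditions × 2 replicates) on
80 females and 107 males, allocated to treatment groups proportionally to
the growth design (the study does not break the assay sample down).
Per-group generating values for `a_mat`, `r`, `β` are the published
point estimates; weights are derived through the (2.7, 0.04) allometry
with lognormal noise (log-SD 0.1) and are missing at the photograph-based
occasions (14 and 28 dph).

The unpublished noise components are calibration choices, fixed once and
exposed in the config: individual SD 0.02 on β (both sexes) and 0.003 on
r (males, where r carries a random effect), marginal residual SD 0.5 mm
with MA(2) coefficients (0.3, 0.1) — together giving a trajectory spread
comparable to the raw-data envelope — and behaviour random-intercept SDs
(0.4 fish, 0.2 session, 0.2 condition on the log scale) with dispersions
k = 1.2 (bites) and 0.8 (freezing). Zero-part intercepts are calibrated so
the realized zero fractions match the reported rates (≈33% female bites,
≈49% male bites, ≈52% freezing); zero- and count-part treatment effects
use the published contrasts (e.g. zero-part line log-odds log 2.4 for
female bites, count-part line effect −0.43 for male freezing). Individual
`r` draws are floored at zero (a 2.7-SD event for the male low-food
groups).

What the generator does *not* emulate: mortality and dropout (all fish
complete all occasions), the ten-generation selection process itself,
measurement rounding and handling effects, any age-dependence of the
residual SD, and correlation between a fish's growth and its behaviour.
Passing recovery tests therefore demonstrate that the estimation machinery
inverts the assumed data-generating process at the study's size and noise
level — not that the original data satisfy those assumptions.

## Validation experiments and problem sizes

The recovery experiments (`recover_growth()`, `recover_behavior()`)
simulate each published design at its generating values across 20 seeded
replicates, refit the published model structure, and compare median
estimates against the truth within ±2 published SEs; `scripts/acceptance.R`
runs exactly this and writes the medians as JSON (about a minute on one
CPU). Unit-level Monte-Carlo checks (AIC detecting a true interaction,
backward elimination removing a null term, structure selection, ICC
recovery) run on reduced designs — typically 8–12 fish per group and 8–10
replicates — which keeps the whole suite in a few minutes while still
giving clear majorities; the full-size experiments live in the acceptance
tests.

## Known limitations

* Estimates are unconstrained on the natural scale; for data far noisier
  than the design envelope, group parameters could in principle leave
  their domains (the fit flags rather than forbids this).
* The MA(2) structure is positional; irregular measurement schedules with
  missing occasions are treated as consecutive.
* No REML, no general ARMA(p,q), no bootstrap intervals, no alternative
  growth families (von Bertalanffy, Gompertz) — deliberately out of scope.
* Real experimental data can be analysed by mapping their tables to the
  `fish_id`/`line`/`food`/`age`/`length` (and behaviour) schemas and
  passing them to `run_fit_growth()` / `run_fit_behavior()`; the package
  does not download or bundle any dataset.
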