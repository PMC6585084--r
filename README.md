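# biphasr

Life-history and behaviour analysis for size-selected medaka (*Oryzias
latipes*) reared under high or low food availability: biphasic growth
modelling by nonlinear mixed-effects, and zero-inflated count models for
feeding and boldness assays. The package is aimed at researchers analysing
longitudinal fish length-at-age data from selection or feeding experiments,
and ships a synthetic-data generator that emulates the full experimental
design so every stage of the pipeline can be validated by
parameter-recovery simulation without access to the original data.

## The models

**Growth.** Somatic growth follows the Quince–Boukal biphasic
energy-allocation model. Maximal potential growth scales allometrically
with weight, dW/dt = c W^β, and weight relates to standard length through
W = b L^α. Juveniles allocate all surplus energy to growth; writing
k = (1 − β)α and H = c(1 − β) b^−(1−β), length at age *a* (days post-hatch)
is

    L_a = (L0^k + H a)^(1/k)                        (juvenile, a ≤ a_mat)

After maturation at age a_mat a constant reproductive investment *r* per
day discounts growth by R = 1 / (1 + (1 − β) r):

    L_a = (R^(a−a_mat) (L0^k + H a_mat)
           + R H / (1 − R) (1 − R^(a−a_mat)))^(1/k)   (adult, a > a_mat)

The two phases join continuously at a_mat and adult length approaches the
asymptote (R H / (1 − R))^(1/k) = (c b^−(1−β) / r)^(1/k). The parameters of
interest — a_mat, r and β — are estimated per sex by maximum-likelihood
nonlinear mixed-effects (`nlme`), with selection line, food and their
interaction as additive fixed effects on the natural parameter scale,
individual Gaussian random effects (on β for females; on r and β for
males), and an MA(2) correlation structure over consecutive within-fish
measurement occasions. The allometry (α, b), the growth coefficient
c = 0.15 and the hatch length L0 = 4.0 mm are pre-estimated/fixed before
the nonlinear fit. Fixed-effect structures are compared by AIC over the
full 125-model lattice, with optional backward elimination of
non-significant terms.

**Behaviour.** Bite counts and freezing seconds (5-minute assays, three
conditions, two replicates per fish) are modelled as zero-inflated negative
binomial (NB2) mixed models via `glmmTMB`: a logit-linear zero part with
treatment effects, and a log-linear count part with treatment effects plus
random intercepts for fish, test session within fish, and condition.
Contrasts are reported as zero-part odds ratios and count-scale ratios;
latent-scale repeatability and posterior-predictive zero checks are
included.

## Worked example

Simulate the female design (143 fish, two lines × two foods, measured
every 14 days from 14 to 180 dph) at the study's point estimates and refit:

```r
library(biphasr)

cfg <- synth_config("F")
traj <- generate_growth(cfg, seed = 1)
fit  <- fit_growth(traj, default_growth_spec("F"),
                   default_growth_random_spec("F"))
fit$group_params
#>            line food a_mat a_mat_se        r      r_se   beta  beta_se
#>  large_selected high 47.86    1.048 0.018218 0.0004035 0.6634 0.003394
#>  small_selected high 48.13    1.071 0.018218 0.0004035 0.6634 0.003394
#>  large_selected  low 96.07    2.402 0.006963 0.0001949 0.5282 0.002692
#>  small_selected  low 84.74    2.307 0.006963 0.0001949 0.5282 0.002692
```

The generating values (high food: a_mat = 48 d, r = 0.018 d⁻¹, β = 0.66;
low food: a_mat = 97/81 d for the large-/small-selected line, r = 0.007,
β = 0.53) are recovered within sampling error: high-food fish of both lines
mature around 48 dph with high reproductive investment, while low food
delays maturation — by much less in the small-selected line — and lowers
both investment and the growth exponent. `fit$coef_table` gives the
treatment-contrast coefficients (reference: large-selected × high food)
with SEs, t and p values; `fit$theta` and `fit$re_sd` hold the MA(2) and
random-effect estimates.

The full analysis workflow lives under `analysis/`:

1. `01_simulate.R` — write the synthetic study (both sexes) to `results/data/`
2. `02_fit_growth.R` — allometry and hatch-length pre-estimation, then the
   per-sex growth fits (backward elimination for males)
3. `03_fit_behavior.R` — ZINB behaviour models with AIC structure selection
4. `04_recovery.R` — a reduced parameter-recovery table (truth vs median
   estimate)

Each script is run from the repository root, e.g.
`Rscript analysis/01_simulate.R`.

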