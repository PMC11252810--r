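# gscoben

Generalized synthetic control estimation of air-pollution co-benefits from
carbon policy.

## The problem

Cap-and-trade schemes such as the EU emissions trading system regulate CO2,
but the combustion they curb also emits toxic co-pollutants — SO2, PM2.5,
NOx. Quantifying how much co-pollution a carbon market avoided requires a
counterfactual: what would regulated sectors have emitted without the
policy? `gscoben` is a tested, reusable pipeline for that question on
annual country-level emissions panels, aimed at policy analysts and applied
econometricians working with inventory-style data (one regulated and one
unregulated aggregate per country, ~1990 onwards, treatment switching on in
2005).

## The method

Log emissions are modelled with an interactive fixed-effects (IFE) factor
model,

    log y_it = tau_it D_it + x_it' beta + lambda_i' f_t + eps_it,

where `D_it` is the treatment indicator (regulated unit, year >= 2005),
`x_it` are covariates (log GDP and its square in the main specification),
and `lambda_i' f_t` is a low-rank structure of unobserved time-varying
confounders with unit-specific loadings, estimated alongside additive unit
and year effects. The generalized synthetic control method (GSCM) proceeds
in three steps:

1. **Control fit** — estimate `beta`, the factors `f_t` and additive
   effects on control units only (joint least squares; the factor
   structure is profiled out in closed form via two-way demeaning plus a
   truncated SVD, and the few covariate coefficients are minimized by
   quasi-Newton iteration). The factor count `r` is chosen by
   leave-one-pretreatment-year-out cross-validation.
2. **Projection** — for each treated unit, choose loadings (and a unit
   intercept) minimizing pretreatment mean squared prediction error.
3. **Imputation** — impute the counterfactual
   `yhat_it(0) = x_it' beta + lambda_i' f_t + ...` for treated unit-years;
   the unit-period effect is `tau_it = log y_it - log yhat_it(0)` and the
   period ATT is its mean across treated units.

Inference uses a parametric bootstrap: control outcomes are resimulated
from the fitted factor model with resampled residual series, treated
outcomes from the imputed counterfactual plus the estimated effect plus
resampled prediction-error series (obtained by leaving each control out
and predicting it as if treated), and the estimator is refitted per
replication; percentile bands are reported.

Estimated effects are then aggregated into physical reductions
(counterfactual minus observed tons, summed over treated units and post
years), bounded for overlapping large-combustion-plant (LCP) standards via
`Reductions_t = E_t / (1 - ATT_t) - E_t` applied to LCP emissions after
2008, and monetized linearly with configurable per-ton damage costs
(Joint vs. Bounded benefits).

A synthetic-panel generator (`emissions_preset()`, `generate_panel()`)
simulates the same factor model forward with known ground truth, so every
stage is testable end to end without external data.

## Worked example

```r
library(gscoben)

sp <- generate_panel(emissions_preset(seed = 1, tau_profile = -0.40))
g  <- gscm(sp$panel)                                   # CV over r = 0..5
b  <- parametric_bootstrap(g, n_reps = 200, seed = 1001)
print(g)
print(b)
```

```
ife_fit: r = 2, force = two-way, 25 control units x 32 years
beta:
   log_gdp log_gdp_sq
    0.7346    -0.0206
converged in 24 iterations (SSR 1.82023)
cross-validation MSPE by r:
       0        1        2        3        4        5
0.035900 0.025310 0.004125 0.004465 0.004934 0.005431
gscm_result: 25 treated units, treatment from 2005
mean post-period effect: -0.3900 log points (-32.3% via 100*(exp-1))
mean pretreatment fit RMSE: 0.0501
gscm_bootstrap: 200 replications (0 failed), 95% percentile bands, seed 1001
mean post-period effect CI (log scale): [-0.4014, -0.3794]
```

Cross-validation recovers the true factor count (r = 2, minimal MSPE), and
the mean post-period effect of −0.390 log points matches the −0.40 built
into the simulation; the bootstrap interval covers it. Aggregation into a
co-benefit report (here with a synthetic LCP series equal to 40% of
treated emissions and a configured cost of 15,000 EUR/ton):

```r
lcp <- data.frame(year = g$result$post_years,
                  emissions = 0.4 * rowSums(g$result$observed_level)[
                    as.character(g$result$post_years)])
cobenefit_report(g$result, b, pollutant = "SO2", cost_per_ton = 15000,
                 lcp = lcp)
```

```
cobenefit_report: SO2
  mean effect: -32.3% [-33.1%, -31.6%]
  cumulative reduction: 1.414e+09 tons over 2005-2021
  joint benefit: 2.121e+13 | LCP-attributed: 3.593e+12 | bounded: 1.762e+13
```

The *joint* benefit values all estimated reductions; the *bounded* figure
subtracts the part ascribable to jointly regulated LCPs. Real analyses
feed `read_panel()` a long CSV (arbitrary headers via a schema mapping)
and run the same calls, or drive everything through `run_pipeline()` /
the `inst/cli/gscoben.R` command-line front end.

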