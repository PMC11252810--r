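---
title: "Counterfactual emissions and co-benefit accounting with gscoben"
author: "gscoben authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual emissions and co-benefit accounting with gscoben}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gscoben)
```

## The model and its assumptions

`gscoben` estimates the effect of a policy that switches on in a known
year (2005 by default, matching the first EU ETS trading period) on the
emissions of treated units, using untreated units to learn the
counterfactual. Log emissions follow an interactive fixed-effects model

$$\log y_{it} = \tau_{it} D_{it} + x_{it}'\beta + \lambda_i' f_t +
\alpha_i + \xi_t + \varepsilon_{it},$$

with covariates $x_{it}$, $r$ unobserved common factors $f_t$ with
unit-specific loadings $\lambda_i$, additive unit and year effects, and
idiosyncratic noise. Treatment effects are on the log scale, i.e.
multiplicative on tons. The key identifying assumptions are (i) no
interference between units, (ii) the control units' factor structure spans
the confounders that also drive treated units, and (iii) enough
pretreatment years to pin down each treated unit's loadings. None of these
are testable from the data alone; the in-time placebo and leave-one-out
re-runs probe their plausibility.

Estimation is the three-step counterfactual-imputation scheme of the
generalized synthetic control literature: fit the factor model on controls,
project treated units' loadings on their pretreatment residuals, impute
$\hat y_{it}(0)$ and average $\hat\tau_{it} = \log y_{it} - \log\hat
y_{it}(0)$ across treated units into the period ATT.

### Additive effects

The bare factor model can absorb additive unit/year effects only by
spending factor ranks on them, so the estimator defaults to two-way
additive effects alongside the factors (`force = "two-way"`), the standard
practice for this estimator family; `force = "none"` gives the bare model.
The choice is recorded in the run manifest.

## Numerical strategy

For fixed $\beta$ the inner least-squares problem is solved exactly on a
balanced panel: two-way demeaning yields the additive effects, and a
truncated SVD of the demeaned residual matrix yields the rank-$r$ factor
structure (the two parts are mutually orthogonal, so the one-shot solution
is jointly optimal). The profiled sum of squares is therefore a function
of the few covariate coefficients only, and is minimized by BFGS with the
envelope-theorem gradient $-2\langle X_k, \text{residual}\rangle$,
initialized at the deterministic two-way within-OLS estimate — fits are
reproducible without a seed.

We use this nested formulation rather than plain alternating updates
because the profiled objective can have long, curved, nearly flat valleys
when covariates are collinear (log GDP and its square) and the factors can
partially mimic their effect. Alternating updates stall in such valleys: on
a noise-free test panel they terminated far from the optimum with
coefficients off by an order of magnitude, while the imputed ATT barely
moved — the tell-tale of a weakly identified $\beta$ ridge. The
quasi-Newton profile reaches the optimum (objective $\sim 10^{-12}$ on
noise-free data, exact coefficient recovery) in tens of evaluations.
Practical consequences documented here:

* $\beta$ itself can remain weakly identified under collinear covariates;
  the ATT and counterfactuals are insensitive to movement along the ridge
  (verified to $\sim 10^{-3}$ log points across a $10^2$-fold range of
  iteration budgets).
* Convergence tolerance is `reltol = 1e-10` with a 2000-iteration cap per
  attempt; near singular-value crossings the profiled objective is only
  piecewise smooth, so the solver restarts BFGS up to three times (the
  accumulated Hessian approximation is the casualty of a kink) and falls
  back to a Nelder-Mead polish before declaring failure.
* The $r=0$ and no-covariate paths are exact closed forms (within-OLS /
  pure decomposition), so they agree with independent dummy-variable OLS
  oracles to machine precision.
* Factors are normalized to $F'F/T = I$ with orthogonal loadings; all
  reported quantities are rotation-invariant.

### Cross-validated factor count

The factor count is selected over candidates 0–5 (configurable) by
leave-one-pretreatment-year-out prediction of the treated units: for each
held-out year, loadings are re-estimated from the remaining pretreatment
years and the held-out observations are predicted under the candidate
model. Ties in mean squared prediction error break toward smaller $r$.
Candidates infeasible for the panel's dimensions are dropped. The search
range matters: selection degrades gracefully by over-selecting one rank
(extra factors fit pretreatment noise), which in simulations inflates
variance slightly but leaves the ATT nearly unbiased.

## The parametric bootstrap

Confidence bands come from simulating the fitted model. Two error pools
are built once: in-sample control residual series, and prediction-error
series obtained by leaving each control out, re-fitting, and predicting it
as if it were treated (the honest analogue of the treated units'
prediction problem). Each of the `n_reps` replications resimulates
controls as fitted values plus a resampled residual series and treated
units as imputed counterfactual plus estimated effect plus a resampled
prediction-error series, then refits everything at the selected $r$
(warm-started at the point estimate). Percentile bands use the inverse
empirical CDF, so with two draws they degenerate to the min/max, and the
across-units-and-periods mean effect gets its own interval.

Residual series are resampled as whole unit blocks by default, preserving
within-unit serial correlation; `resample = "iid"` scrambles cells for
sensitivity. Failed refits are dropped and counted rather than redrawn so
the draw stream stays reproducible; more than 10% failures aborts.
Calibration under the preset conditions: 95% bands covered a true constant
effect in 92% of 50 seeded trials at 200 replications.

## The synthetic data generator

`generate_panel()` simulates the model forward. The `emissions_preset()`
defaults encode the study-like conditions the pipeline is tested under:
25 treated + 25 control units, years 1990–2021, treatment from 2005, two
random-walk factors (innovation sd 0.2) with N(0, 0.5) loadings,
covariates log GDP (unit-specific random walks, drift 0.02, innovation sd
0.02, initial level N(10, 0.5)) and its square with coefficients (0.5,
−0.01), unit intercepts N(12, 0.5) on the log-tons scale (≈ 160k tons/yr),
noise sd 0.05, and a treatment-effect profile declining linearly from
−0.05 to −0.85 log points over 2005–2021 (a policy biting harder as the
cap tightens). Random-walk factors emulate trending, persistent
confounders such as structural change in energy systems; `factor_type =
"iid"` gives stationary ones. A `confound` knob correlates the first
loading with mean log GDP to simulate covariate-correlated confounding
(off by default). Treatment effects enter exactly on the log scale, so
the generated ground truth satisfies $\log Y(1) - \log Y(0) = \tau_t$ by
construction.

What the generator does *not* emulate: inventory reporting revisions,
sectoral reallocation between the regulated and unregulated aggregates,
heteroskedastic or serially correlated noise, and anticipation effects.
Passing tests on the preset therefore demonstrate estimator correctness
under the stated factor model, not robustness to every feature of real
inventory data.

## Co-benefit accounting choices

* **Percent convention**: effects from the log-outcome model are reported
  both as log points ×100 and as $100(e^{\tau}-1)$; headline numbers use
  the exponentiated (exact) conversion, and both appear in outputs so the
  choice is auditable.
* **Level-scale counterfactuals** are plain exponentials of the log-scale
  imputations — no retransformation (smearing) correction — and the
  omission is noted in every report.
* **Bounding**: reductions ascribed to jointly regulated large combustion
  plants use $\text{Reductions}_t = E_t/(1-\text{ATT}_t) - E_t$ on LCP
  emissions from 2008 (when tightened standards became binding;
  configurable), with the ATT taken as the level-scale proportional effect
  $e^{\tau}-1$ by default and the raw log-point alternative available for
  sensitivity. Negative values denote avoided emissions; their magnitude
  is subtracted from the Joint benefit to give the Bounded benefit.
* **Costs are configuration**: per-ton damage costs, currency and price
  year are inputs; no inflation arithmetic is done internally.
* **The economy-wide denominator** for reduction shares is a separate
  input series, because the estimation panel covers only the two
  aggregates per country.
* The post-treatment totalling window is inclusive 2005–2021 by default
  and configurable.

## Degenerate inputs and guards

Unbalanced panels, non-positive outcomes and missing covariate cells are
rejected at validation with the offending units/rows named (no imputation
is invented). Factor counts above $\min(N_{co}, T) - 1$, projections with
fewer pretreatment years than parameters, bounding with
$\text{ATT}_t \ge 1$, zero economy-wide denominators and missing cost
factors are all errors. The in-time placebo requires at least three
pretreatment years before the pseudo-adoption year and discards all data
from the true adoption year onward.

## Problem sizes used in the test suite

Unit tests run on small panels (4–6 treated, 8–10 controls, 13–16 years);
statistical checks use the full preset (50 units × 32 years) with 50
seeded replicates, and bootstrap calibration uses 200 replications per
trial — enough for stable 2.5%/97.5% percentile estimates while keeping
the default suite in minutes. The study-scale bootstrap default in
`parametric_bootstrap()` remains 1000 replications.

## Known limitations

The estimator assumes a single shiftable adoption year (no staggered
adoption), balanced panels without missingness, and homogeneous damage
costs per ton regardless of where emissions occur. Matrix-completion and
synthetic difference-in-differences alternatives are out of scope, as are
chemical-transport-model-based spatially resolved damages.
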