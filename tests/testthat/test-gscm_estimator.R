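# Estimation-step tests: control-unit factor fit, cross-validation of the
# factor count, treated-unit projection, counterfactual imputation.

test_that("r = 0 without covariates or additive effects fits nothing", {
  sp <- generate_panel(small_spec(seed = 1))
  fit <- fit_ife_controls(sp$panel, r = 0, covariates = character(),
                          force = "none")
  expect_length(fit$beta, 0)
  expect_equal(fit$fitted, matrix(0, nrow(fit$resid), ncol(fit$resid)),
               ignore_attr = TRUE)
  lg <- log_transform(sp$panel)
  yc <- gscoben:::panel_matrix(lg, "outcome", fit$control_units)
  expect_equal(unname(fit$resid), unname(yc), tolerance = 1e-12)
})

test_that("r = 0 coefficient paths equal independent OLS oracles", {
  sp <- generate_panel(small_spec(seed = 2))
  lg <- as.data.frame(log_transform(sp$panel))
  ctrl <- lg[!lg$treated, ]

  # bare factor model, no additive effects: plain no-intercept OLS
  fit_none <- fit_ife_controls(sp$panel, r = 0, force = "none")
  ols <- stats::lm(outcome ~ 0 + log_gdp + log_gdp_sq, data = ctrl)
  expect_equal(unname(fit_none$beta), unname(stats::coef(ols)),
               tolerance = 1e-8)

  # two-way additive effects: least-squares dummy-variable oracle
  fit_tw <- fit_ife_controls(sp$panel, r = 0, force = "two-way")
  lsdv <- stats::lm(outcome ~ log_gdp + log_gdp_sq + factor(unit) +
                      factor(year), data = ctrl)
  expect_equal(unname(fit_tw$beta),
               unname(stats::coef(lsdv)[c("log_gdp", "log_gdp_sq")]),
               tolerance = 1e-8)
})

test_that("estimated factors span the true factor space at low noise", {
  sp <- generate_panel(emissions_preset(seed = 3, noise_sd = 0.01))
  fit <- fit_ife_controls(sp$panel, r = 2)
  # additive effects absorb means: compare on demeaned true factors
  f_true <- scale(sp$truth$factors, scale = FALSE)
  cc <- stats::cancor(fit$factors, f_true)$cor
  expect_true(all(cc > 0.99))
})

test_that("fits are deterministic and the objective is reproducible", {
  sp <- generate_panel(small_spec(seed = 4))
  f1 <- fit_ife_controls(sp$panel, r = 2)
  f2 <- fit_ife_controls(sp$panel, r = 2)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$ssr, f2$ssr)
  expect_true(f1$converged)
  expect_equal(crossprod(f1$factors) / length(f1$years),
               diag(2), ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("infeasible factor counts are rejected", {
  sp <- generate_panel(small_spec(seed = 5))
  expect_error(fit_ife_controls(sp$panel, r = 10), "too large")
})

test_that("ATT is invariant to factor rotation and to starting values", {
  sp <- generate_panel(small_spec(seed = 6))
  g <- gscm(sp$panel, r = 2)

  # any orthogonal rotation of (factors, loadings) leaves the common
  # component, hence predictions, untouched
  q <- qr.Q(qr(matrix(stats::rnorm(4), 2, 2)))
  common <- g$fit$factors %*% t(g$projection$treated_loadings)
  common_rot <- (g$fit$factors %*% q) %*% t(g$projection$treated_loadings %*% q)
  expect_equal(common, common_rot, tolerance = 1e-10)

  # refitting from perturbed starting coefficients moves the ATT by at
  # most the flat-ridge indeterminacy
  mats <- gscoben:::panel_matrices(sp$panel, g$fit$covariates)
  alt <- gscoben:::gscm_core(mats$yc, mats$yt, mats$xc, mats$xt,
                             mats$pre_idx, mats$post_idx, r = 2,
                             force = "two-way",
                             beta_init = unname(g$fit$beta) + c(0.5, -0.02))
  expect_lt(abs(alt$mean_att - mean(g$result$tau)), 5e-3)
})

test_that("cross-validation returns a single candidate unchanged and records MSPE", {
  sp <- generate_panel(small_spec(seed = 7))
  fit <- cross_validate_r(sp$panel, candidates = 3)
  expect_equal(fit$r, 3L)
  expect_length(fit$mspe_by_r, 1)
  fit2 <- cross_validate_r(sp$panel, candidates = 0:3)
  expect_length(fit2$mspe_by_r, 4)
  expect_equal(unname(fit2$mspe_by_r[as.character(fit2$r)]),
               min(fit2$mspe_by_r))
})

test_that("cross-validation recovers the true factor count on clear designs", {
  picks2 <- vapply(1:5, function(s) {
    cross_validate_r(generate_panel(emissions_preset(seed = s))$panel)$r
  }, integer(1))
  picks0 <- vapply(1:5, function(s) {
    cross_validate_r(
      generate_panel(emissions_preset(seed = s, n_factors = 0))$panel)$r
  }, integer(1))
  expect_gte(sum(picks2 == 2L), 4)
  expect_equal(picks0, rep(0L, 5))
})

test_that("a treated unit duplicating a control reproduces its loadings", {
  spec <- dgp_spec(n_treated = 2, n_control = 6, years = 2000:2015,
                   treatment_start = 2010, n_factors = 2,
                   beta_true = numeric(0), tau_profile = 0,
                   noise_sd = 1e-8, seed = 8)
  sp <- generate_panel(spec)
  pd <- sp$panel
  dup_src <- pd$outcome[pd$unit == "C01"]
  pd$outcome[pd$unit == "T01"] <- dup_src
  pd <- panel_data(as.data.frame(pd), covariates = character(),
                   treatment_start = 2010)
  g <- gscm(pd, r = 2, covariates = character())
  expect_lt(g$result$pre_fit_rmse[["T01"]], 1e-6)
  expect_equal(g$projection$treated_loadings["T01", ],
               g$fit$loadings["C01", ], tolerance = 1e-4)
  # its imputed counterfactual tracks the duplicated control exactly
  expect_equal(unname(g$result$y0_log[, "T01"]),
               unname(log(dup_src)), tolerance = 1e-4)
})

test_that("r = 0 treated projection residuals equal the OLS pre-period residuals", {
  sp <- generate_panel(small_spec(seed = 9))
  g <- gscm(sp$panel, r = 0, force = "none")
  lg <- as.data.frame(log_transform(sp$panel))
  ctrl <- lg[!lg$treated, ]
  ols <- stats::lm(outcome ~ 0 + log_gdp + log_gdp_sq, data = ctrl)
  pre_t <- lg[lg$treated & lg$year < 2010, ]
  pred <- as.matrix(pre_t[c("log_gdp", "log_gdp_sq")]) %*% stats::coef(ols)
  resid_oracle <- pre_t$outcome - as.numeric(pred)
  eta <- g$projection$eta
  resid_pkg <- as.numeric(eta[cbind(as.character(pre_t$year), pre_t$unit)])
  expect_equal(resid_pkg, resid_oracle, tolerance = 1e-10)
})

test_that("noise-free effects are recovered to numerical tolerance", {
  spec <- emissions_preset(seed = 10, noise_sd = 1e-7, tau_profile = -0.40,
                           n_treated = 6, n_control = 10)
  sp <- generate_panel(spec)
  g <- gscm(sp$panel, r = 2)
  expect_equal(unname(g$result$att_by_year),
               rep(-0.40, length(g$result$post_years)), tolerance = 1e-3)
  # treated loadings match the realized truth up to the factor rotation:
  # compare the common components instead of raw loadings
  expect_lt(max(abs(g$result$tau + 0.40)), 1e-2)
})

test_that("period ATT is the arithmetic mean of unit effects", {
  sp <- generate_panel(small_spec(seed = 11))
  g <- gscm(sp$panel, r = 1)
  expect_equal(g$result$att_by_year, rowMeans(g$result$tau))
  expect_equal(g$result$att_all_years[names(g$result$att_by_year)],
               g$result$att_by_year)
  # mean pretreatment gap vanishes by construction of the projection
  pre_gap <- g$result$gap[as.character(2000:2009), ]
  expect_lt(max(abs(colMeans(pre_gap))), 1e-10)
})
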