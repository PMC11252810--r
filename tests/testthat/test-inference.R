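# Parametric bootstrap and robustness re-runs.

test_that("bootstrap bands are seed-reproducible and ordered", {
  sp <- generate_panel(small_spec(seed = 1))
  g <- gscm(sp$panel, r = 2)
  b1 <- parametric_bootstrap(g, n_reps = 25, seed = 42)
  b2 <- parametric_bootstrap(g, n_reps = 25, seed = 42)
  expect_identical(b1$att_draws, b2$att_draws)
  expect_identical(b1$ci_lower, b2$ci_lower)
  b3 <- parametric_bootstrap(g, n_reps = 25, seed = 43)
  expect_false(identical(b1$ci_lower, b3$ci_lower))
  expect_true(all(b1$ci_lower <= b1$ci_upper))
  expect_equal(b1$n_failed, 0L)
})

test_that("bands collapse onto the point estimate as noise vanishes", {
  sp <- generate_panel(small_spec(seed = 2, noise_sd = 1e-7))
  g <- gscm(sp$panel, r = 2)
  b <- parametric_bootstrap(g, n_reps = 30, seed = 1)
  width <- b$ci_upper - b$ci_lower
  expect_lt(max(width), 1e-4)
  post <- as.character(g$result$post_years)
  expect_true(all(abs(b$ci_lower[post] - g$result$att_by_year) < 1e-4))
})

test_that("band width shrinks with the noise level", {
  widths <- vapply(c(0.02, 0.1), function(ns) {
    sp <- generate_panel(small_spec(seed = 3, noise_sd = ns))
    g <- gscm(sp$panel, r = 2)
    b <- parametric_bootstrap(g, n_reps = 40, seed = 5)
    mean(b$ci_upper - b$ci_lower)
  }, numeric(1))
  expect_lt(widths[1], widths[2])
})

test_that("two replications give degenerate min/max percentile bands", {
  sp <- generate_panel(small_spec(seed = 4))
  g <- gscm(sp$panel, r = 1)
  b <- parametric_bootstrap(g, n_reps = 2, seed = 9)
  expect_equal(unname(b$ci_lower), apply(b$att_draws, 2, min))
  expect_equal(unname(b$ci_upper), apply(b$att_draws, 2, max))
})

test_that("iid and unit-block resampling are both available and differ", {
  sp <- generate_panel(small_spec(seed = 5))
  g <- gscm(sp$panel, r = 1)
  bu <- parametric_bootstrap(g, n_reps = 20, seed = 3,
                             resample = "unit-block")
  bi <- parametric_bootstrap(g, n_reps = 20, seed = 3, resample = "iid")
  expect_false(identical(bu$att_draws, bi$att_draws))
})

test_that("leave-one-out refits once per omitted unit; symmetric panels give identical series", {
  spec <- dgp_spec(n_treated = 3, n_control = 6, years = 2000:2012,
                   treatment_start = 2008, n_factors = 1,
                   beta_true = numeric(0), tau_profile = -0.3,
                   noise_sd = 1e-6, seed = 6)
  sp <- generate_panel(spec)
  pd <- sp$panel
  # make the three treated units carbon copies of the first
  src <- pd$outcome[pd$unit == "T01"]
  for (u in c("T02", "T03")) pd$outcome[pd$unit == u] <- src
  pd <- panel_data(as.data.frame(pd), covariates = character(),
                   treatment_start = 2008)
  lo <- leave_one_out(pd, r = 1, covariates = character())
  expect_length(lo$fits, 3)
  expect_equal(lo$att_by_year["T01", ], lo$att_by_year["T02", ],
               tolerance = 1e-8)
  expect_equal(lo$att_by_year["T02", ], lo$att_by_year["T03", ],
               tolerance = 1e-8)
  expect_error(leave_one_out(sp$panel[0, ]), class = "error")
})

test_that("omitting a null-effect unit moves the mean ATT away from zero", {
  spec <- dgp_spec(n_treated = 3, n_control = 8, years = 2000:2015,
                   treatment_start = 2010, n_factors = 1,
                   beta_true = numeric(0), tau_profile = -0.4,
                   noise_sd = 0.01, seed = 7)
  sp <- generate_panel(spec)
  pd <- sp$panel
  # cancel the effect for T01 by restoring its counterfactual outcomes
  post <- pd$year >= 2010 & pd$unit == "T01"
  pd$outcome[post] <- exp(sp$truth$y0_log[as.character(2010:2015), "T01"])
  pd <- panel_data(as.data.frame(pd), covariates = character(),
                   treatment_start = 2010)
  lo <- leave_one_out(pd, r = 1, covariates = character())
  full <- gscm(pd, r = 1, covariates = character())
  expect_lt(lo$mean_att[["T01"]], mean(full$result$tau))
  expect_lt(abs(lo$mean_att[["T02"]] - mean(full$result$tau)) ,
            abs(lo$mean_att[["T01"]] - mean(full$result$tau)))
})

test_that("leave-one-out requires enough treated units", {
  sp <- generate_panel(small_spec(seed = 8, n_treated = 2))
  expect_error(leave_one_out(sp$panel, r = 1), ">= 3")
})

test_that("in-time placebo truncates at the true start and respects guards", {
  sp <- generate_panel(emissions_preset(seed = 9, tau_profile = -0.4))
  pl <- in_time_placebo(sp$panel, pseudo_start = 1999, r = 2)
  expect_equal(max(pl$panel$year), 2004L)
  expect_equal(pl$result$post_years, 1999:2004)
  # the true 2005 effect never enters, so the placebo ATT is small
  expect_lt(abs(mean(pl$result$tau)), 0.05)
  expect_error(in_time_placebo(sp$panel, pseudo_start = 2006),
               "strictly before")
  expect_error(in_time_placebo(sp$panel, pseudo_start = 1991),
               ">= 3 pretreatment years")
})
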