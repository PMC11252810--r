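# Accounting layer: percent conversion, physical reductions, bounding of
# overlapping combustion-plant standards, monetization.

# build a gscm_result by hand with known counterfactuals
fake_result <- function(y_obs_log, y0_log, years, t0) {
  post <- which(years >= t0)
  gap <- y_obs_log - y0_log
  structure(list(
    y0_log = y0_log, y0_level = exp(y0_log),
    observed_log = y_obs_log, observed_level = exp(y_obs_log),
    gap = gap, tau = gap[post, , drop = FALSE],
    att_by_year = rowMeans(gap[post, , drop = FALSE]),
    att_all_years = rowMeans(gap),
    pre_fit_rmse = numeric(ncol(y0_log)), eta = NULL,
    years = years, post_years = years[post],
    treated_units = colnames(y0_log), treatment_start = t0
  ), class = "gscm_result")
}

two_unit_result <- function(tau1 = -0.1, tau2 = -0.3) {
  years <- 2003:2006
  y0 <- matrix(5, 4, 2, dimnames = list(years, c("a", "b")))
  yo <- y0
  yo[3:4, 1] <- 5 + tau1
  yo[3:4, 2] <- 5 + tau2
  fake_result(yo, y0, years, 2005L)
}

test_that("mean effects convert between log points and exact percent", {
  res0 <- two_unit_result(0, 0)
  expect_equal(summarize_effects(res0)$mean_pct, 0)

  res <- two_unit_result(log(0.61), log(0.61))
  expect_equal(summarize_effects(res, convention = "exp")$mean_pct, -39,
               tolerance = 1e-10)
  expect_equal(summarize_effects(res, convention = "log")$mean_pct,
               100 * log(0.61), tolerance = 1e-10)

  res2 <- two_unit_result(-0.1, -0.3)
  expect_equal(summarize_effects(res2)$mean_log, -0.2, tolerance = 1e-12)
})

test_that("cumulative reductions sum counterfactual-minus-observed levels", {
  res0 <- two_unit_result(0, 0)
  expect_equal(cumulative_reductions(res0)$total, 0)

  years <- 2004:2006
  y0 <- matrix(log(150), 3, 1, dimnames = list(years, "a"))
  yo <- y0; yo[2, 1] <- log(100); yo[3, 1] <- log(150)
  res <- fake_result(yo, y0, years, 2005L)
  cr <- cumulative_reductions(res)
  expect_equal(unname(cr$by_year), c(50, 0), tolerance = 1e-10)
  expect_equal(cr$total, 50, tolerance = 1e-10)
  # additivity: total is exactly the sum of its per-year components
  expect_identical(cr$total, sum(cr$by_year))
  # window restriction
  expect_equal(cumulative_reductions(res, window = 2006)$total, 0,
               tolerance = 1e-10)
  expect_error(cumulative_reductions(res, window = 1999), "outside")
})

test_that("share of economy-wide emissions is a plain ratio in percent", {
  econ <- stats::setNames(c(40, 60), 2005:2006)
  expect_equal(share_of_economy_wide(10, econ, 2005:2006), 10)
  expect_equal(share_of_economy_wide(0, econ, 2005:2006), 0)
  expect_error(share_of_economy_wide(1, econ * 0, 2005:2006), "zero")
  expect_error(share_of_economy_wide(1, econ, 2004:2006), "missing years")
})

test_that("the LCP bounding formula matches hand-computed values", {
  lcp <- data.frame(year = 2008:2010, emissions = c(100, 100, 0))
  att_zero <- stats::setNames(rep(0, 3), 2008:2010)
  bz <- bound_lcp(att_zero, lcp, convention = "log")
  expect_equal(unname(bz$by_year), c(0, 0, 0))

  att <- stats::setNames(c(-0.5, -0.5, -0.5), 2008:2010)
  bl <- bound_lcp(att, lcp, convention = "log")
  expect_equal(unname(bl$by_year[1]), 100 / 1.5 - 100, tolerance = 1e-10)
  expect_equal(unname(bl$by_year[3]), 0)
  expect_equal(bl$attributed_tons, -sum(bl$by_year))

  # exp convention: a log effect of log(0.5) is a level fraction of -0.5
  att_log <- stats::setNames(rep(log(0.5), 3), 2008:2010)
  be <- bound_lcp(att_log, lcp, convention = "exp")
  expect_equal(unname(be$by_year[1]), 100 / 1.5 - 100, tolerance = 1e-10)

  # years before the bounding window are ignored
  att5 <- stats::setNames(rep(-0.5, 5), 2006:2010)
  lcp5 <- data.frame(year = 2006:2010, emissions = 100)
  b5 <- bound_lcp(att5, lcp5, convention = "log")
  expect_equal(as.integer(names(b5$by_year)), 2008:2010)

  expect_error(bound_lcp(stats::setNames(1.2, 2008),
                         data.frame(year = 2008, emissions = 1),
                         convention = "log"),
               "undefined")
})

test_that("monetization is linear and validates its configuration", {
  costs <- list(SO2 = 15000, currency = "EUR", price_year = 2021)
  expect_equal(unname(monetize(c(SO2 = 1), costs)), 15000)
  expect_equal(unname(monetize(c(SO2 = 0), costs)), 0)
  expect_equal(monetize(c(SO2 = 2), costs), 2 * monetize(c(SO2 = 1), costs))
  expect_error(monetize(c(NOx = 1), costs), "no cost factor")
})

test_that("bounded benefit is joint minus LCP-attributed, end to end", {
  res <- two_unit_result(log(0.8), log(0.8))
  lcp <- data.frame(year = 2005:2006, emissions = c(1000, 1000))
  rep_out <- cobenefit_report(res, pollutant = "SO2", cost_per_ton = 10,
                              lcp = lcp, lcp_start_year = 2005)
  expect_equal(rep_out$bounded_benefit,
               rep_out$joint_benefit - rep_out$lcp_attributed_benefit)
  expect_lte(rep_out$bounded_benefit, rep_out$joint_benefit)
  expect_equal(rep_out$joint_benefit,
               10 * rep_out$cumulative_reduction_tons)
  econ <- stats::setNames(rep(1e5, 2), 2005:2006)
  rep2 <- cobenefit_report(res, pollutant = "SO2", cost_per_ton = 10,
                           economy_series = econ)
  expect_equal(rep2$share_of_economy_wide,
               100 * rep2$cumulative_reduction_tons / 2e5)
})
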