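#' Project treated units onto the estimated factor structure
#'
#' Step two of the generalized synthetic control method: for each treated
#' unit, the loadings (and, with additive effects on, the unit intercept)
#' are the least-squares solution regressing the pretreatment residual
#' (log outcome minus covariate contribution and time effects) on the
#' estimated factors, restricted to pretreatment years — i.e. loadings are
#' chosen to minimize pretreatment mean squared prediction error.
#'
#' @param fit an `ife_fit` from [fit_ife_controls()] or
#'   [cross_validate_r()].
#' @param panel the same panel the fit was computed on.
#' @return A `gscm_projection`: `treated_loadings` (N_tr x r),
#'   `treated_alpha` unit intercepts, `eta` (pretreatment residuals,
#'   T_0 x N_tr), and `pre_fit_rmse` per treated unit.
#' @export
project_treated <- function(fit, panel) {
  stopifnot(inherits(fit, "ife_fit"))
  mats <- panel_matrices(panel, fit$covariates)
  if (!identical(mats$units$control, fit$control_units)) {
    stop("fit and panel disagree on the control units")
  }
  proj <- project_units(fit, mats$yt, mats$xt, mats$pre_idx)
  rownames(proj$lambda) <- mats$units$treated
  names(proj$alpha) <- mats$units$treated
  dimnames(proj$resid_fit) <- list(mats$years[mats$pre_idx], mats$units$treated)
  names(proj$rmse_fit) <- mats$units$treated
  structure(list(
    treated_loadings = proj$lambda, treated_alpha = proj$alpha,
    eta = proj$resid_fit, pre_fit_rmse = proj$rmse_fit,
    y0_log = proj$pred, treated_units = mats$units$treated
  ), class = "gscm_projection")
}

#' Impute counterfactuals and compute treatment effects
#'
#' Step three: the counterfactual log outcome of each treated unit-year is
#' imputed from the estimated coefficients, factors and the treated unit's
#' projected loadings; its exponential gives the level-scale counterfactual
#' in tons (no retransformation correction is applied). The unit-period
#' effect is the observed-minus-counterfactual log gap for years at or
#' after the treatment start, and the period ATT is its unweighted mean
#' across treated units.
#'
#' @param fit an `ife_fit`.
#' @param projection the matching [project_treated()] output.
#' @param panel the panel both were computed on.
#' @return A `gscm_result` with `y0_log` and `y0_level` (years x treated
#'   units), observed levels, `gap` (log observed minus imputed, all
#'   years), `tau` (the gap restricted to post-treatment years),
#'   `att_by_year` (post years), `att_all_years`, `pre_fit_rmse` and `eta`.
#' @export
impute_and_att <- function(fit, projection, panel) {
  stopifnot(inherits(fit, "ife_fit"), inherits(projection, "gscm_projection"))
  mats <- panel_matrices(panel, fit$covariates)
  y0 <- projection$y0_log
  dimnames(y0) <- list(mats$years, mats$units$treated)
  gap <- mats$yt - y0
  post <- mats$post_idx
  tau <- gap[post, , drop = FALSE]
  structure(list(
    y0_log = y0, y0_level = exp(y0),
    observed_log = mats$yt, observed_level = exp(mats$yt),
    gap = gap, tau = tau,
    att_by_year = rowMeans(tau),
    att_all_years = rowMeans(gap),
    pre_fit_rmse = projection$pre_fit_rmse, eta = projection$eta,
    years = mats$years, post_years = mats$years[post],
    treated_units = mats$units$treated,
    treatment_start = mats$treatment_start
  ), class = "gscm_result")
}

#' @export
print.gscm_result <- function(x, ...) {
  cat(sprintf(
    "gscm_result: %d treated units, treatment from %d\n",
    length(x$treated_units), x$treatment_start
  ))
  m <- mean(x$tau)
  cat(sprintf(
    "mean post-period effect: %.4f log points (%.1f%% via 100*(exp-1))\n",
    m, 100 * (exp(m) - 1)
  ))
  cat(sprintf("mean pretreatment fit RMSE: %.4f\n", mean(x$pre_fit_rmse)))
  invisible(x)
}

#' Generalized synthetic control estimation
#'
#' One-call wrapper running the three estimation steps: fit the interactive
#' fixed-effects model on control units (with cross-validated factor count
#' when `r` is `NULL`), project treated-unit loadings on pretreatment
#' years, and impute counterfactuals / treatment effects.
#'
#' @inheritParams fit_ife_controls
#' @param r factor count; `NULL` (default) selects it by
#'   [cross_validate_r()] over `candidates`.
#' @param candidates candidate factor counts for cross-validation.
#' @return A `gscm` object bundling `fit` (`ife_fit`), `projection` and
#'   `result` (`gscm_result`), plus the logged panel for downstream
#'   inference.
#' @examples
#' sp <- generate_panel(emissions_preset(n_treated = 5, n_control = 8,
#'                                       seed = 7))
#' g <- gscm(sp$panel, r = 2)
#' g$result$att_by_year
#' @export
gscm <- function(panel, r = NULL, candidates = 0:5,
                 covariates = attr(panel, "covariates"),
                 force = c("two-way", "none"), tol = 1e-10,
                 max_iter = 2000L) {
  force <- match.arg(force)
  panel <- log_transform(panel)
  fit <- if (is.null(r)) {
    cross_validate_r(panel, candidates, covariates, force, tol, max_iter)
  } else {
    fit_ife_controls(panel, r, covariates, force, tol, max_iter)
  }
  projection <- project_treated(fit, panel)
  result <- impute_and_att(fit, projection, panel)
  structure(list(
    panel = panel, fit = fit, projection = projection, result = result,
    settings = list(r = fit$r, candidates = if (is.null(r)) candidates,
                    covariates = covariates, force = force, tol = tol,
                    max_iter = max_iter)
  ), class = "gscm")
}

#' @export
print.gscm <- function(x, ...) {
  cat("Generalized synthetic control fit\n")
  print(x$fit)
  print(x$result)
  invisible(x)
}

# Internal fast path used by bootstrap/robustness refits: everything in
# matrices, fixed r, warm-startable beta.
gscm_core <- function(yc, yt, xc, xt, pre_idx, post_idx, r, force,
                      tol = 1e-10, max_iter = 2000L, beta_init = NULL) {
  fit <- ife_solve(yc, xc, r, force, tol, max_iter, beta_init)
  proj <- project_units(fit, yt, xt, pre_idx)
  gap <- yt - proj$pred
  list(fit = fit, proj = proj, gap = gap,
       att_all = rowMeans(gap),
       att_post = rowMeans(gap[post_idx, , drop = FALSE]),
       mean_att = mean(gap[post_idx, , drop = FALSE]))
}
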