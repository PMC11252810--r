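#' Parametric bootstrap confidence bands for the ATT
#'
#' Simulation-based inference under the fitted factor model. Two error
#' pools are built once from the point fit: (i) in-sample residual series
#' of control units, and (ii) prediction-error series obtained by treating
#' each control unit in turn as pseudo-treated — refitting the factor model
#' on the remaining controls, projecting the left-out unit's loadings on
#' pretreatment years, and recording its observed-minus-predicted series.
#' Each replication then simulates control outcomes as fitted values plus a
#' resampled residual series, and treated outcomes as the imputed
#' counterfactual plus the estimated effect plus a resampled prediction
#' error series, refits the full estimator at the selected factor count,
#' and records the ATT path. Pointwise percentile bands (inverse empirical
#' CDF) are reported at the stated level, as is an interval for the
#' across-units-and-periods mean effect.
#'
#' Residual series are resampled as whole unit blocks by default, which
#' preserves within-unit serial correlation; `resample = "iid"` scrambles
#' individual cells instead. Replications whose refit fails are dropped and
#' counted, not retried, so the draw stream is reproducible; more than 10%
#' failures is an error.
#'
#' @param object a fitted [gscm()] object.
#' @param n_reps number of bootstrap replications (>= 2; the study-scale
#'   default is 1000).
#' @param level confidence level for the percentile bands.
#' @param seed integer seed; identical seeds give identical bands.
#' @param resample `"unit-block"` (default) or `"iid"` residual resampling.
#' @return A `gscm_bootstrap`: `att_draws` (replications x years, all
#'   years), `ci_lower`/`ci_upper` pointwise bands, `mean_att_draws` and
#'   `mean_att_ci` for the mean post-period effect (log scale), counts of
#'   failed refits, and the settings used.
#' @export
parametric_bootstrap <- function(object, n_reps = 1000L, level = 0.95,
                                 seed = 1L,
                                 resample = c("unit-block", "iid")) {
  stopifnot(inherits(object, "gscm"))
  resample <- match.arg(resample)
  if (n_reps < 2L) stop("n_reps must be >= 2")
  if (!object$fit$converged) stop("point fit did not converge")
  mats <- panel_matrices(object$panel, object$fit$covariates)
  r <- object$fit$r
  force <- object$fit$force
  tol <- object$settings$tol
  max_iter <- object$settings$max_iter
  n_co <- ncol(mats$yc)
  n_tr <- ncol(mats$yt)
  t_len <- length(mats$years)
  beta_warm <- if (length(object$fit$beta)) unname(object$fit$beta)

  # prediction-error pool: leave each control out, predict it as if treated
  pe_pool <- matrix(NA_real_, t_len, n_co)
  for (j in seq_len(n_co)) {
    sub <- ife_solve(mats$yc[, -j, drop = FALSE],
                   lapply(mats$xc, function(x) x[, -j, drop = FALSE]),
                   r, force, tol, max_iter, beta_init = beta_warm)
    pj <- project_units(sub, mats$yc[, j, drop = FALSE],
                        lapply(mats$xc, function(x) x[, j, drop = FALSE]),
                        mats$pre_idx)
    pe_pool[, j] <- mats$yc[, j] - pj$pred[, 1]
  }

  resid_c <- mats$yc - object$fit$fitted
  fitted_c <- object$fit$fitted
  # treated DGP: imputed counterfactual plus estimated unit-period effects
  y1_base <- object$result$y0_log
  y1_base[mats$post_idx, ] <- y1_base[mats$post_idx, , drop = FALSE] +
    object$result$tau

  draw_series <- function(pool, n_units) {
    if (resample == "unit-block") {
      pool[, sample.int(ncol(pool), n_units, replace = TRUE), drop = FALSE]
    } else {
      matrix(sample(as.vector(pool), t_len * n_units, replace = TRUE),
             t_len, n_units)
    }
  }

  att_draws <- matrix(NA_real_, n_reps, t_len)
  mean_att_draws <- rep(NA_real_, n_reps)
  n_failed <- 0L
  failures <- character(0)
  with_seed(seed, {
    for (b in seq_len(n_reps)) {
      yc_b <- fitted_c + draw_series(resid_c, n_co)
      yt_b <- y1_base + draw_series(pe_pool, n_tr)
      res_b <- tryCatch(
        gscm_core(yc_b, yt_b, mats$xc, mats$xt, mats$pre_idx, mats$post_idx,
                  r, force, tol, max_iter, beta_init = beta_warm),
        error = function(e) e
      )
      if (inherits(res_b, "error")) {
        n_failed <- n_failed + 1L
        failures <- c(failures, conditionMessage(res_b))
      } else {
        att_draws[b, ] <- res_b$att_all
        mean_att_draws[b] <- res_b$mean_att
      }
    }
  })
  if (n_failed > 0.10 * n_reps) {
    stop("parametric bootstrap: ", n_failed, "/", n_reps,
         " replications failed; first error: ", failures[1])
  }
  ok <- !is.na(mean_att_draws)
  alpha <- (1 - level) / 2
  qs <- function(v) stats::quantile(v, c(alpha, 1 - alpha), type = 1,
                                    names = FALSE)
  bands <- apply(att_draws[ok, , drop = FALSE], 2, qs)
  structure(list(
    n_reps = n_reps, n_failed = n_failed, level = level, seed = seed,
    resample = resample,
    att_draws = att_draws[ok, , drop = FALSE],
    mean_att_draws = mean_att_draws[ok],
    ci_lower = stats::setNames(bands[1, ], mats$years),
    ci_upper = stats::setNames(bands[2, ], mats$years),
    mean_att_ci = qs(mean_att_draws[ok]),
    years = mats$years, post_years = mats$years[mats$post_idx]
  ), class = "gscm_bootstrap")
}

#' @export
print.gscm_bootstrap <- function(x, ...) {
  cat(sprintf(
    "gscm_bootstrap: %d replications (%d failed), %.0f%% percentile bands, seed %d\n",
    x$n_reps, x$n_failed, 100 * x$level, x$seed
  ))
  cat(sprintf("mean post-period effect CI (log scale): [%.4f, %.4f]\n",
              x$mean_att_ci[1], x$mean_att_ci[2]))
  invisible(x)
}
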