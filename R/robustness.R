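#' Leave-one-out re-estimation
#'
#' Robustness check re-running the full estimator once per omitted unit:
#' by default each treated unit is dropped in turn (optionally each control
#' unit), and the ATT series of every re-fit is collected so that the
#' influence of any single unit on the headline effect can be inspected.
#'
#' @param panel a [panel_data()].
#' @param which `"treated"` (default) or `"control"`: which set to omit
#'   from, one unit at a time.
#' @param ... arguments passed to [gscm()] (e.g. `r`, `covariates`,
#'   `force`).
#' @return A `gscm_loo`: named list of [gscm()] fits (one per omitted
#'   unit), plus an `att_by_year` matrix (omitted unit x post year) and the
#'   mean post-period effect per omission.
#' @export
leave_one_out <- function(panel, which = c("treated", "control"), ...) {
  which <- match.arg(which)
  validate_panel(panel)
  units <- panel_units(panel)
  pool <- units[[which]]
  min_n <- if (which == "treated") 3L else 3L
  if (length(pool) < min_n) {
    stop("leave-one-out over ", which, " units needs >= ", min_n,
         " such units, found ", length(pool))
  }
  log_scale <- isTRUE(attr(panel, "log_scale"))
  covs <- attr(panel, "covariates")
  t0 <- attr(panel, "treatment_start")
  fits <- lapply(pool, function(u) {
    sub_panel <- rebuild_panel(panel[panel$unit != u, , drop = FALSE],
                               covs, t0, log_scale)
    gscm(sub_panel, ...)
  })
  names(fits) <- pool
  att <- do.call(rbind, lapply(fits, function(f) f$result$att_by_year))
  structure(list(
    fits = fits, omitted = pool, which = which, att_by_year = att,
    mean_att = vapply(fits, function(f) mean(f$result$tau), numeric(1))
  ), class = "gscm_loo")
}

#' @export
print.gscm_loo <- function(x, ...) {
  cat(sprintf("gscm_loo: %d re-fits, each omitting one %s unit\n",
              length(x$fits), x$which))
  cat("mean post-period effect (log scale) by omission:\n")
  print(round(x$mean_att, 4))
  invisible(x)
}

#' In-time placebo estimation
#'
#' Falsification test pretending adoption happened at `pseudo_start`,
#' strictly before the true treatment start, using only data from before
#' the true start (later years are discarded so no genuinely treated
#' observation can contaminate the placebo). A detectable placebo "effect"
#' on such data signals estimator misspecification or spurious fit.
#'
#' @param panel a [panel_data()] with the true treatment start.
#' @param pseudo_start placebo adoption year (< true start).
#' @param ... arguments passed to [gscm()].
#' @return A [gscm()] object fitted on the truncated panel with
#'   `treatment_start = pseudo_start`; its `result$att_by_year` is the
#'   placebo ATT series.
#' @export
in_time_placebo <- function(panel, pseudo_start, ...) {
  validate_panel(panel)
  true_start <- attr(panel, "treatment_start")
  if (pseudo_start >= true_start) {
    stop("pseudo_start (", pseudo_start, ") must lie strictly before the ",
         "true treatment start (", true_start, ")")
  }
  years <- sort(unique(panel$year))
  n_pre <- sum(years < pseudo_start)
  if (n_pre < 3L) {
    stop("placebo needs >= 3 pretreatment years before ", pseudo_start,
         ", found ", n_pre)
  }
  keep_years <- years[years < true_start]
  if (!any(keep_years >= pseudo_start)) {
    stop("no post-placebo years remain after truncation at ", true_start)
  }
  sub_panel <- rebuild_panel(panel[panel$year < true_start, , drop = FALSE],
                             attr(panel, "covariates"), pseudo_start,
                             isTRUE(attr(panel, "log_scale")))
  gscm(sub_panel, ...)
}
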