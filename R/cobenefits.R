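#' Mean percent effect with confidence interval
#'
#' The headline effect: the unweighted mean of the unit-period effects over
#' treated units and post-treatment years, converted to percent. Two
#' conventions are supported for a log-outcome model: `"exp"` (default)
#' reports `100 * (exp(tau) - 1)`, the exact percent change on levels;
#' `"log"` reports `100 * tau` (log points). The interval applies the same
#' functional to the bootstrap draws of the mean effect.
#'
#' @param result a `gscm_result`.
#' @param bands a matching [parametric_bootstrap()] output (optional; omit
#'   for a point estimate only).
#' @param convention `"exp"` or `"log"` percent conversion.
#' @return A list: `mean_log` (log points), `mean_pct`, `ci_pct`
#'   (if bands supplied), `convention`, `level`.
#' @export
summarize_effects <- function(result, bands = NULL,
                              convention = c("exp", "log")) {
  stopifnot(inherits(result, "gscm_result"))
  convention <- match.arg(convention)
  to_pct <- function(tau) {
    if (convention == "exp") 100 * (exp(tau) - 1) else 100 * tau
  }
  mean_log <- mean(result$tau)
  out <- list(mean_log = mean_log, mean_pct = to_pct(mean_log),
              convention = convention)
  if (!is.null(bands)) {
    stopifnot(inherits(bands, "gscm_bootstrap"))
    if (!identical(bands$post_years, result$post_years)) {
      stop("bootstrap bands and result come from different runs ",
           "(post-treatment years differ)")
    }
    out$ci_log <- bands$mean_att_ci
    out$ci_pct <- to_pct(bands$mean_att_ci)
    out$level <- bands$level
  }
  out
}

#' Cumulative physical emission reductions
#'
#' Converts imputed counterfactuals into tons: per post-treatment year,
#' the sum over treated units of (counterfactual minus observed) levels; a
#' positive value means emissions were reduced relative to the
#' counterfactual. The total sums the per-year terms over the configured
#' window (default: all post years).
#'
#' @param result a `gscm_result` with level-scale counterfactuals.
#' @param window integer years to total over (default: all post-treatment
#'   years).
#' @return A list: `by_year` named vector of tons, `total` tons over the
#'   window, `window`.
#' @export
cumulative_reductions <- function(result, window = NULL) {
  stopifnot(inherits(result, "gscm_result"))
  post <- result$post_years
  if (is.null(window)) window <- post
  if (!all(window %in% post)) {
    stop("window years outside the post-treatment range: ",
         paste(setdiff(window, post), collapse = ", "))
  }
  idx <- match(post, result$years)
  by_year <- rowSums(result$y0_level[idx, , drop = FALSE] -
                       result$observed_level[idx, , drop = FALSE])
  names(by_year) <- post
  list(by_year = by_year,
       total = sum(by_year[as.character(window)]),
       window = window)
}

#' Reductions as a share of economy-wide emissions
#'
#' Expresses cumulative reductions relative to an observed economy-wide
#' emissions series over the same window: `100 * total / sum(economy)`.
#' The denominator is a separate input (the estimation panel covers only
#' the regulated/unregulated aggregates, not the whole economy).
#'
#' @param total_tons cumulative reduction in tons.
#' @param economy_series named numeric vector of economy-wide tons/year
#'   (names are years) covering the window.
#' @param window integer years.
#' @return Percent share (scalar).
#' @export
share_of_economy_wide <- function(total_tons, economy_series, window) {
  missing_years <- setdiff(as.character(window), names(economy_series))
  if (length(missing_years)) {
    stop("economy-wide series missing years: ",
         paste(missing_years, collapse = ", "))
  }
  denom <- sum(economy_series[as.character(window)])
  if (denom == 0) stop("economy-wide emissions sum to zero over the window")
  100 * total_tons / denom
}

#' Bound the contribution of jointly regulated combustion plants
#'
#' Overlapping emission standards for large combustion plants (LCPs) also
#' bite after the policy start, so part of the estimated joint reduction
#' may be theirs. Given observed LCP emissions E_t and the proportional
#' period effect ATT_t, the reduction ascribed to LCPs is
#' `Reductions_t = E_t / (1 - ATT_t) - E_t`: the gap between the
#' counterfactual LCP level implied by scaling observed emissions up by the
#' estimated effect and the observed level. With a negative ATT this is
#' negative — avoided emissions attributed to LCPs; its magnitude is the
#' `attributed_tons` used to discount joint benefits.
#'
#' @param att_by_year named numeric vector of post-period ATT (log scale by
#'   default; see `convention`).
#' @param lcp data.frame with columns `year` and `emissions` (tons of one
#'   pollutant from jointly regulated LCPs).
#' @param start_year first year of the bounding window (default 2008, when
#'   tightened LCP standards became binding).
#' @param convention `"exp"` (default) treats the ATT as the level-scale
#'   proportional effect `exp(att) - 1`; `"log"` uses the log-point value
#'   directly as a fraction, for sensitivity.
#' @return A list: `by_year` (signed Reductions_t, negative = avoided),
#'   `total` (signed sum), `attributed_tons` (= -total, positive when
#'   emissions were avoided), `convention`, `start_year`.
#' @export
bound_lcp <- function(att_by_year, lcp, start_year = 2008L,
                      convention = c("exp", "log")) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(lcp), all(c("year", "emissions") %in% names(lcp)))
  if (any(lcp$emissions < 0)) stop("LCP emissions must be >= 0")
  years <- intersect(as.integer(names(att_by_year)),
                     lcp$year[lcp$year >= start_year])
  if (!length(years)) stop("no overlap between ATT years >= ", start_year,
                           " and the LCP series")
  att <- att_by_year[as.character(years)]
  frac <- if (convention == "exp") exp(att) - 1 else att
  if (any(frac >= 1)) {
    stop("ATT_t >= 1 makes the bounding formula undefined (year ",
         paste(years[frac >= 1], collapse = ", "), ")")
  }
  e_t <- lcp$emissions[match(years, lcp$year)]
  by_year <- e_t / (1 - frac) - e_t
  names(by_year) <- years
  list(by_year = by_year, total = sum(by_year),
       attributed_tons = -sum(by_year),
       convention = convention, start_year = start_year)
}

#' Monetize emission reductions
#'
#' Linear damage-cost accounting: benefit = tons x configured cost per ton.
#' Cost factors are pure configuration (currency, price year, per-ton
#' values); no inflation arithmetic is performed internally.
#'
#' @param tons named numeric vector or single value of reduced tons per
#'   pollutant.
#' @param costs named list/vector of per-ton damage costs covering every
#'   pollutant in `tons`; an attached `currency`/`price_year` attribute or
#'   list entry is echoed through.
#' @return Named numeric vector of monetized benefits (same currency units
#'   as the cost factors).
#' @export
monetize <- function(tons, costs) {
  cost_vals <- unlist(costs[setdiff(names(costs), c("currency", "price_year"))])
  if (is.null(names(tons))) names(tons) <- names(cost_vals)[seq_along(tons)]
  missing_p <- setdiff(names(tons), names(cost_vals))
  if (length(missing_p)) {
    stop("no cost factor configured for: ", paste(missing_p, collapse = ", "))
  }
  if (any(cost_vals <= 0)) stop("cost factors must be > 0")
  tons * cost_vals[names(tons)]
}

#' Assemble a co-benefit report for one pollutant
#'
#' Ties the accounting steps together: mean percent effect with CI,
#' cumulative physical reductions, optional share of an economy-wide
#' series, and monetized Joint versus Bounded benefits, where Bounded
#' subtracts the benefit attributed to jointly regulated LCPs via
#' [bound_lcp()].
#'
#' @param result a `gscm_result`.
#' @param bands a [parametric_bootstrap()] output.
#' @param pollutant label (e.g. `"SO2"`).
#' @param cost_per_ton damage cost for this pollutant (currency/ton).
#' @param lcp optional LCP emissions data.frame (see [bound_lcp()]).
#' @param economy_series optional economy-wide series (see
#'   [share_of_economy_wide()]).
#' @param window reporting window (default all post years).
#' @param convention percent-effect convention, passed through.
#' @param lcp_start_year bounding window start (default 2008).
#' @return A `cobenefit_report` list with the fields above; invariantly
#'   `bounded_benefit == joint_benefit - lcp_attributed_benefit`.
#' @export
cobenefit_report <- function(result, bands = NULL, pollutant = "pollutant",
                             cost_per_ton = NULL, lcp = NULL,
                             economy_series = NULL, window = NULL,
                             convention = c("exp", "log"),
                             lcp_start_year = 2008L) {
  convention <- match.arg(convention)
  eff <- summarize_effects(result, bands, convention)
  red <- cumulative_reductions(result, window)
  rep_out <- list(
    pollutant = pollutant,
    mean_pct_effect = eff$mean_pct,
    ci_pct = eff$ci_pct,
    mean_log_effect = eff$mean_log,
    convention = convention,
    reductions_by_year = red$by_year,
    cumulative_reduction_tons = red$total,
    window = red$window,
    note = paste("level-scale counterfactuals are plain exponentials of",
                 "log-scale imputations; no retransformation (smearing)",
                 "correction is applied")
  )
  if (!is.null(economy_series)) {
    rep_out$share_of_economy_wide <-
      share_of_economy_wide(red$total, economy_series, red$window)
  }
  if (!is.null(cost_per_ton)) {
    costs <- stats::setNames(list(cost_per_ton), pollutant)
    rep_out$joint_benefit <-
      unname(monetize(stats::setNames(red$total, pollutant), costs))
    if (!is.null(lcp)) {
      att <- result$att_by_year
      bl <- bound_lcp(att, lcp, lcp_start_year, convention)
      rep_out$lcp_attributed_tons <- bl$attributed_tons
      rep_out$lcp_attributed_benefit <-
        unname(monetize(stats::setNames(bl$attributed_tons, pollutant), costs))
      rep_out$bounded_benefit <-
        rep_out$joint_benefit - rep_out$lcp_attributed_benefit
    }
  }
  structure(rep_out, class = "cobenefit_report")
}

#' @export
print.cobenefit_report <- function(x, ...) {
  cat("cobenefit_report:", x$pollutant, "\n")
  cat(sprintf("  mean effect: %.1f%%", x$mean_pct_effect))
  if (!is.null(x$ci_pct)) {
    cat(sprintf(" [%.1f%%, %.1f%%]", x$ci_pct[1], x$ci_pct[2]))
  }
  cat("\n")
  cat(sprintf("  cumulative reduction: %.4g tons over %d-%d\n",
              x$cumulative_reduction_tons, min(x$window), max(x$window)))
  if (!is.null(x$share_of_economy_wide)) {
    cat(sprintf("  share of economy-wide emissions: %.1f%%\n",
                x$share_of_economy_wide))
  }
  if (!is.null(x$joint_benefit)) {
    cat(sprintf("  joint benefit: %.4g", x$joint_benefit))
    if (!is.null(x$bounded_benefit)) {
      cat(sprintf(" | LCP-attributed: %.4g | bounded: %.4g",
                  x$lcp_attributed_benefit, x$bounded_benefit))
    }
    cat("\n")
  }
  invisible(x)
}
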