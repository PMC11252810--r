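#' Specify a synthetic emissions-panel data-generating process
#'
#' Defines the interactive fixed-effects DGP from which test panels are
#' simulated: on the log scale, outcomes are
#' `log y_it = alpha_i + X_it' beta + lambda_i' F_t + tau_t ETS_it + eps_it`,
#' exponentiated to strictly positive levels. The treatment effect `tau_t`
#' is applied only to treated units at or after `treatment_start`, so by
#' construction `log Y(1) - log Y(0) = tau_t` exactly for treated
#' unit-years.
#'
#' @param n_treated,n_control unit counts in the treated and control sets.
#' @param years inclusive integer year range.
#' @param treatment_start adoption year.
#' @param n_factors true factor count r (>= 0).
#' @param factor_type `"walk"` for random-walk (trending) factors, `"iid"`
#'   for independent innovations.
#' @param factor_scale standard deviation of factor innovations.
#' @param loading_scale standard deviation of unit loadings.
#' @param beta_true named numeric vector of covariate coefficients; names
#'   define the covariate set (use `log_gdp`, `log_gdp_sq`, `carbon_price`,
#'   `log_renewables` for the built-in covariate model).
#' @param tau_profile numeric vector of per-year log-scale treatment
#'   effects, one per post-treatment year (recycled if length 1).
#' @param noise_sd standard deviation of idiosyncratic shocks (> 0 required
#'   at generation; may be made arbitrarily small).
#' @param intercept_mean,intercept_sd distribution of unit intercepts on the
#'   log-tons scale.
#' @param confound loading-covariate correlation knob in [0, 1): the first
#'   loading is shifted by `confound * scale(mean log GDP)` so that factor
#'   confounding correlated with covariates can be simulated; 0 disables.
#' @param seed integer RNG seed; same seed implies a bit-identical panel.
#' @return A `dgp_spec` list.
#' @export
dgp_spec <- function(n_treated = 25L, n_control = 25L, years = 1990:2021,
                     treatment_start = 2005L, n_factors = 2L,
                     factor_type = c("walk", "iid"), factor_scale = 0.2,
                     loading_scale = 0.5,
                     beta_true = c(log_gdp = 0.5, log_gdp_sq = -0.01),
                     tau_profile = -0.4, noise_sd = 0.05,
                     intercept_mean = 12, intercept_sd = 0.5,
                     confound = 0, seed = 1L) {
  factor_type <- match.arg(factor_type)
  if (n_treated < 1L || n_control < 2L) {
    stop("need >= 1 treated and >= 2 control units")
  }
  if (length(years) < 3L || !all(diff(years) == 1L)) {
    stop("years must be a contiguous range of length >= 3")
  }
  if (n_factors < 0L) stop("n_factors must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  post_years <- years[years >= treatment_start]
  if (!length(post_years)) stop("no post-treatment years in range")
  if (length(tau_profile) == 1L) {
    tau_profile <- rep(tau_profile, length(post_years))
  }
  if (length(tau_profile) != length(post_years)) {
    stop("tau_profile must have one value per post-treatment year (",
         length(post_years), ")")
  }
  stopifnot(all(is.finite(c(factor_scale, loading_scale, beta_true,
                            tau_profile, noise_sd))))
  structure(list(
    n_treated = as.integer(n_treated), n_control = as.integer(n_control),
    years = as.integer(years), treatment_start = as.integer(treatment_start),
    n_factors = as.integer(n_factors), factor_type = factor_type,
    factor_scale = factor_scale, loading_scale = loading_scale,
    beta_true = beta_true, tau_profile = stats::setNames(tau_profile, post_years),
    noise_sd = noise_sd, intercept_mean = intercept_mean,
    intercept_sd = intercept_sd, confound = confound, seed = as.integer(seed)
  ), class = "dgp_spec")
}

#' Emissions-like default DGP
#'
#' A documented preset shaped like the EU-25 study design: 25 treated
#' (ETS-regulated) plus 25 control (unregulated) country aggregates,
#' 1990-2021, adoption in 2005, two trending common factors, covariates
#' log GDP and squared log GDP, and a declining treatment-effect profile
#' (from -0.05 to -0.85 log points across 2005-2021) mimicking a policy
#' whose bite grows as the emissions cap tightens.
#'
#' @param ... overrides passed to [dgp_spec()].
#' @return A `dgp_spec`.
#' @export
emissions_preset <- function(...) {
  defaults <- list(
    n_treated = 25L, n_control = 25L, years = 1990:2021,
    treatment_start = 2005L, n_factors = 2L, factor_type = "walk",
    factor_scale = 0.2, loading_scale = 0.5,
    beta_true = c(log_gdp = 0.5, log_gdp_sq = -0.01),
    tau_profile = seq(-0.05, -0.85, length.out = 17L),
    noise_sd = 0.05, seed = 1L
  )
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(dgp_spec, defaults)
}

# run expr under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic panel with known ground truth
#'
#' Simulates the factor model forward from a [dgp_spec()]. Covariates follow
#' unit-specific log-GDP random walks (drift 0.02, innovation sd 0.02,
#' initial level N(10, 0.5)); `carbon_price` is a binary indicator switched
#' on for a random half of units from a random year in 1995-2015;
#' `log_renewables` is an upward random walk. Factors are random walks or
#' i.i.d. innovations; loadings are i.i.d. normal, optionally correlated
#' with mean log GDP via the `confound` knob.
#'
#' @param spec a `dgp_spec`.
#' @return A `synthetic_panel` list: `panel` (a validated [panel_data()] on
#'   the level scale) and `truth` (realized factors `F`, loadings `lambda`,
#'   intercepts, `beta`, `tau` and the noise-free-treatment log
#'   counterfactual `y0_log`, a years x units matrix of log Y(0)).
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "dgp_spec"))
  with_seed(spec$seed, {
    years <- spec$years
    t_len <- length(years)
    n <- spec$n_treated + spec$n_control
    units <- c(sprintf("T%02d", seq_len(spec$n_treated)),
               sprintf("C%02d", seq_len(spec$n_control)))
    treated <- c(rep(TRUE, spec$n_treated), rep(FALSE, spec$n_control))

    covs <- names(spec$beta_true)
    lgdp <- matrix(0, t_len, n)
    lgdp[1, ] <- stats::rnorm(n, 10, 0.5)
    for (t in seq_len(t_len)[-1]) {
      lgdp[t, ] <- lgdp[t - 1, ] + stats::rnorm(n, 0.02, 0.02)
    }
    x_arr <- list()
    for (cv in covs) {
      x_arr[[cv]] <- switch(cv,
        log_gdp = lgdp,
        log_gdp_sq = lgdp^2,
        carbon_price = {
          on_unit <- stats::runif(n) < 0.5
          on_year <- sample(1995:2015, n, replace = TRUE)
          outer(years, seq_len(n),
                function(y, i) as.numeric(on_unit[i] & y >= on_year[i]))
        },
        log_renewables = {
          w <- matrix(0, t_len, n)
          w[1, ] <- stats::rnorm(n, 6, 1)
          for (t in seq_len(t_len)[-1]) {
            w[t, ] <- w[t - 1, ] + abs(stats::rnorm(n, 0.05, 0.05))
          }
          w
        },
        stop("no built-in covariate model for '", cv, "'")
      )
    }

    r <- spec$n_factors
    if (r > 0) {
      innov <- matrix(stats::rnorm(t_len * r, 0, spec$factor_scale), t_len, r)
      f <- if (spec$factor_type == "walk") apply(innov, 2, cumsum) else innov
      f <- matrix(f, t_len, r)
      lambda <- matrix(stats::rnorm(n * r, 0, spec$loading_scale), n, r)
      if (spec$confound > 0) {
        lambda[, 1] <- lambda[, 1] +
          spec$confound * as.numeric(scale(colMeans(lgdp)))
      }
      common <- f %*% t(lambda)
    } else {
      f <- matrix(0, t_len, 0)
      lambda <- matrix(0, n, 0)
      common <- matrix(0, t_len, n)
    }

    alpha <- stats::rnorm(n, spec$intercept_mean, spec$intercept_sd)
    xb <- matrix(0, t_len, n)
    for (cv in covs) xb <- xb + spec$beta_true[[cv]] * x_arr[[cv]]
    eps <- matrix(stats::rnorm(t_len * n, 0, spec$noise_sd), t_len, n)

    y0_log <- sweep(xb + common + eps, 2, alpha, `+`)
    tau_mat <- matrix(0, t_len, n)
    post_idx <- which(years >= spec$treatment_start)
    tau_mat[post_idx, treated] <- spec$tau_profile
    y1_log <- y0_log + tau_mat

    df <- data.frame(
      unit = rep(units, each = t_len),
      treated = rep(treated, each = t_len),
      year = rep(years, n),
      outcome = exp(as.vector(y1_log)),
      stringsAsFactors = FALSE
    )
    for (cv in covs) df[[cv]] <- as.vector(x_arr[[cv]])

    panel <- panel_data(df, covariates = covs,
                        treatment_start = spec$treatment_start)
    dimnames(y0_log) <- list(years, units)
    rownames(f) <- years
    rownames(lambda) <- units
    structure(list(
      panel = panel,
      truth = list(
        factors = f, lambda = lambda, alpha = stats::setNames(alpha, units),
        beta = spec$beta_true, tau = spec$tau_profile, y0_log = y0_log
      ),
      spec = spec
    ), class = "synthetic_panel")
  })
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("synthetic_panel (seed", x$spec$seed, ")\n")
  print(x$panel)
  cat("true factor count:", x$spec$n_factors,
      "| mean post-period tau:", round(mean(x$spec$tau_profile), 3), "\n")
  invisible(x)
}
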