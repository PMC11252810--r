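# Interactive fixed-effects estimation on control units: the additive and
# factor structure is profiled out in closed form and the covariate
# coefficients are found by quasi-Newton minimization of the profiled sum
# of squares. Internals operate on wide matrices (T years x N units) so
# that bootstrap refits avoid data-frame overhead; exported wrappers
# translate from panel_data.

# Two-way decomposition of a T x N matrix into grand mean, time effects,
# unit effects and a doubly demeaned remainder. On a balanced panel the
# remainder has exactly zero row and column means, so the additive part and
# any truncated SVD of the remainder are jointly least-squares optimal.
twoway_decompose <- function(m, force) {
  if (force == "none") {
    return(list(mu = 0, time = rep(0, nrow(m)), unit = rep(0, ncol(m)),
                resid = m))
  }
  mu <- mean(m)
  time_eff <- rowMeans(m) - mu
  unit_eff <- colMeans(m) - mu
  resid <- m - mu - outer(time_eff, rep(1, ncol(m))) -
    outer(rep(1, nrow(m)), unit_eff)
  list(mu = mu, time = time_eff, unit = unit_eff, resid = resid)
}

# Rank-r factor extraction with the normalization F'F/T = I_r and
# Lambda'Lambda diagonal (descending), from the SVD of the residual matrix.
extract_factors <- function(e, r) {
  t_len <- nrow(e)
  if (r == 0L) {
    return(list(f = matrix(0, t_len, 0), lambda = matrix(0, ncol(e), 0)))
  }
  sv <- svd(e, nu = r, nv = r)
  f <- sqrt(t_len) * sv$u
  lambda <- sv$v %*% diag(sv$d[seq_len(r)] / sqrt(t_len), r, r)
  list(f = f, lambda = lambda)
}

# Core joint least-squares solver. y: T x N outcomes (log scale); xs:
# list of K T x N covariate matrices. The inner problem (additive effects
# plus the rank-r factor structure, for fixed coefficients) has a closed
# form — two-way demeaning followed by a truncated SVD — so the profiled
# sum of squares is a smooth function of the K coefficients alone; it is
# minimized by quasi-Newton iteration (BFGS) with the envelope-theorem
# gradient -2<X_k, residual>. This follows curved, nearly flat valleys
# (collinear covariates whose effect the factors can partly mimic) that
# defeat plain alternating updates. Exact one-shot solutions are used
# where the problem is linear (no covariates, or r = 0 where the
# estimator reduces to the two-way within estimator), so those paths
# agree with direct OLS to machine precision.
ife_solve <- function(y, xs, r, force = c("two-way", "none"),
                    tol = 1e-10, max_iter = 2000L, beta_init = NULL) {
  force <- match.arg(force)
  t_len <- nrow(y); n <- ncol(y); k <- length(xs)
  if (r > min(n, t_len) - 1L) {
    stop("r = ", r, " too large for a ", t_len, " x ", n, " control block ",
         "(need r <= min(N_co, T) - 1)")
  }
  apply_beta <- function(beta) {
    acc <- matrix(0, t_len, n)
    for (j in seq_len(k)) acc <- acc + beta[j] * xs[[j]]
    acc
  }

  if (k == 0L) {
    dec <- twoway_decompose(y, force)
    fac <- extract_factors(dec$resid, r)
    fitted <- dec$mu + outer(dec$time, rep(1, n)) +
      outer(rep(1, t_len), dec$unit) + fac$f %*% t(fac$lambda)
    return(list(beta = numeric(0), mu = dec$mu, time = dec$time,
                unit = dec$unit, factors = fac$f, loadings = fac$lambda,
                fitted = fitted, resid = y - fitted,
                ssr = sum((y - fitted)^2), n_iterations = 1L,
                converged = TRUE, r = r, force = force))
  }

  if (r == 0L) {
    # exact two-way (or plain) within OLS
    yd <- twoway_decompose(y, force)$resid
    xd <- vapply(xs, function(x) as.vector(twoway_decompose(x, force)$resid),
                 numeric(t_len * n))
    beta <- as.numeric(qr.solve(qr(xd), as.vector(yd)))
    u <- y - apply_beta(beta)
    dec <- twoway_decompose(u, force)
    fitted <- apply_beta(beta) + dec$mu + outer(dec$time, rep(1, n)) +
      outer(rep(1, t_len), dec$unit)
    return(list(beta = beta, mu = dec$mu, time = dec$time, unit = dec$unit,
                factors = matrix(0, t_len, 0), loadings = matrix(0, n, 0),
                fitted = fitted, resid = y - fitted,
                ssr = sum((y - fitted)^2), n_iterations = 1L,
                converged = TRUE, r = 0L, force = force))
  }

  beta0 <- if (is.null(beta_init)) {
    yd <- twoway_decompose(y, force)$resid
    xd <- vapply(xs, function(x) as.vector(twoway_decompose(x, force)$resid),
                 numeric(t_len * n))
    as.numeric(qr.solve(qr(xd), as.vector(yd)))
  } else beta_init

  inner <- function(beta) {
    u <- y - apply_beta(beta)
    dec <- twoway_decompose(u, force)
    fac <- extract_factors(dec$resid, r)
    nonbeta <- dec$mu + outer(dec$time, rep(1, n)) +
      outer(rep(1, t_len), dec$unit) + fac$f %*% t(fac$lambda)
    list(resid = u - nonbeta, ssr = sum((u - nonbeta)^2),
         dec = dec, fac = fac, nonbeta = nonbeta)
  }
  fn <- function(b) inner(b)$ssr
  gr <- function(b) {
    rs <- inner(b)$resid
    -2 * vapply(xs, function(x) sum(x * rs), numeric(1))
  }
  # BFGS with deterministic restarts: near singular-value crossings the
  # profiled objective has kinks that can spoil the accumulated Hessian
  # approximation; restarting from the current point usually resolves it.
  # A derivative-free polish is the last resort before giving up.
  opt <- list(par = beta0, convergence = 1L)
  n_evals <- 0L
  for (attempt in 1:3) {
    opt <- stats::optim(opt$par, fn, gr, method = "BFGS",
                        control = list(maxit = max_iter, reltol = tol))
    n_evals <- n_evals + unname(opt$counts["function"])
    if (opt$convergence == 0L) break
  }
  if (opt$convergence != 0L) {
    opt <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                        control = list(maxit = max_iter, reltol = tol))
    n_evals <- n_evals + unname(opt$counts["function"])
  }
  if (opt$convergence != 0L) {
    stop("factor-model estimation did not converge within ", max_iter,
         " iterations per attempt (objective ", signif(opt$value, 6),
         ", optim code ", opt$convergence, ")")
  }
  beta <- opt$par
  st <- inner(beta)
  dec <- st$dec
  fac <- st$fac
  fitted <- apply_beta(beta) + st$nonbeta
  list(beta = beta, mu = dec$mu, time = dec$time, unit = dec$unit,
       factors = fac$f, loadings = fac$lambda, fitted = fitted,
       resid = y - fitted, ssr = st$ssr,
       n_iterations = n_evals,
       converged = TRUE, r = r, force = force)
}

# Least-squares projection of held-out units onto an estimated factor
# structure using the rows in `fit_idx`: regress (y - X beta - mu - xi_t)
# on an intercept (if additive effects are on) and the factors, returning
# per-unit intercepts, loadings and predictions for all rows.
project_units <- function(core, y, xs, fit_idx) {
  t_len <- nrow(y); n <- ncol(y); r <- core$r
  k <- length(core$beta)
  xb <- matrix(0, t_len, n)
  for (j in seq_len(k)) xb <- xb + core$beta[j] * xs[[j]]
  w <- y - xb - core$mu - outer(core$time, rep(1, n))
  has_int <- core$force != "none"
  z <- cbind(if (has_int) rep(1, t_len), core$factors)
  p <- ncol(z)
  if (p > 0 && length(fit_idx) < p) {
    stop("need at least ", p, " fitting periods for ", r,
         " factors, have ", length(fit_idx))
  }
  if (p > 0) {
    zf <- z[fit_idx, , drop = FALSE]
    coefs <- qr.solve(qr(zf), w[fit_idx, , drop = FALSE])
    coefs <- matrix(coefs, nrow = p)
    pred <- xb + core$mu + outer(core$time, rep(1, n)) + z %*% coefs
    alpha <- if (has_int) coefs[1, ] else rep(0, n)
    lam_rows <- if (has_int) seq_len(r) + 1L else seq_len(r)
    lambda <- if (r > 0L) t(coefs[lam_rows, , drop = FALSE]) else matrix(0, n, 0)
  } else {
    pred <- xb
    alpha <- rep(0, n)
    lambda <- matrix(0, n, 0)
  }
  resid_fit <- (y - pred)[fit_idx, , drop = FALSE]
  list(alpha = alpha, lambda = lambda, pred = pred, resid_fit = resid_fit,
       rmse_fit = sqrt(colMeans(resid_fit^2)))
}

# Assemble matrices for a panel fit
panel_matrices <- function(panel, covariates) {
  absent <- setdiff(covariates, names(panel))
  if (length(absent)) {
    stop("covariates not present in the panel: ",
         paste(absent, collapse = ", "))
  }
  panel <- log_transform(panel)
  units <- panel_units(panel)
  years <- sort(unique(panel$year))
  t0 <- attr(panel, "treatment_start")
  list(
    yc = panel_matrix(panel, "outcome", units$control),
    yt = panel_matrix(panel, "outcome", units$treated),
    xc = lapply(covariates, function(cv) panel_matrix(panel, cv, units$control)),
    xt = lapply(covariates, function(cv) panel_matrix(panel, cv, units$treated)),
    years = years, pre_idx = which(years < t0), post_idx = which(years >= t0),
    units = units, treatment_start = t0
  )
}

#' Fit the interactive fixed-effects model on control units
#'
#' Step one of the generalized synthetic control method: on control units
#' only, jointly estimates covariate coefficients and r common factors with
#' unit loadings by nested least squares. For fixed coefficients the inner
#' problem is solved exactly — additive unit/time effects by two-way
#' demeaning, the factor structure by a truncated SVD of the demeaned
#' residual matrix — so the profiled sum of squares depends only on the
#' few covariate coefficients, which are found by quasi-Newton (BFGS)
#' minimization with an analytic gradient. Initialization is deterministic
#' (within-OLS coefficients), so fits are reproducible without a seed.
#' Factors are normalized to F'F/T = I with loadings orthogonal (diagonal
#' cross-product).
#'
#' @param panel a [panel_data()]; logged internally if still on levels.
#' @param r number of factors (>= 0, at most `min(N_co, T) - 1`).
#' @param covariates covariate set to include (default: the panel's).
#' @param force `"two-way"` (default) for additive unit and time intercepts
#'   alongside the factors, `"none"` for the bare factor model.
#' @param tol relative objective-change convergence tolerance of the outer
#'   quasi-Newton minimization.
#' @param max_iter outer iteration cap; non-convergence is an error
#'   carrying the last objective value.
#' @return An `ife_fit`: coefficients `beta`, `factors` (T x r), control
#'   `loadings`, additive effects (`mu`, `time`, `unit`), residuals,
#'   convergence diagnostics, and bookkeeping (years, unit ids, covariates).
#' @export
fit_ife_controls <- function(panel, r, covariates = attr(panel, "covariates"),
                             force = c("two-way", "none"), tol = 1e-10,
                             max_iter = 2000L) {
  force <- match.arg(force)
  validate_panel(panel)
  mats <- panel_matrices(panel, covariates)
  core <- ife_solve(mats$yc, mats$xc, r, force, tol, max_iter)
  build_ife_fit(core, mats, covariates)
}

build_ife_fit <- function(core, mats, covariates, mspe_by_r = NULL) {
  fit <- core
  names(fit$beta) <- covariates
  rownames(fit$factors) <- mats$years
  rownames(fit$loadings) <- mats$units$control
  names(fit$time) <- mats$years
  names(fit$unit) <- mats$units$control
  dimnames(fit$resid) <- list(mats$years, mats$units$control)
  fit$covariates <- covariates
  fit$years <- mats$years
  fit$control_units <- mats$units$control
  fit$treatment_start <- mats$treatment_start
  fit$mspe_by_r <- mspe_by_r
  class(fit) <- "ife_fit"
  fit
}

#' @export
print.ife_fit <- function(x, ...) {
  cat(sprintf(
    "ife_fit: r = %d, force = %s, %d control units x %d years\n",
    x$r, x$force, length(x$control_units), length(x$years)
  ))
  if (length(x$beta)) {
    cat("beta:\n"); print(round(x$beta, 4))
  } else cat("beta: (no covariates)\n")
  cat(sprintf("converged in %d iterations (SSR %.6g)\n",
              x$n_iterations, x$ssr))
  if (!is.null(x$mspe_by_r)) {
    cat("cross-validation MSPE by r:\n"); print(signif(x$mspe_by_r, 4))
  }
  invisible(x)
}

# Leave-one-pretreatment-period-out MSPE for one candidate r, given
# matrices. Fits controls once on all years; for each held-out pretreatment
# year, treated loadings are re-estimated on the remaining pretreatment
# years and the held-out year is predicted.
cv_mspe_r <- function(mats, r, force, tol, max_iter) {
  core <- ife_solve(mats$yc, mats$xc, r, force, tol, max_iter)
  pre <- mats$pre_idx
  errs <- vapply(pre, function(s) {
    proj <- project_units(core, mats$yt, mats$xt, setdiff(pre, s))
    mean((mats$yt[s, ] - proj$pred[s, ])^2)
  }, numeric(1))
  list(core = core, mspe = mean(errs))
}

#' Cross-validate the number of factors
#'
#' Selects r by the leave-one-pretreatment-period-out scheme: for each
#' candidate, the factor model is fitted on control units over all years,
#' then each pretreatment year of the treated units is held out in turn,
#' loadings are re-estimated from the remaining pretreatment years, and the
#' held-out year is predicted. The candidate minimizing the mean squared
#' prediction error wins; ties break toward smaller r (parsimony).
#' Candidates infeasible for the panel's dimensions (too few pretreatment
#' years or control units) are dropped; if none remain, an error is raised.
#'
#' @inheritParams fit_ife_controls
#' @param candidates integer vector of candidate factor counts
#'   (default 0-5).
#' @return An `ife_fit` for the selected r, with `mspe_by_r` recording the
#'   MSPE of every feasible candidate.
#' @export
cross_validate_r <- function(panel, candidates = 0:5,
                             covariates = attr(panel, "covariates"),
                             force = c("two-way", "none"), tol = 1e-10,
                             max_iter = 2000L) {
  force <- match.arg(force)
  validate_panel(panel)
  if (!length(candidates)) stop("candidates must be non-empty")
  mats <- panel_matrices(panel, covariates)
  n_pre <- length(mats$pre_idx)
  if (n_pre < 3L) stop("cross-validation needs >= 3 pretreatment periods")
  candidates <- sort(unique(as.integer(candidates)))
  n_par <- function(r) r + as.integer(force != "none")
  feasible <- candidates[candidates <= min(ncol(mats$yc), length(mats$years)) - 1L &
                           n_par(candidates) <= n_pre - 1L]
  if (!length(feasible)) {
    stop("no candidate factor count is feasible for this panel (",
         n_pre, " pretreatment years, ", ncol(mats$yc), " controls)")
  }
  mspe <- stats::setNames(rep(NA_real_, length(feasible)), feasible)
  cores <- vector("list", length(feasible))
  for (j in seq_along(feasible)) {
    cvj <- cv_mspe_r(mats, feasible[j], force, tol, max_iter)
    mspe[j] <- cvj$mspe
    cores[[j]] <- cvj$core
  }
  best <- which.min(mspe)  # candidates ascending: ties resolve to smaller r
  build_ife_fit(cores[[best]], mats, covariates, mspe_by_r = mspe)
}
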