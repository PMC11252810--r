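#' Construct a validated emissions panel
#'
#' A `panel_data` object is a long-format data frame with one row per
#' unit-year, holding a strictly positive outcome (emissions in tons/year),
#' a treated-unit flag, and named covariate columns. Treatment switches on
#' for treated units from `treatment_start` onwards (default 2005, the first
#' trading period of the EU ETS); the pre/post split is purely on calendar
#' year, which also supports in-time placebos that shift the start earlier.
#'
#' The panel must be balanced: every unit has exactly one row for every year
#' of a contiguous range. No missing-data handling is offered — the
#' estimator requires a complete panel and no imputation rule is invented.
#'
#' @param data data.frame with columns `unit`, `treated`, `year`, `outcome`
#'   plus any covariate columns.
#' @param covariates character vector of covariate column names (may be
#'   empty).
#' @param treatment_start integer year at which treatment begins for treated
#'   units.
#' @return A `panel_data` object: the input data.frame, sorted by
#'   (unit, year), with attributes `covariates`, `treatment_start`,
#'   `log_scale` and a computed integer column `ets` (the treatment
#'   indicator, 1 iff treated and year >= treatment_start).
#' @examples
#' df <- expand.grid(unit = c("a", "b", "c"), year = 2000:2009)
#' df$treated <- df$unit == "a"
#' df$outcome <- exp(rnorm(nrow(df)))
#' pd <- panel_data(df, covariates = character(), treatment_start = 2005)
#' @export
panel_data <- function(data, covariates = character(), treatment_start = 2005L) {
  stopifnot(is.data.frame(data))
  required <- c("unit", "treated", "year", "outcome")
  missing_cols <- setdiff(c(required, covariates), names(data))
  if (length(missing_cols)) {
    stop("panel is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$unit <- as.character(data$unit)
  data$treated <- as.logical(data$treated)
  data$year <- as.integer(data$year)
  data <- data[order(data$unit, data$year), , drop = FALSE]
  rownames(data) <- NULL
  data$ets <- as.integer(data$treated & data$year >= treatment_start)
  obj <- structure(
    data,
    covariates = covariates,
    treatment_start = as.integer(treatment_start),
    log_scale = FALSE,
    class = c("panel_data", "data.frame")
  )
  validate_panel(obj)
  obj
}

#' Validate panel invariants
#'
#' Checks balance (one row per unit-year over a contiguous year range),
#' strict positivity of the outcome on the level scale, completeness of
#' covariate cells, presence of at least two control units, and at least two
#' pretreatment periods for treated units. Errors name the offending units,
#' years or rows.
#'
#' @param panel a `panel_data` object.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_data"))
  years <- sort(unique(panel$year))
  if (!all(diff(years) == 1L)) {
    stop("year range is not contiguous: ", paste(years, collapse = ", "))
  }
  tab <- table(panel$unit, panel$year)
  if (any(tab != 1L)) {
    bad <- which(tab != 1L, arr.ind = TRUE)
    stop(
      "panel is not balanced; offending (unit, year) cells: ",
      paste(sprintf(
        "(%s, %s: %d rows)",
        rownames(tab)[bad[, 1]], colnames(tab)[bad[, 2]],
        tab[bad]
      ), collapse = ", ")
    )
  }
  if (!isTRUE(attr(panel, "log_scale")) && any(panel$outcome <= 0, na.rm = TRUE)) {
    bad <- which(panel$outcome <= 0)
    stop(
      "outcome must be strictly positive (log transform undefined); rows: ",
      paste(utils::head(bad, 5), collapse = ", ")
    )
  }
  if (anyNA(panel$outcome)) stop("outcome contains missing values")
  for (cv in attr(panel, "covariates")) {
    if (anyNA(panel[[cv]])) {
      stop("covariate '", cv, "' has missing cells (no imputation is performed)")
    }
  }
  treated_units <- unique(panel$unit[panel$treated])
  control_units <- unique(panel$unit[!panel$treated])
  if (length(control_units) < 2L) {
    stop("need at least 2 control units, found ", length(control_units))
  }
  t0 <- attr(panel, "treatment_start")
  n_pre <- sum(years < t0)
  if (length(treated_units) && n_pre < 2L) {
    stop("treated units need >= 2 pretreatment periods, found ", n_pre)
  }
  ets <- as.integer(panel$treated & panel$year >= t0)
  if (!identical(ets, panel$ets)) stop("treatment indicator is inconsistent")
  invisible(TRUE)
}

#' Read an emissions panel from delimited text
#'
#' Reads a long-format CSV and returns a validated [panel_data()]. A `schema`
#' mapping lets exports with arbitrary headers (e.g. inventory-derived
#' files) be consumed without renaming upstream: names are the canonical
#' column names (`unit`, `treated`, `year`, `outcome`, covariate names),
#' values the column names in the file.
#'
#' @param path CSV file path (UTF-8, header row).
#' @param covariates canonical covariate names to retain.
#' @param schema named character vector mapping canonical -> file column
#'   names; canonical names absent from the schema are taken verbatim.
#' @param treatment_start integer adoption year.
#' @return A validated `panel_data`.
#' @export
read_panel <- function(path, covariates = character(), schema = NULL,
                       treatment_start = 2005L) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  canonical <- c("unit", "treated", "year", "outcome", covariates)
  for (cn in canonical) {
    src <- if (!is.null(schema) && cn %in% names(schema)) schema[[cn]] else cn
    if (!src %in% names(raw)) {
      stop("column '", src, "' (for '", cn, "') not found in ", path)
    }
    if (src != cn) raw[[cn]] <- raw[[src]]
  }
  panel_data(raw[canonical], covariates = covariates,
             treatment_start = treatment_start)
}

#' Write a panel back to CSV
#'
#' Inverse of [read_panel()]: writes the canonical columns so that a
#' read/write round trip is the identity on validated datasets.
#'
#' @param panel a `panel_data`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_data"))
  cols <- c("unit", "treated", "year", "outcome", attr(panel, "covariates"))
  df <- as.data.frame(panel)[cols]
  # serialize doubles at full precision so read/write round-trips exactly
  for (cl in cols) {
    if (is.double(df[[cl]])) df[[cl]] <- sprintf("%.17g", df[[cl]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Log-transform the outcome
#'
#' Replaces the outcome by its natural log, keeping the original levels in
#' an `outcome_level` column for later back-transformation of
#' counterfactuals to tons. The factor model is specified on log outcomes,
#' so treatment effects are multiplicative on levels.
#'
#' @param panel a `panel_data` on the level scale.
#' @return The panel with `outcome = log(outcome)` and attribute
#'   `log_scale = TRUE`.
#' @export
log_transform <- function(panel) {
  stopifnot(inherits(panel, "panel_data"))
  if (attr(panel, "log_scale")) return(panel)
  if (any(panel$outcome <= 0)) stop("outcome must be strictly positive")
  panel$outcome_level <- panel$outcome
  panel$outcome <- log(panel$outcome)
  attr(panel, "log_scale") <- TRUE
  panel
}

#' @export
print.panel_data <- function(x, ...) {
  t0 <- attr(x, "treatment_start")
  cat(sprintf(
    "panel_data: %d units (%d treated) x %d years (%d-%d), treatment from %d\n",
    length(unique(x$unit)), length(unique(x$unit[x$treated])),
    length(unique(x$year)), min(x$year), max(x$year), t0
  ))
  cat("covariates:",
      if (length(attr(x, "covariates"))) paste(attr(x, "covariates"), collapse = ", ")
      else "(none)", "\n")
  cat("outcome scale:", if (attr(x, "log_scale")) "log" else "levels", "\n")
  invisible(x)
}

# Internal: rebuild a level-scale panel_data from (possibly subsetted or
# logged) panel rows, optionally overriding the treatment start.
rebuild_panel <- function(rows, covariates, treatment_start, log_scale = FALSE) {
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (log_scale) df$outcome <- df$outcome_level
  df <- df[c("unit", "treated", "year", "outcome", covariates)]
  panel_data(df, covariates = covariates, treatment_start = treatment_start)
}

# Internal: wide T x N matrix of a panel column for the given units.
# Rows are years in ascending order; columns follow `units` order.
panel_matrix <- function(panel, column, units) {
  years <- sort(unique(panel$year))
  m <- matrix(NA_real_, nrow = length(years), ncol = length(units),
              dimnames = list(years, units))
  idx <- cbind(match(panel$year, years), match(panel$unit, units))
  keep <- !is.na(idx[, 2])
  m[idx[keep, , drop = FALSE]] <- panel[[column]][keep]
  m
}

# Internal: split unit ids by treatment status
panel_units <- function(panel) {
  u <- unique(panel[, c("unit", "treated")])
  list(
    treated = sort(u$unit[u$treated]),
    control = sort(u$unit[!u$treated])
  )
}
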