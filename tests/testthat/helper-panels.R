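# Small fixture builders shared across tests.

# Fully specified tiny panel: n_units x n_years, deterministic outcomes.
toy_panel <- function(n_treated = 1, n_control = 3, years = 2000:2005,
                      treatment_start = 2003, outcome_fun = NULL,
                      covariates = character()) {
  units <- c(sprintf("T%d", seq_len(n_treated)),
             sprintf("C%d", seq_len(n_control)))
  df <- expand.grid(unit = units, year = years, stringsAsFactors = FALSE)
  df$treated <- df$unit %in% sprintf("T%d", seq_len(n_treated))
  if (is.null(outcome_fun)) {
    outcome_fun <- function(u, y) exp(1 + 0.1 * (y - min(years)) +
                                        0.05 * match(u, units))
  }
  df$outcome <- mapply(outcome_fun, df$unit, df$year)
  for (cv in covariates) df[[cv]] <- stats::rnorm(nrow(df))
  panel_data(df, covariates = covariates, treatment_start = treatment_start)
}

# Small fast DGP for estimator tests (8 controls, 4 treated, 16 years)
small_spec <- function(...) {
  emissions_preset(n_treated = 4, n_control = 8, years = 2000:2015,
                   treatment_start = 2010,
                   tau_profile = -0.4, ...)
}
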