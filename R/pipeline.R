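# Pipeline orchestration: one declarative configuration drives
# simulate -> fit -> bootstrap -> report, with a run manifest recording
# settings, input digests and seeds so a run can be reproduced exactly.

covariate_sets <- list(
  none = character(0),
  main = c("log_gdp", "log_gdp_sq"),
  `additional-policies` = c("log_gdp", "log_gdp_sq", "carbon_price",
                            "log_renewables")
)

#' Resolve a named covariate set
#'
#' Three model specifications are predefined: `"none"` (bare factor
#' model), `"main"` (log GDP and squared log GDP), and
#' `"additional-policies"` (adds a binary carbon-pricing indicator and log
#' renewable electricity production). A character vector is passed through
#' as an explicit covariate list.
#'
#' @param set name of a predefined set, or a character vector of column
#'   names.
#' @return Character vector of covariate column names.
#' @export
resolve_covariate_set <- function(set) {
  if (length(set) == 1L && set %in% names(covariate_sets)) {
    return(covariate_sets[[set]])
  }
  as.character(set)
}

# md5 of an R object via its canonical JSON serialization (config hashing)
hash_object <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

default_config <- function() {
  list(
    seed = 1L,
    simulate = list(preset = "emissions", overrides = list()),
    input = NULL,
    fit = list(covariate_set = "main", r = NULL, candidates = 0:5,
               force = "two-way"),
    bootstrap = list(n_reps = 200L, level = 0.95, resample = "unit-block"),
    report = list(pollutant = "pollutant", cost_per_ton = NULL, lcp = NULL,
                  economy = NULL, window = NULL, convention = "exp",
                  lcp_start_year = 2008L),
    plot = list(enabled = FALSE, format = "pdf")
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  merge_config(default_config(), config)
}

read_series_csv <- function(path, value_col = "emissions") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("year", value_col) %in% names(df)))
  df
}

#' Run the full estimation-and-reporting pipeline
#'
#' Executes the configured stages in order — simulate (or load an input
#' panel), fit, bootstrap, report — writing every stage's output plus a
#' run manifest to `out_dir`. Any stage error aborts with the stage name
#' attached. Outputs: `panel.csv` (and `truth.csv` when simulated),
#' `att.csv`, `tau.csv`, `bands.csv`, `draws.csv`, `report.json`,
#' `manifest.json`, and figures when plotting is enabled. `report.json` is
#' deterministic given the configuration and seeds (timestamps live only
#' in the manifest).
#'
#' @param config nested configuration list, or path to a YAML file with
#'   the same structure; omitted keys take documented defaults. Top-level
#'   keys: `seed`, `simulate` (preset + DGP overrides) or `input`
#'   (`panel` CSV path, `covariates`, `schema`, `treatment_start`), `fit`
#'   (`covariate_set`, `r`, `candidates`, `force`), `bootstrap`
#'   (`n_reps`, `level`, `resample`), `report` (`pollutant`,
#'   `cost_per_ton`, `lcp` CSV path or data.frame, `economy` CSV path or
#'   named vector, `window`, `convention`, `lcp_start_year`), `plot`
#'   (`enabled`, `format`).
#' @param out_dir output directory (created if missing).
#' @param stages which stages to run (fit is always implied by later
#'   stages).
#' @return Invisibly, a list with the fitted `gscm` object, `bands`,
#'   `report`, `manifest` and `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("gscoben_run_"),
                         stages = c("simulate", "fit", "bootstrap",
                                    "report")) {
  cfg <- load_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(
    config_hash = hash_object(cfg),
    settings = cfg,
    package_version = as.character(utils::packageVersion("gscoben")),
    timestamp = format(Sys.time(), tz = "UTC"),
    input_digests = list()
  )

  truth <- NULL
  if (!is.null(cfg$input)) {
    panel <- stage("input", {
      manifest$input_digests$panel <-
        unname(tools::md5sum(cfg$input$panel))
      read_panel(cfg$input$panel,
                 covariates = resolve_covariate_set(
                   cfg$input$covariates %||% cfg$fit$covariate_set),
                 schema = cfg$input$schema,
                 treatment_start = cfg$input$treatment_start %||% 2005L)
    })
  } else if ("simulate" %in% stages) {
    sim <- stage("simulate", {
      ov <- cfg$simulate$overrides
      ov$seed <- ov$seed %||% cfg$seed
      sp <- do.call(emissions_preset, ov)
      generate_panel(sp)
    })
    panel <- sim$panel
    truth <- sim$truth
    write_panel(panel, file.path(out_dir, "panel.csv"))
    utils::write.csv(
      data.frame(year = as.integer(names(truth$tau)), tau_true = truth$tau,
                 row.names = NULL),
      file.path(out_dir, "truth.csv"), row.names = FALSE
    )
  } else {
    stop("no input panel configured and simulate stage not requested")
  }

  need_fit <- any(c("fit", "bootstrap", "report") %in% stages)
  if (!need_fit) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    return(invisible(list(panel = panel, truth = truth, manifest = manifest,
                          out_dir = out_dir)))
  }

  covs <- resolve_covariate_set(cfg$fit$covariate_set)
  fit_obj <- stage("fit", {
    gscm(panel, r = cfg$fit$r,
         candidates = cfg$fit$candidates %||% 0:5,
         covariates = covs, force = cfg$fit$force %||% "two-way")
  })
  res <- fit_obj$result
  utils::write.csv(
    data.frame(year = res$post_years, att_log = res$att_by_year,
               att_pct_exp = 100 * (exp(res$att_by_year) - 1),
               row.names = NULL),
    file.path(out_dir, "att.csv"), row.names = FALSE
  )
  tau_df <- data.frame(
    year = rep(res$post_years, ncol(res$tau)),
    unit = rep(colnames(res$tau), each = nrow(res$tau)),
    tau_log = as.vector(res$tau), row.names = NULL
  )
  utils::write.csv(tau_df, file.path(out_dir, "tau.csv"), row.names = FALSE)

  bands <- NULL
  if ("bootstrap" %in% stages) {
    bands <- stage("bootstrap", {
      parametric_bootstrap(fit_obj, n_reps = cfg$bootstrap$n_reps,
                           level = cfg$bootstrap$level,
                           seed = cfg$seed,
                           resample = cfg$bootstrap$resample)
    })
    utils::write.csv(
      data.frame(year = bands$years, ci_lower = bands$ci_lower,
                 ci_upper = bands$ci_upper, row.names = NULL),
      file.path(out_dir, "bands.csv"), row.names = FALSE
    )
    utils::write.csv(as.data.frame(bands$att_draws),
                     file.path(out_dir, "draws.csv"), row.names = FALSE)
  }

  report <- NULL
  if ("report" %in% stages) {
    report <- stage("report", {
      rc <- cfg$report
      lcp <- rc$lcp
      if (is.character(lcp)) {
        manifest$input_digests$lcp <- unname(tools::md5sum(lcp))
        lcp <- read_series_csv(lcp)
      }
      economy <- rc$economy
      if (is.character(economy) && file.exists(economy[1])) {
        manifest$input_digests$economy <- unname(tools::md5sum(economy))
        edf <- read_series_csv(economy)
        economy <- stats::setNames(edf$emissions, edf$year)
      }
      cobenefit_report(res, bands, pollutant = rc$pollutant,
                       cost_per_ton = rc$cost_per_ton, lcp = lcp,
                       economy_series = economy, window = rc$window,
                       convention = rc$convention %||% "exp",
                       lcp_start_year = rc$lcp_start_year %||% 2008L)
    })
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }

  if (isTRUE(cfg$plot$enabled)) {
    stage("plot", {
      plot_paths(res, bands, out_dir = out_dir,
                 format = cfg$plot$format %||% "pdf")
    })
  }

  manifest$selected_r <- fit_obj$fit$r
  manifest$mspe_by_r <- as.list(fit_obj$fit$mspe_by_r)
  manifest$converged <- fit_obj$fit$converged
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(gscm = fit_obj, bands = bands, report = report,
                 truth = truth, manifest = manifest, out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot emission paths and the ATT series
#'
#' Two-panel display: observed versus imputed counterfactual emission
#' levels averaged across treated units (with a vertical marker at the
#' treatment start), and the ATT series in percent with its shaded
#' confidence band.
#'
#' @param result a `gscm_result`.
#' @param bands optional [parametric_bootstrap()] output for the shaded
#'   band.
#' @param out_dir if non-NULL, figures are also written there.
#' @param format vector graphics format, `"pdf"` (default) or `"svg"`.
#' @return A list of two ggplot objects (`paths`, `att`), invisibly when
#'   writing files.
#' @export
plot_paths <- function(result, bands = NULL, out_dir = NULL,
                       format = c("pdf", "svg")) {
  stopifnot(inherits(result, "gscm_result"))
  format <- match.arg(format)
  years <- result$years
  df_paths <- rbind(
    data.frame(year = years, emissions = rowMeans(result$observed_level),
               series = "observed"),
    data.frame(year = years, emissions = rowMeans(result$y0_level),
               series = "counterfactual")
  )
  p_paths <- ggplot2::ggplot(
    df_paths, ggplot2::aes(x = .data$year, y = .data$emissions,
                           colour = .data$series)
  ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = result$treatment_start,
                        linetype = "solid") +
    ggplot2::scale_colour_manual(
      values = c(observed = "black", counterfactual = "darkorange")) +
    ggplot2::labs(x = NULL, y = "emissions (tons/year, mean of treated)",
                  colour = NULL, title = "Observed vs. counterfactual") +
    ggplot2::theme_minimal()

  df_att <- data.frame(year = years,
                       att = 100 * (exp(result$att_all_years) - 1))
  if (!is.null(bands)) {
    df_att$lo <- 100 * (exp(bands$ci_lower) - 1)
    df_att$hi <- 100 * (exp(bands$ci_upper) - 1)
  }
  p_att <- ggplot2::ggplot(df_att, ggplot2::aes(x = .data$year,
                                                y = .data$att)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_vline(xintercept = result$treatment_start,
                        linetype = "solid")
  if (!is.null(bands)) {
    p_att <- p_att +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           fill = "steelblue", alpha = 0.25)
  }
  p_att <- p_att +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = NULL, y = "ATT (%)",
                  title = "Estimated treatment effect") +
    ggplot2::theme_minimal()

  plots <- list(paths = p_paths, att = p_att)
  if (!is.null(out_dir)) {
    dev <- if (format == "svg") grDevices::svg else grDevices::cairo_pdf
    for (nm in names(plots)) {
      ggplot2::ggsave(
        file.path(out_dir, paste0(nm, ".", format)), plots[[nm]],
        device = dev, width = 7, height = 4.5
      )
    }
    return(invisible(plots))
  }
  plots
}
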