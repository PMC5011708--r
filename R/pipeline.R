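# End-to-end workflow: simulate or load a spectrum set, run the global fit
# and the model-free dispersion analysis, and write tidy artifacts to disk.

pipeline_known_keys <- c("input", "simulate", "resolution_fwhm_meV",
                         "resolution_table", "seed", "outdir", "fit",
                         "dispersion", "label", "verbosity")

#' Run configuration
#'
#' Builds (and validates) the configuration driving [run_pipeline()].
#' Exactly one of `input` (a spectrum-set TSV path) or `simulate` (a list
#' with `scenario` and optionally `noise`, `counts_per_spectrum`) must be
#' given. Unknown keys are rejected.
#'
#' @param ... configuration entries; see Details.
#' @details Recognized keys: `input`, `simulate`, `resolution_fwhm_meV`,
#'   `resolution_table` (path), `seed` (non-negative integer), `outdir`,
#'   `fit` (list passed to [fit_global()]: `init`, `fixed`, `n_starts`),
#'   `dispersion` (list: `n_lorentzians`), `label`, `verbosity`.
#' @return a validated config list of class `qens_config`.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) == 1 && is.null(names(cfg)) && is.list(cfg[[1]])) cfg <- cfg[[1]]
  unknown <- setdiff(names(cfg), pipeline_known_keys)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulate)
  if (has_input == has_sim) {
    abort("Exactly one of `input` or `simulate` must be specified.")
  }
  if (has_input && !file.exists(cfg$input)) {
    abort(sprintf("Input file does not exist: %s", cfg$input))
  }
  if (has_sim && is.null(cfg$simulate$scenario)) {
    abort("`simulate` needs a `scenario` entry.")
  }
  cfg$seed <- cfg$seed %||% 1L
  if (cfg$seed < 0 || cfg$seed != round(cfg$seed)) {
    abort("`seed` must be a non-negative integer.")
  }
  cfg$outdir <- cfg$outdir %||% "."
  cfg$fit <- cfg$fit %||% list()
  cfg$dispersion <- cfg$dispersion %||% list()
  cfg$verbosity <- cfg$verbosity %||% 1
  structure(cfg, class = "qens_config")
}

#' Load a run configuration from a JSON file
#'
#' @param path JSON file with the keys documented in [run_config()].
#' @return a `qens_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

pipeline_log <- function(con, verbosity, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 sprintf(...))
  writeLines(msg, con)
  if (verbosity > 1) message(msg)
  invisible(NULL)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a spectrum set, area-normalizes it, runs the global
#' four-component fit, runs the model-free per-Q analysis and extracts
#' dispersion curves for the two water components, computes derived
#' quantities, and writes everything under `outdir`:
#' `params.csv`, `params_stderr.csv`, `dispersion_bulk.csv`,
#' `dispersion_hyd.csv`, `derived.json` and `run.log`. A fit failure leaves
#' partial artifacts plus a `FAILED` marker file and returns with
#' `status = 1`.
#'
#' @param config a [run_config()] (or plain list passed through it).
#' @return invisibly, a list with `status` (0 ok, 1 fit failure), `fit`,
#'   `dispersion` (list of curves), `artifacts` (paths written).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "qens_config")) config <- run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con))
  vb <- config$verbosity
  pipeline_log(con, vb, "qenscell %s | seed = %d",
               as.character(utils::packageVersion("qenscell")), config$seed)

  resolution <- NULL
  if (!is.null(config$resolution_table)) {
    resolution <- read_resolution_table(config$resolution_table)
  } else if (!is.null(config$resolution_fwhm_meV)) {
    resolution <- resolution_gaussian(config$resolution_fwhm_meV)
  }

  if (!is.null(config$simulate)) {
    sim <- config$simulate
    preset <- preset_in5()
    if (!is.null(resolution)) preset$resolution <- resolution
    if (!is.null(sim$q_values) || !is.null(sim$n_energy_bins)) {
      preset <- instrument_preset(
        name = "custom",
        q_values = sim$q_values %||% preset$q_values,
        energy_window_meV = sim$energy_window_meV %||% preset$energy_window_meV,
        n_energy_bins = sim$n_energy_bins %||% preset$n_energy_bins,
        resolution = preset$resolution)
    }
    params <- scenario_params(sim$scenario)
    spectra <- generate_spectra(
      params, preset,
      noise = sim$noise %||% "none",
      counts_per_spectrum = sim$counts_per_spectrum %||% 1e5,
      seed = config$seed)
    pipeline_log(con, vb, "simulated scenario %s (%s noise), %d Q groups",
                 sim$scenario, sim$noise %||% "none", length(preset$q_values))
  } else {
    spectra <- read_spectrum_set(config$input, resolution)
    pipeline_log(con, vb, "read %s: %d Q groups, %d points", config$input,
                 length(spectra_q_values(spectra)), nrow(spectra))
  }
  if (is.null(attr(spectra, "resolution"))) {
    abort("No resolution available: pass resolution_fwhm_meV or resolution_table.")
  }

  spectra <- normalize_spectra(spectra)
  artifacts <- character()

  fit_args <- c(list(spectra = spectra, seed = config$seed), config$fit)
  bounds <- default_global_bounds()
  pipeline_log(con, vb, "global fit: bounds d_t_bulk [%g, %g] 1e-5 cm2/s, gamma [%g, %g] meV",
               bounds$lower[["d_t_bulk"]], bounds$upper[["d_t_bulk"]],
               bounds$lower[["gamma_proteome"]], bounds$upper[["gamma_proteome"]])
  fit <- tryCatch(do.call(fit_global, fit_args), error = function(e) e)

  if (inherits(fit, "error") || !fit$converged) {
    msg <- if (inherits(fit, "error")) conditionMessage(fit)
           else "optimizer did not converge"
    pipeline_log(con, vb, "FIT FAILED: %s", msg)
    writeLines(c("FAILED", msg), file.path(config$outdir, "FAILED"))
    return(invisible(list(status = 1L,
                          fit = if (inherits(fit, "error")) NULL else fit,
                          dispersion = NULL,
                          artifacts = c(log_path, file.path(config$outdir, "FAILED")))))
  }
  pipeline_log(con, vb, "global fit converged: chi2_red = %.6g after %d iterations",
               fit$chi2_reduced, fit$n_evaluations)
  if (any(fit$at_bound)) {
    pipeline_log(con, vb, "warning: bound-pinned parameter(s): %s",
                 paste(fit$free_names[fit$at_bound], collapse = ", "))
  }

  td <- tidy(fit)
  params_path <- file.path(config$outdir, "params.csv")
  readr::write_csv(td[, c("term", "estimate", "unit", "fixed", "at_bound")],
                   params_path)
  stderr_path <- file.path(config$outdir, "params_stderr.csv")
  readr::write_csv(td[, c("term", "std.error")], stderr_path)
  artifacts <- c(artifacts, params_path, stderr_path)

  # Table-style rounded report into the log (decimals as conventionally printed)
  dec <- c(p_elastic = 2, p_hyd = 2, p_proteome = 2, p_bulk = 2,
           d_t_bulk = 2, tau_bulk = 2, d_r_bulk = 2, d_t_hyd = 2,
           tau_hyd = 2, d_r_hyd = 2, gamma_proteome = 3)
  for (i in seq_len(nrow(td))) {
    d <- dec[[td$term[i]]] %||% 3
    pipeline_log(con, vb, "  %-14s = %s %s", td$term[i],
                 formatC(td$estimate[i], format = "f", digits = d), td$unit[i])
  }

  n_lor <- config$dispersion$n_lorentzians %||% 3
  mf <- fit_model_free(spectra, n_lorentzians = n_lor, seed = config$seed)
  disp <- list()
  comp_index <- c(hyd = 1L, bulk = 2L)
  for (nm in names(comp_index)) {
    curve <- tryCatch(
      suppressWarnings(extract_dispersion(mf, comp_index[[nm]],
                                          component_label = nm)),
      error = function(e) NULL)
    if (!is.null(curve)) {
      p <- file.path(config$outdir, sprintf("dispersion_%s.csv", nm))
      readr::write_csv(as_tibble(curve), p)
      artifacts <- c(artifacts, p)
      disp[[nm]] <- curve
    }
  }
  pipeline_log(con, vb, "model-free dispersion: %d Lorentzians per Q, %d slices",
               n_lor, length(spectra_q_values(spectra)))

  dq <- derived_quantities(fit)
  derived_path <- file.path(config$outdir, "derived.json")
  jsonlite::write_json(
    list(label = attr(spectra, "label") %||% config$label,
         seed = config$seed,
         chi2_reduced = fit$chi2_reduced,
         derived = dq),
    derived_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  artifacts <- c(artifacts, derived_path, log_path)
  pipeline_log(con, vb, "done: %d artifacts", length(artifacts))

  invisible(list(status = 0L, fit = fit, dispersion = disp,
                 model_free = mf, artifacts = artifacts))
}

#' Write a two-condition comparison report
#'
#' Runs [compare_fits()] and writes `comparison.csv` (relative changes to one
#' decimal) into `outdir`.
#'
#' @param fit_a,fit_b `qens_fit` objects.
#' @param outdir output directory.
#' @param label_a,label_b condition labels.
#' @return the comparison tibble, invisibly.
#' @export
write_comparison <- function(fit_a, fit_b, outdir = ".",
                             label_a = "A", label_b = "B") {
  cmp <- compare_fits(fit_a, fit_b, label_a, label_b)
  out <- as_tibble(cmp)
  out$rel_change_pct <- round(out$rel_change_pct, 1)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(out, file.path(outdir, "comparison.csv"))
  invisible(cmp)
}
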