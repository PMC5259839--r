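# Configuration, long-format CSV dialect, JSON serialization and the
# end-to-end pipeline driver (simulate -> quantify -> fit -> metrics ->
# predict -> evaluate).

.TS_COLUMNS <- c("species", "compound", "replicate", "condition", "time_h",
                 "value", "value_type", "flags")
.VALUE_TYPES <- c("concentration_uM", "od600", "peak_area")
.CONDITIONS <- c("mono", "co", "control")

#' Default pipeline configuration
#'
#' Assembles the configuration driving [run_pipeline()]: the medium
#' definition (compound, mg/mL and molecular weight, converted internally to
#' uM), species list, sampling schedule, replicate count, noise level,
#' anomalies and perturbations for the bundled synthetic scenario, the
#' biomass conversion factor `k` (gCDW/L/OD600) per species, fit and
#' prediction options, the evaluation threshold and the master seed.
#' Any element can be overridden via `...` or loaded from YAML with
#' [read_pipeline_config()].
#'
#' @param ... Named overrides of the defaults.
#' @return A list of class `pipeline_config`, validated.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    medium = default_medium(),
    species = c("Bc", "Pl", "Pb"),
    sampling_times = c(0:12, 26),
    replicates = 3,
    noise_cv = 0.05,
    anomalies = list(list(compound = "glycine",
                          kind = "transient_accumulation"),
                     list(compound = "methionine", kind = "high_variance")),
    perturbations = list(),
    k_gcdw = c(Bc = 0.9, Pl = 0.9, Pb = 0.9),
    v0_l = 0.050,
    sample_draw_l = 0.0012,
    fit_restarts = 5,
    prediction_grid_step = 0.05,
    evaluation_threshold = 0.9,
    noise_cv_areas = 0,
    seed = 1)
  over <- list(...)
  cfg[names(over)] <- over
  validate_pipeline_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks that every compound has a molecular weight (so mg/mL converts to
#' uM), the threshold lies in (0, 1], every species has a `k` factor and the
#' sampling schedule is valid. Called before any stage runs.
#'
#' @param cfg A configuration list.
#' @return The validated configuration, classed `pipeline_config`.
#' @export
validate_pipeline_config <- function(cfg) {
  med <- cfg$medium
  if (is.null(med) || !all(c("compound", "mw_g_per_mol") %in% names(med))) {
    stop("config medium must define compound and mw_g_per_mol")
  }
  if (any(!is.finite(med$mw_g_per_mol) | med$mw_g_per_mol <= 0)) {
    stop("every compound needs a positive molecular weight")
  }
  if (is.null(med$conc_uM)) {
    if (is.null(med$mg_per_ml)) stop("medium needs mg_per_ml or conc_uM")
    med$conc_uM <- med$mg_per_ml / med$mw_g_per_mol * 1e6
    cfg$medium <- med
  }
  if (!(cfg$evaluation_threshold > 0 && cfg$evaluation_threshold <= 1)) {
    stop("evaluation_threshold must lie in (0, 1]")
  }
  if (!all(cfg$species %in% names(cfg$k_gcdw))) {
    stop("every species needs a k (gCDW/L/OD600) entry")
  }
  if (cfg$sampling_times[1] != 0 ||
      is.unsorted(cfg$sampling_times, strictly = TRUE)) {
    stop("sampling_times must start at 0 and be strictly increasing")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file of overrides (any subset of the [pipeline_config()]
#' elements; `medium` as a list of records) and merges it onto the defaults.
#'
#' @param path Path to the YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$medium)) {
    raw$medium <- do.call(rbind, lapply(raw$medium, as.data.frame))
  }
  if (!is.null(raw$k_gcdw)) raw$k_gcdw <- unlist(raw$k_gcdw)
  do.call(pipeline_config, raw)
}

#' Read a long-format time-series CSV
#'
#' The single CSV dialect used throughout the pipeline: exactly the columns
#' `species, compound, replicate, condition, time_h, value, value_type,
#' flags`, with `condition` one of mono/co/control, `value_type` one of
#' concentration_uM/od600/peak_area and flags serialised as semicolon-joined
#' tokens. Parse errors name the offending row.
#'
#' @param path CSV path.
#' @return Validated data frame (possibly empty).
#' @export
read_timeseries_csv <- function(path) {
  df <- suppressWarnings(
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(flags = "character")))
  missing_cols <- setdiff(.TS_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[.TS_COLUMNS]
  if (!nrow(df)) return(df)
  df$flags[is.na(df$flags)] <- ""
  if (!is.numeric(df$time_h) || anyNA(df$time_h)) {
    stop("non-numeric time_h at row ",
         which(!is.finite(suppressWarnings(as.numeric(df$time_h))))[1])
  }
  if (any(df$time_h < 0)) {
    stop("negative time_h at row ", which(df$time_h < 0)[1])
  }
  if (!is.numeric(df$value) || anyNA(df$value)) {
    stop("non-numeric value at row ", which(is.na(df$value))[1])
  }
  bad_vt <- !df$value_type %in% .VALUE_TYPES
  if (any(bad_vt)) {
    stop("unknown value_type '", df$value_type[bad_vt][1], "' at row ",
         which(bad_vt)[1])
  }
  bad_cond <- !df$condition %in% .CONDITIONS
  if (any(bad_cond)) {
    stop("unknown condition '", df$condition[bad_cond][1], "' at row ",
         which(bad_cond)[1])
  }
  df
}

#' Write a long-format time-series CSV
#'
#' @param data Data frame with the dialect columns (see
#'   [read_timeseries_csv()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(data, path) {
  stopifnot(all(.TS_COLUMNS %in% names(data)))
  utils::write.csv(data[.TS_COLUMNS], path, row.names = FALSE)
  invisible(path)
}

#' Serialize fits to JSON
#'
#' @param fits List of `behrends_fit` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(fits, path) {
  payload <- lapply(unname(fits), function(f) {
    list(species = f$species, compound = f$compound, a = f$a, o = f$o,
         t50 = f$t50, w = f$w, rmse = f$rmse, converged = f$converged,
         flags = as.list(f$anomaly_flags))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read fits from JSON
#'
#' @param path Path written by [write_fits_json()].
#' @return Named list of `behrends_fit` objects (`"species|compound"`).
#' @export
read_fits_json <- function(path) {
  payload <- jsonlite::read_json(path)
  fits <- lapply(payload, function(p) {
    behrends_fit(a = p$a, o = p$o, t50 = p$t50, w = p$w,
                 species = p$species, compound = p$compound,
                 converged = isTRUE(p$converged),
                 rmse = if (is.null(p$rmse)) NA_real_ else p$rmse,
                 anomaly_flags = unlist(p$flags) %||% character())
  })
  names(fits) <- vapply(fits, function(f) paste(f$species, f$compound,
                                                sep = "|"), character(1))
  fits
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline on the bundled synthetic scenario
#'
#' Executes the stages simulate -> quantify -> fit -> metrics -> predict ->
#' evaluate, writing every stage's outputs under `out_dir` together with a
#' machine-readable run manifest (seed, configuration summary, per-stage row
#' counts and file list). The run is deterministic for a fixed seed:
#' rerunning with the same seed reproduces every output byte for byte. A
#' stage failure aborts with the failing stage named; outputs of completed
#' stages are preserved.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the key in-memory objects (`scenario`,
#'   `fits`, `metrics`, `predictions`, `evaluation`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL,
                         quiet = FALSE) {
  config <- validate_pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  # --- simulate -------------------------------------------------------------
  sim <- stage("simulate", {
    scenario <- synthetic_scenario(
      species = config$species, medium = config$medium,
      sampling_times = config$sampling_times,
      replicates = config$replicates, noise_cv = config$noise_cv,
      anomalies = config$anomalies, perturbations = config$perturbations,
      seed = config$seed)
    monos <- lapply(config$species, simulate_monoculture,
                    scenario = scenario)
    conc <- do.call(rbind, lapply(monos, `[[`, "concentrations"))
    od <- do.call(rbind, lapply(monos, `[[`, "od600"))
    co <- simulate_coculture(scenario)
    assays <- simulate_growth_assays(scenario)
    rf <- .with_seed(.derive_seed(config$seed, 500),
                     stats::setNames(stats::runif(nrow(config$medium),
                                                  0.5, 5),
                                     config$medium$compound))
    areas <- simulate_peak_areas(rbind(conc, co), rf,
                                 is_response_factor = 2,
                                 noise_cv = config$noise_cv_areas,
                                 seed = config$seed, medium = config$medium)
    write_timeseries_csv(rbind(conc, co), file.path(out_dir,
                                                    "concentrations_true.csv"))
    write_timeseries_csv(od, file.path(out_dir, "od600.csv"))
    utils::write.csv(assays, file.path(out_dir, "growth_assays.csv"),
                     row.names = FALSE)
    utils::write.csv(areas, file.path(out_dir, "peak_areas.csv"),
                     row.names = FALSE)
    list(scenario = scenario, od = od, co = co, assays = assays,
         areas = areas)
  })
  counts$simulate <- nrow(sim$areas)
  say("simulate: %d peak-area rows", counts$simulate)

  # --- quantify -------------------------------------------------------------
  quant <- stage("quantify", {
    cal <- build_calibration(sim$areas[sim$areas$condition == "calibration", ])
    conc <- peak_areas_to_concentrations(
      sim$areas[sim$areas$condition != "calibration", ], cal)
    jsonlite::write_json(cal, file.path(out_dir, "calibration.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_timeseries_csv(conc, file.path(out_dir, "concentrations.csv"))
    list(calibration = cal, conc = conc)
  })
  counts$quantify <- nrow(quant$conc)
  say("quantify: %d quantified rows", counts$quantify)

  # --- fit ------------------------------------------------------------------
  fits <- stage("fit", {
    f <- fit_depletion(quant$conc[quant$conc$condition == "mono", ],
                       restarts = config$fit_restarts)
    write_fits_json(f, file.path(out_dir, "fits.json"))
    utils::write.csv(fits_to_df(f), file.path(out_dir, "fit_diagnostics.csv"),
                     row.names = FALSE)
    f
  })
  counts$fit <- length(fits)
  say("fit: %d series fitted", counts$fit)

  # --- metrics --------------------------------------------------------------
  met <- stage("metrics", {
    biomass <- lapply(stats::setNames(config$species, config$species),
                      function(sp) {
      od_sp <- sim$od[sim$od$species == sp, ]
      m <- .replicate_means(od_sp)
      biomass_trajectory(m$time_h, m$value, k = config$k_gcdw[[sp]],
                         v0 = config$v0_l,
                         sample_draw_l = config$sample_draw_l)
    })
    metr <- preference_metrics(fits, biomass = biomass)
    cors <- do.call(rbind, lapply(config$species, function(sp) {
      a_sp <- sim$assays[sim$assays$species == sp, ]
      mu <- vapply(split(a_sp, a_sp$compound), function(d) {
        specific_growth_rate(d$time_h, d$od600)
      }, numeric(1))
      pc <- tryCatch(
        preference_correlations(metr[metr$species == sp, ], mu, species = sp),
        error = function(e) NULL)
      if (is.null(pc)) NULL else pc$correlations
    }))
    utils::write.csv(metr, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(cors, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    list(metrics = metr, correlations = cors, biomass = biomass)
  })
  counts$metrics <- nrow(met$metrics)
  say("metrics: %d species x compound rows", counts$metrics)

  # --- predict --------------------------------------------------------------
  preds <- stage("predict", {
    grid <- seq(0, max(config$sampling_times),
                by = config$prediction_grid_step)
    p <- predict_depletion(fits, config$medium, grid = grid,
                           grid_step = config$prediction_grid_step)
    curves <- do.call(rbind, lapply(names(p), function(cp) {
      data.frame(compound = cp, p[[cp]]$curve, stringsAsFactors = FALSE)
    }))
    utils::write.csv(curves, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)
    write_fits_json(do.call(c, lapply(p, `[[`, "primed")),
                    file.path(out_dir, "primed_fits.json"))
    p
  })
  counts$predict <- length(preds)
  say("predict: %d compounds predicted", counts$predict)

  # --- evaluate -------------------------------------------------------------
  ev <- stage("evaluate", {
    obs <- quant$conc[quant$conc$condition == "co", ]
    res <- evaluate_coculture(obs, preds,
                              threshold = config$evaluation_threshold)
    utils::write.csv(res, file.path(out_dir, "evaluation.csv"),
                     row.names = FALSE)
    summary <- list(
      n_compounds = nrow(res),
      n_consistent = sum(res$class == "consistent"),
      n_deviating_faster = sum(res$class == "deviating_faster"),
      n_deviating_slower = sum(res$class == "deviating_slower"),
      n_not_determined = sum(res$class == "not_determined"),
      n_pred_below10_by_6h = sum(res$t_below10_pred <= 6),
      n_obs_below10_by_6h = sum(is.finite(res$t_below10_obs) &
                                  res$t_below10_obs <= 6))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(results = res, summary = summary)
  })
  counts$evaluate <- nrow(ev$results)
  say("evaluate: %d compounds scored", counts$evaluate)

  manifest <- list(
    package = "exodeplete",
    version = as.character(utils::packageVersion("exodeplete")),
    seed = config$seed,
    species = config$species,
    n_compounds = nrow(config$medium),
    sampling_times = config$sampling_times,
    replicates = config$replicates,
    noise_cv = config$noise_cv,
    evaluation_threshold = config$evaluation_threshold,
    stage_rows = counts,
    outputs = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(scenario = sim$scenario, calibration = quant$calibration,
                 fits = fits, metrics = met$metrics,
                 correlations = met$correlations, predictions = preds,
                 evaluation = ev$results, summary = ev$summary,
                 manifest = manifest))
}
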