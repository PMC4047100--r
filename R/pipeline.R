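# End-to-end orchestration: simulate -> features -> QC -> stats -> report.

#' Extract all per-sweep and per-cell features from one cell record
#'
#' Runs the passive fit (on the first available sweep's probe step), the
#' spike analysis and the AHP decomposition on every sweep of a cell.
#'
#' @param cell a cell record (list with `cell_id`, `group_label`, `sweeps`).
#' @param decimate_hz AHP fit rate, Hz.
#' @return list with `passive` (one-row data.frame), `sweeps` (long
#'   data.frame: AHP fit, spike count and train statistics per step) and
#'   `first_spike` (averaged first-spike features).
#' @export
extract_cell_features <- function(cell, decimate_hz = 1000) {
  stopifnot(length(cell$sweeps) >= 1)
  pf <- fit_passive(cell$sweeps[[1]])
  passive <- data.frame(
    cell_id = cell$cell_id, group = cell$group_label,
    rmp = pf$rmp, r_in = pf$r_in, tau_m = pf$tau_m, r_a = pf$r_a,
    tau_p = pf$tau_p, passive_converged = pf$converged,
    stringsAsFactors = FALSE)
  sweep_rows <- vector("list", length(cell$sweeps))
  spike_feature_list <- list()
  for (k in seq_along(cell$sweeps)) {
    sid <- names(cell$sweeps)[k]
    tr <- cell$sweeps[[sid]]
    sf <- sweep_spike_features(tr)
    af <- fit_ahp(tr, decimate_hz = decimate_hz)
    sweep_rows[[k]] <- data.frame(
      cell_id = cell$cell_id, group = cell$group_label,
      step = as.numeric(sid),
      v_med = af$v_med, tau_med = af$tau_med,
      v_slow = af$v_slow, tau_slow = af$tau_slow,
      r2 = af$r2, peak_amp = af$peak_amp, ahp_converged = af$converged,
      n_spikes = sf$train$n_spikes,
      mean_isi = sf$train$mean_isi,
      accommodation_pct = sf$train$accommodation_pct,
      stringsAsFactors = FALSE)
    if (length(sf$spikes))
      spike_feature_list[[sid]] <- as.data.frame(unclass(sf$spikes[[1]]))
  }
  sweeps <- do.call(rbind, sweep_rows)
  sweeps <- sweeps[order(sweeps$step), , drop = FALSE]
  fs_avg <- if (length(spike_feature_list))
    first_spike_cell_average(do.call(rbind, spike_feature_list))
  else first_spike_cell_average(list())
  fs_avg$cell_id <- cell$cell_id
  fs_avg$group <- cell$group_label
  list(passive = passive, sweeps = sweeps, first_spike = fs_avg)
}

#' Default pipeline configuration
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param out_dir output directory.
#' @param ... overrides of the default fields: `cohort` (list of
#'   [cohort_gen_params()] arguments), `trace` (list of
#'   [trace_gen_params()] arguments), `sampling_rate` (Hz, simulation rate),
#'   `decimate_hz`, `m_imputations`, `response`, `stages` (character subset
#'   of simulate/features/qc/stats/power in pipeline order), `power` (list:
#'   `n_grid`, `n_sim`), `write_traces`.
#' @return named list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1, out_dir = "sahp_run", ...) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    stages = c("simulate", "features", "qc", "stats"),
    cohort = list(), trace = list(),
    sampling_rate = 10000, decimate_hz = 1000,
    response = "v_slow", m_imputations = 20,
    power = list(n_grid = c(20, 40, 70), n_sim = 200),
    write_traces = FALSE)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stopf("unknown config field(s): %s", paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  valid <- c("simulate", "features", "qc", "stats", "power")
  if (!all(cfg$stages %in% valid)) stopf("unknown stage name")
  # stage list must be a prefix-closed subset of the DAG
  need <- valid[seq_len(max(match(cfg$stages, valid)))]
  need <- setdiff(need, "power")
  if (!all(setdiff(need, "power") %in% c(cfg$stages, "power")))
    stopf("stages must form a prefix of simulate < features < qc < stats")
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a cohort, extracts per-cell features, applies the
#' input-resistance inclusion filter, and runs the group-level statistics:
#' interaction and main-effect likelihood-ratio tests on the chosen AHP
#' response with Cook's-distance influence screening (flagged observations
#' are set missing and imputed together with the genuinely missing ones),
#' multiple imputation with pooled estimates and pooled LRTs, and the
#' per-group sAHP-spike-count correlation. All stage outputs are written as
#' CSV/JSON under `out_dir` along with a manifest recording the
#' configuration, seeds and package version; identical configurations and
#' seeds reproduce every output exactly.
#'
#' @param config a [pipeline_config()] (or a path to a YAML file of config
#'   fields).
#' @return list with the stage results (`cohort`, `features`, `qc`,
#'   `stats`, `power`, `manifest`), invisibly writing files under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) {
    fields <- yaml::read_yaml(config)
    config <- do.call(pipeline_config, fields)
  }
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)
  t0 <- Sys.time()

  if ("simulate" %in% config$stages) {
    cohort_params <- do.call(cohort_gen_params,
                             modifyList(config$cohort,
                                        list(seed = seed_child(config$seed, 1))))
    trace_params <- do.call(trace_gen_params, config$trace)
    res$cohort <- generate_cohort(
      cohort_params, trace_params,
      protocol_args = list(sampling_rate = config$sampling_rate),
      traces = "features" %in% config$stages)
    write.csv(res$cohort$truth, file.path(config$out_dir, "truth.csv"),
              row.names = FALSE)
    if (config$write_traces && !is.null(res$cohort$cells))
      write_sweeps(res$cohort$cells, file.path(config$out_dir, "sweeps"))
  }

  if ("features" %in% config$stages) {
    feats <- lapply(res$cohort$cells, extract_cell_features,
                    decimate_hz = config$decimate_hz)
    res$features <- list(
      passive = do.call(rbind, lapply(feats, `[[`, "passive")),
      sweeps = do.call(rbind, lapply(feats, `[[`, "sweeps")),
      first_spike = do.call(rbind, lapply(feats, `[[`, "first_spike")))
    rownames(res$features$passive) <- rownames(res$features$sweeps) <-
      rownames(res$features$first_spike) <- NULL
    for (nm in names(res$features))
      write.csv(res$features[[nm]],
                file.path(config$out_dir, paste0(nm, ".csv")),
                row.names = FALSE)
  }

  if ("qc" %in% config$stages) {
    res$qc <- qc_filter(res$features$passive)
    write.csv(res$qc$report, file.path(config$out_dir, "qc_exclusions.csv"),
              row.names = FALSE)
  }

  if ("stats" %in% config$stages) {
    kept <- res$qc$kept$cell_id
    sw <- res$features$sweeps[res$features$sweeps$cell_id %in% kept, ]
    res$stats <- cohort_inference(sw, response = config$response,
                                  m = config$m_imputations,
                                  seed = seed_child(config$seed, 2))
    jsonlite::write_json(stats_summary_json(res$stats),
                         file.path(config$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if ("power" %in% config$stages) {
    spec <- effect_spec_from_lme(res$stats$full_pooled_source %||%
                                   res$stats$full_complete, uncertainty = TRUE)
    res$power <- power_curve(spec, n_grid = config$power$n_grid,
                             n_sim = config$power$n_sim,
                             seed = seed_child(config$seed, 3))
    write.csv(as.data.frame(res$power),
              file.path(config$out_dir, "power_curve.csv"), row.names = FALSE)
  }

  res$manifest <- list(
    package = "sahpkit",
    version = as.character(packageVersion("sahpkit")),
    r_version = R.version.string,
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "out_dir")],
    outputs = list.files(config$out_dir, recursive = TRUE),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(res$manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Group-level inference on a sweep feature table
#'
#' The statistical stage of the pipeline as one call: builds the long table,
#' fits the complete-data model, screens influential observations (Cook's
#' distance above 4/n), sets the flagged observations missing, imputes them
#' together with the genuinely missing observations, and pools estimates and
#' interaction/main-effect LRTs across imputations.
#'
#' @param sweep_features long data.frame with `cell_id`, `group`, `step`
#'   and the response column.
#' @param response response column name (default `"v_slow"`).
#' @param m number of imputations.
#' @param seed integer seed for the imputation draws.
#' @return list with the complete-data fits and tests, the influence
#'   report, the pooled estimates and pooled LRTs, and the per-group
#'   sAHP/spike-count correlation when spike counts are available.
#' @export
cohort_inference <- function(sweep_features, response = "v_slow", m = 20,
                             seed = NULL) {
  tab <- build_long_table(sweep_features, response)
  complete <- test_interaction(tab)
  infl <- cooks_screen(tab, complete$full)
  tab_screened <- tab
  if (length(infl$flagged)) {
    tab_screened$response[infl$flagged] <- NA_real_
    tab_screened$missing[infl$flagged] <- TRUE
  }
  imps <- impute_cohort(tab_screened, m = m, seed = seed)
  fits_full <- lapply(imps, fit_lme, formula_terms = "full")
  fits_red <- lapply(imps, fit_lme, formula_terms = "no_interaction")
  fits_nog <- lapply(imps, fit_lme, formula_terms = "no_group")
  lrts_int <- Map(lrt, fits_full, fits_red)
  lrts_main <- Map(lrt, fits_red, fits_nog)
  out <- list(
    table = tab, influence = infl,
    full_complete = complete$full,
    lrt_complete = complete$test,
    pooled = pool_estimates(fits_full),
    lrt_interaction = pool_lrt(lrts_int),
    lrt_main = pool_lrt(lrts_main),
    m = m,
    full_pooled_source = fits_full[[1]])
  if ("n_spikes" %in% names(sweep_features) &&
      response %in% names(sweep_features))
    out$correlation <- tryCatch(
      correlate_sahp_spikes(sweep_features), error = function(e) NULL)
  out
}

stats_summary_json <- function(stats) {
  list(
    pooled_fixed_effects = stats$pooled,
    interaction_lrt = stats$lrt_interaction,
    main_effect_lrt = stats$lrt_main,
    complete_data_lrt = unclass(stats$lrt_complete),
    influence = list(cutoff = stats$influence$cutoff,
                     n_flagged = length(stats$influence$flagged),
                     flagged_rows = stats$influence$flagged),
    correlation = stats$correlation,
    m_imputations = stats$m)
}

#' Summarize a pipeline run as a group-comparison report
#'
#' Rebuilds, from the stage CSVs of a completed run, the standard
#' passive/active property table (group mean and SEM for resting potential,
#' input resistance, membrane time constant, spike amplitude, rise time,
#' rising slope, threshold, half-width, and the medium/slow AHP decay
#' constants), the per-step medium and slow AHP amplitude curves, and the
#' test results.
#'
#' @param run_dir output directory of [run_pipeline()].
#' @return list of class `sahp_report` with `properties` (feature x group
#'   table), `ahp_by_step` (per-step group means), `stats` (parsed
#'   stats.json), `manifest`.
#' @export
pipeline_report <- function(run_dir) {
  f <- function(name) file.path(run_dir, name)
  if (!file.exists(f("manifest.json"))) stopf("'%s' is not a completed run", run_dir)
  passive <- read.csv(f("passive.csv"))
  sweeps <- read.csv(f("sweeps.csv"))
  first_spike <- read.csv(f("first_spike.csv"))
  cell_tab <- merge(passive, first_spike, by = c("cell_id", "group"))
  tau_cell <- aggregate(cbind(tau_med, tau_slow) ~ cell_id + group,
                        data = sweeps, FUN = mean, na.rm = TRUE)
  cell_tab <- merge(cell_tab, tau_cell, by = c("cell_id", "group"))
  rows <- c(rmp = "Resting membrane potential (mV)",
            r_in = "Input resistance (MOhm)",
            tau_m = "Membrane time constant (ms)",
            amplitude = "Action potential amplitude (mV)",
            rise_time_20_80 = "Action potential rise time (us)",
            rising_slope = "Action potential rising slope (mV/ms)",
            threshold_v = "Action potential threshold (mV)",
            half_width = "Action potential width at half maximum (ms)",
            tau_med = "mAHP decay (ms)",
            tau_slow = "sAHP decay (ms)")
  props <- do.call(rbind, lapply(names(rows), function(v) {
    agg <- aggregate(cell_tab[[v]], by = list(group = cell_tab$group),
                     FUN = function(x) c(mean = mean(x, na.rm = TRUE),
                                         sem = sd(x, na.rm = TRUE) /
                                           sqrt(sum(!is.na(x)))))
    data.frame(feature = rows[[v]], group = agg$group,
               mean = agg$x[, "mean"], sem = agg$x[, "sem"],
               stringsAsFactors = FALSE)
  }))
  by_step <- aggregate(cbind(v_med, v_slow) ~ group + step, data = sweeps,
                       FUN = mean, na.rm = TRUE)
  out <- list(
    properties = props,
    ahp_by_step = by_step[order(by_step$group, by_step$step), ],
    stats = if (file.exists(f("stats.json")))
      jsonlite::read_json(f("stats.json"), simplifyVector = TRUE) else NULL,
    power = if (file.exists(f("power_curve.csv")))
      read.csv(f("power_curve.csv")) else NULL,
    manifest = jsonlite::read_json(f("manifest.json"), simplifyVector = TRUE))
  class(out) <- "sahp_report"
  out
}

#' @export
print.sahp_report <- function(x, ...) {
  cat("== Passive and active membrane properties (mean +/- SEM) ==\n")
  wide <- reshape(x$properties, idvar = "feature", timevar = "group",
                  direction = "wide")
  print(wide, row.names = FALSE, digits = 4)
  if (!is.null(x$stats)) {
    li <- x$stats$interaction_lrt
    cat(sprintf("\nInteraction LRT (pooled over %d imputations): chi-square = %.3g, p = %.3g\n",
                x$stats$m_imputations, li$chi_square, li$p_value))
    lm_ <- x$stats$main_effect_lrt
    cat(sprintf("Main treatment effect: chi-square = %.3g, p = %.3g\n",
                lm_$chi_square, lm_$p_value))
  }
  invisible(x)
}
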