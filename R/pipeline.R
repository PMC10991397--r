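# End-to-end pipeline: simulate (or load) -> preprocess -> detect ->
# aggregate -> decompose -> model. Every stage writes a plain table so any
# stage can be re-run in isolation; a run log records parameters, seed and
# per-stage exclusion counts.

#' Default pipeline configuration
#'
#' All module parameter blocks with their standard defaults, plus the
#' simulation design and stage toggles.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(seed = 1,
       sim = sim_params(),
       pupil = pupil_params(),
       gaze = gaze_params(),
       pca = list(grid_ms = 10, n_components = 3, use_correlation = FALSE),
       bins = list(bin_ms = 50, window_start = 500, window_end = 4500),
       models = list(degree = 4, ddf = "Satterthwaite"),
       stages = list(models = TRUE))
}

#' Run the full analysis pipeline on a dataset
#'
#' Executes preprocess -> fixation detection -> AOI outcomes -> PCA
#' components -> mixed models over an in-memory dataset (e.g. from
#' [simulate_dataset()]) and optionally writes the tidy stage outputs to a
#' directory. Deterministic given identical config and dataset.
#'
#' @param dataset list with `streams`, `trials`, `participants`, `aoi_map`
#'   (see [simulate_dataset()]).
#' @param config configuration list, see [default_config()].
#' @param out_dir optional output directory for the stage tables.
#' @return list with `traces`, `events`, `outcomes`, `bins`, `covariates`,
#'   `components`, `pd`, `models` (when enabled), and `log` (per-stage
#'   exclusion accounting).
#' @export
run_pipeline <- function(dataset, config = default_config(), out_dir = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  validate_aoi_map(dataset$aoi_map)
  trials_by_p <- split(dataset$trials, dataset$trials$participant_id)
  log <- list(n_trials_in = nrow(dataset$trials))

  traces <- list(); events <- list(); bins_rows <- list(); cov_rows <- list()
  for (pid in names(dataset$streams)) {
    stream <- dataset$streams[[pid]]
    segs <- segment_trials(stream, trials_by_p[[pid]],
                           window_ms = cfg$pupil$window_ms)
    cov_rows[[pid]] <- cbind(data.frame(participant_id = pid),
                             compute_covariates(stream))
    for (nm in names(segs)) {
      trial <- segs[[nm]]
      traces[[nm]] <- preprocess_trial(trial, cfg$pupil)
      events[[nm]] <- detect_fixations(trial, cfg$gaze, dataset$aoi_map)
      bt <- bin_looking_time(trial, dataset$aoi_map, cfg$bins$bin_ms,
                             cfg$bins$window_start, cfg$bins$window_end)
      meta <- attr(trial, "meta")
      bt$participant_id <- meta$participant_id
      bt$trial_index <- meta$trial_index
      bt$group <- meta$group; bt$emotion <- meta$emotion
      bins_rows[[nm]] <- bt
    }
  }
  covariates <- merge(dataset$participants, do.call(rbind, cov_rows),
                      by = "participant_id")
  log$n_trials_excluded_pupil <- sum(vapply(traces, function(x)
    isTRUE(x$excluded), logical(1)))
  log$exclusion_reasons <- table(unlist(lapply(traces, function(x)
    x$exclude_reason)))
  outcomes <- fixation_outcomes(events)
  log$n_trials_no_fixation <- length(attr(outcomes, "no_fixation_trials"))
  bins <- do.call(rbind, bins_rows)
  rownames(bins) <- NULL

  m <- build_trial_matrix(traces, cfg$pca$grid_ms,
                          cfg$bins$window_start, cfg$bins$window_end)
  log$n_trials_in_pca <- nrow(m)
  cw <- extract_rotated_components(m, cfg$pca$n_components,
                                   cfg$pca$use_correlation)
  cw <- define_windows(cw)
  pd <- pd_measures(traces, cw$windows)

  models <- NULL
  if (isTRUE(cfg$stages$models)) {
    bins_m <- merge(bins[bins$aoi %in% c("eyes", "mouth"), ],
                    covariates[, setdiff(names(covariates), "group")],
                    by = "participant_id")
    outc <- merge(outcomes, covariates[, setdiff(names(covariates), "group")],
                  by = "participant_id")
    models <- list(
      growth = growth_curve_model(bins_m, cfg$models$degree,
                                  ddf = cfg$models$ddf),
      fix_count = fit_lmm(
        n_fixations ~ group * aoi * emotion + age + sex + onscreen_time +
          (1 | participant_id),
        outc, scale_vars = c("n_fixations", "age", "onscreen_time"),
        ddf = cfg$models$ddf),
      fix_duration = fit_lmm(
        mean_duration ~ group * aoi * emotion + age + sex + onscreen_time +
          (1 | participant_id),
        outc[!is.na(outc$mean_duration), ],
        scale_vars = c("mean_duration", "age", "onscreen_time"),
        ddf = cfg$models$ddf),
      pd_windows = .pd_window_model(pd, covariates, cfg$models$ddf),
      association = association_models(pd, outcomes, bins_m, cw$windows,
                                       covariates, ddf = cfg$models$ddf))
  }

  res <- list(traces = traces, events = events, outcomes = outcomes,
              bins = bins, covariates = covariates, components = cw,
              pd = pd, models = models, log = log, config = cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

# PD-by-window LMM: PD over all windows as outcome, group x emotion x
# window fixed effects, gaze deviation as additional PD covariate
.pd_window_model <- function(pd, covariates, ddf = "Satterthwaite") {
  long <- stats::reshape(pd, direction = "long",
                         varying = grep("^pd_trc", names(pd), value = TRUE),
                         v.names = "pd", timevar = "window",
                         times = grep("^pd_trc", names(pd), value = TRUE))
  long <- long[!is.na(long$pd), , drop = FALSE]
  long <- merge(long, covariates[, setdiff(names(covariates), "group")],
                by = "participant_id")
  fit_lmm(pd ~ group * emotion * window + age + sex + onscreen_time +
            gaze_deviation + (1 | participant_id),
          long, scale_vars = c("pd", "age", "onscreen_time",
                               "gaze_deviation"), ddf = ddf)
}

#' Write pipeline outputs as tidy delimited tables
#'
#' Emits `fixation_outcomes.tsv`, `looking_time_bins.tsv`,
#' `covariates.tsv`, `scree.tsv`, `loadings.tsv`, `windows.tsv`,
#' `pd_measures.tsv`, a `results_summary.tsv` of model tests, and
#' `run_log.txt`.
#'
#' @param res result of [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", row.names = FALSE, quote = FALSE)
  w(res$outcomes, "fixation_outcomes.tsv")
  w(res$bins, "looking_time_bins.tsv")
  w(res$covariates, "covariates.tsv")
  cw <- res$components
  w(data.frame(component = seq_along(cw$scree), share = cw$scree),
    "scree.tsv")
  load_df <- data.frame(time = cw$grid, cw$loadings, cw$rotated)
  names(load_df) <- c("time", paste0("pc", seq_len(ncol(cw$loadings))),
                      paste0("rc", seq_len(ncol(cw$rotated))))
  w(load_df, "loadings.tsv")
  w(cw$windows, "windows.tsv")
  w(res$pd, "pd_measures.tsv")
  if (!is.null(res$models)) {
    norm <- function(nm, tt) {
      if (!"ddf" %in% names(tt)) tt$ddf <- NA_real_
      cbind(model = nm, tt[, c("term", "statistic", "df", "ddf", "p.value")])
    }
    tests <- do.call(rbind, lapply(names(res$models), function(nm) {
      mr <- res$models[[nm]]
      if (inherits(mr, "model_result"))
        norm(nm, mr$tests)
      else do.call(rbind, lapply(names(mr), function(nm2)
        norm(paste(nm, nm2, sep = "."), mr[[nm2]]$tests)))
    }))
    w(tests, "results_summary.tsv")
  }
  writeLines(c(paste("seed:", res$config$seed),
               paste("trials in:", res$log$n_trials_in),
               paste("trials excluded (pupil):",
                     res$log$n_trials_excluded_pupil),
               paste("trials without fixations:",
                     res$log$n_trials_no_fixation),
               paste("trials in PCA:", res$log$n_trials_in_pca)),
             file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
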