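# One-command orchestration: input (synthetic cohort, rendered images, or a
# trace CSV) -> segmentation (if images) -> QC -> features/classification ->
# population summary -> model-based activity inference. Every intermediate
# is written to disk so each stage is independently re-runnable, and all
# randomness derives from a single seed.

#' Pipeline configuration
#'
#' Exactly one input source must be given: a synthetic cohort spec (traces
#' simulated directly), a synthetic cohort rendered to images and then
#' re-quantified by the segmentation stage, or a CSV of measured traces.
#'
#' @param synthetic A [cohort_spec()], or `NULL`.
#' @param images `TRUE` to render the synthetic cohort to images and run
#'   segmentation on them (requires `synthetic`); ignored otherwise.
#' @param trace_csv Path to a trace CSV (columns as in
#'   [simulate_cell_trace()]), or `NULL`.
#' @param stim_time Stimulus time in minutes.
#' @param theta Responder threshold: a number (e.g. the fixed 0.2), or
#'   `"auto"` to derive it from control cells.
#' @param control_csv Trace CSV of signaling-dead control cells (required
#'   when `theta = "auto"`).
#' @param params A [sensor_params()] object.
#' @param frames A [frame_spec()] for image rendering.
#' @param initial_window Initial-response window (min after stimulus).
#' @param slow_factor Slow-response factor.
#' @param basal_activity Baseline kinase activity assumed when fitting the
#'   population activity time course (normalized traces leave the baseline
#'   only weakly identified; 0.2 is the unstimulated activity obtained from
#'   steady-state dose-response inversion).
#' @param out_dir Output directory for intermediates and results.
#' @param seed Integer master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, images = FALSE,
                            trace_csv = NULL, stim_time = 5,
                            theta = 0.2, control_csv = NULL,
                            params = sensor_params(),
                            frames = frame_spec(),
                            initial_window = c(3, 5), slow_factor = 1.5,
                            basal_activity = 0.2,
                            out_dir = tempfile("skars_run_"), seed = 1L) {
  n_src <- (!is.null(synthetic)) + (!is.null(trace_csv))
  if (n_src != 1L)
    stop_skars("exactly one input source (synthetic spec or trace CSV) is required",
               "skars_config_error")
  if (isTRUE(images) && is.null(synthetic))
    stop_skars("images = TRUE requires a synthetic cohort spec",
               "skars_config_error")
  if (identical(theta, "auto") && is.null(control_csv))
    stop_skars("theta = \"auto\" requires control_csv", "skars_config_error")
  structure(list(synthetic = synthetic, images = isTRUE(images),
                 trace_csv = trace_csv, stim_time = stim_time,
                 theta = theta, control_csv = control_csv, params = params,
                 frames = frames, initial_window = initial_window,
                 slow_factor = slow_factor,
                 basal_activity = basal_activity, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Generates or loads single-cell traces, applies quality control, computes
#' response features and responder classes, summarizes the population,
#' derives the responder threshold (if requested), and infers the
#' population kinase activity time course by fitting the kinetic model to
#' the median normalized trace. All intermediates (`traces.csv`,
#' `features.csv`, `summary.csv`, `activity.csv`, `qc_log.csv`,
#' `report.json`) are written under `config$out_dir`; outputs are
#' byte-identical for identical `(config, seed)`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the run report: a list with cell counts per stage,
#'   the threshold used, class counts and fractions, the fitted activity
#'   parameters, and the paths of all written files.
#' @examples
#' cfg <- pipeline_config(synthetic = cohort_spec(n_cells = 8, seed = 1),
#'                        out_dir = tempfile())
#' rep <- run_pipeline(cfg)
#' rep$class_counts
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  paths <- list()
  warnings_log <- character(0)

  # --- stage 1: traces -------------------------------------------------
  if (!is.null(config$synthetic)) {
    spec <- config$synthetic
    cohort <- generate_cohort(spec)
    paths$ground_truth <- write_csv_plain(cohort$cells, out("ground_truth.csv"))
    if (config$images) {
      movie <- render_frames(cohort, config$frames, config$params)
      for (ch in names(movie$images))
        paths[[paste0("channel_", ch)]] <-
          write_image_stack(movie$images[[ch]], out(paste0(ch, ".tif")))
      nuc <- lapply(seq_along(movie$times), function(f)
        segment_nuclei(movie$images$nuclear[, , f]))
      cells <- lapply(seq_along(movie$times), function(f)
        expand_to_cells(nuc[[f]], movie$images$body[, , f]))
      tracks <- track_nuclei(nuc)
      meas <- quantify_cells(tracks, nuc, cells,
                             movie$images[intersect(c("nuclear", "sensor",
                                                      "marker"),
                                                    names(movie$images))],
                             movie$times)
      traces <- traces_from_measurements(meas)
      # segmentation labels objects in scan order: remap track ids to the
      # planted cell ids so downstream tables align with the ground truth
      mp <- match_tracks_to_truth(tracks, movie$truth)
      traces$cell_id <- mp$cell_id[match(traces$cell_id, mp$track_id)]
      paths$measurements <- write_csv_plain(meas, out("measurements.csv"))
    } else {
      traces <- simulate_cohort_traces(cohort, config$params)
    }
    stim_time <- spec$stim_time
  } else {
    traces <- utils::read.csv(config$trace_csv)
    stim_time <- config$stim_time
    cohort <- NULL
  }
  paths$traces <- write_csv_plain(traces, out("traces.csv"))
  n_in <- length(unique(traces$cell_id))

  # --- stage 2: QC -----------------------------------------------------
  qc <- qc_filter(traces)
  paths$qc_log <- write_csv_plain(qc$log, out("qc_log.csv"))
  traces <- qc$kept
  n_qc <- length(unique(traces$cell_id))
  if (n_qc == 0)
    stop_skars("no traces passed quality control", "skars_pipeline_error")

  # --- stage 3: threshold ----------------------------------------------
  theta <- config$theta
  if (identical(theta, "auto")) {
    ctrl <- utils::read.csv(config$control_csv)
    ctrl_feat <- compute_trace_features(ctrl, stim_time = stim_time,
                                        theta = 0.2)$features
    theta <- derive_threshold(ctrl_feat$FR)
  }

  # --- stage 4: features and classes -----------------------------------
  tf <- compute_trace_features(traces, stim_time = stim_time,
                               theta = theta,
                               slow_factor = config$slow_factor,
                               initial_window = config$initial_window)
  features <- tf$features
  if (!is.null(cohort)) {
    features$planted_class <-
      cohort$cells$class[match(features$cell_id, cohort$cells$cell_id)]
  }
  paths$features <- write_csv_plain(features, out("features.csv"))
  ordering <- sort_for_heatmap(features)
  paths$ordering <- write_csv_plain(ordering, out("ordering.csv"))

  # --- stage 5: population summary -------------------------------------
  summ <- population_summary(tf$normalized, value = "norm_ratio")
  paths$summary <- write_csv_plain(summ, out("summary.csv"))

  # --- stage 6: activity inference -------------------------------------
  med <- population_summary(traces, value = "ratio")
  fit <- fit_activity_timecourse(med$time_min, med$median, config$params,
                                 t_on = stim_time, normalize = TRUE,
                                 fix_A0 = config$basal_activity)
  paths$activity <- write_csv_plain(fit$fitted, out("activity.csv"))

  cls <- table(factor(features$class,
                      levels = c("responding", "slow", "non_responding")))
  report <- list(
    n_cells_in = n_in, n_cells_after_qc = n_qc,
    theta = as.numeric(theta),
    class_counts = as.list(cls),
    class_fractions = as.list(cls / sum(cls)),
    activity_fit = as.list(round(fit$par, 6)),
    activity_fit_rms = fit$residual_norm,
    seed = config$seed,
    files = lapply(paths, basename))
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  report$features <- features
  report$summary <- summ
  report$fit <- fit
  report$out_dir <- config$out_dir
  invisible(report)
}

#' Read and write pipeline configuration as YAML
#'
#' Serializes the flat fields of a [pipeline_config()] (and its nested
#' sensor parameters and cohort spec scalars) to YAML, so runs can be
#' reproduced from a text file.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- list(stim_time = config$stim_time,
            theta = config$theta,
            control_csv = config$control_csv,
            trace_csv = config$trace_csv,
            images = config$images,
            initial_window = config$initial_window,
            slow_factor = config$slow_factor,
            out_dir = config$out_dir,
            seed = config$seed,
            params = unclass(config$params))
  if (!is.null(config$synthetic)) {
    s <- unclass(config$synthetic)
    s$profiles <- lapply(s$profiles, unclass)
    # YAML drops names of atomic vectors; store named vectors as maps
    s$class_fractions <- as.list(s$class_fractions)
    s$marker_p <- as.list(s$marker_p)
    x$synthetic <- s
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  params <- do.call(sensor_params, x$params)
  synthetic <- NULL
  if (!is.null(x$synthetic)) {
    s <- x$synthetic
    synthetic <- cohort_spec(
      n_cells = s$n_cells,
      class_fractions = unlist(s$class_fractions),
      basal_median = s$basal_median, basal_sdlog = s$basal_sdlog,
      tau_jitter_sdlog = s$tau_jitter_sdlog,
      marker_p = unlist(s$marker_p),
      ratio_noise_sd = s$ratio_noise_sd,
      profiles = lapply(s$profiles, function(p) {
        p$tau_decay <- as.numeric(p$tau_decay)  # YAML may read Inf as ".inf"
        p
      }),
      timepoints = unlist(s$timepoints),
      stim_time = s$stim_time, seed = s$seed)
  }
  pipeline_config(synthetic = synthetic, images = isTRUE(x$images),
                  trace_csv = x$trace_csv, stim_time = x$stim_time,
                  theta = if (identical(x$theta, "auto")) "auto"
                          else as.numeric(x$theta),
                  control_csv = x$control_csv, params = params,
                  initial_window = unlist(x$initial_window),
                  slow_factor = x$slow_factor,
                  out_dir = x$out_dir, seed = x$seed)
}
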