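# Ground-truthed synthetic cohorts.
#
# The generator emulates the population structure seen in pheromone- and
# cell-wall-stress experiments: heterogeneous basal nuclear enrichment
# (log-normal, median ~3-fold), three responder classes (responding, slow,
# non-responding), relocation kinetics on the minutes scale, a binary
# cell-cycle marker state, and additive measurement noise on the ratio.

#' Specification of a synthetic single-cell cohort
#'
#' Defaults encode the population structure reported for pheromone
#' stimulation: 72% responding, 11% slow-responding, 17% non-responding;
#' basal nuclear enrichment log-normal with median 3 and an interquartile
#' range of roughly 2.3--4; responder activity rising from a basal 0.2
#' towards 0.9 within minutes; non-responders showing a transient early
#' activation that returns to baseline. Cell-cycle marker states are
#' enriched among responders (G1-like cells respond preferentially);
#' the marker probabilities are illustrative defaults, not fitted values.
#'
#' @param n_cells Number of cells (>= 1).
#' @param class_fractions Named fractions for `responding`, `slow`,
#'   `non_responding`; must sum to 1.
#' @param basal_median Median of the log-normal basal-ratio distribution.
#' @param basal_sdlog Log-sd of the basal-ratio distribution (0.4 gives an
#'   IQR of about 2.3--4 at median 3).
#' @param tau_jitter_sdlog Per-cell multiplicative (log-normal) jitter on
#'   `tau_rise`.
#' @param marker_p Named per-class probability that the cell-cycle marker is
#'   nuclear.
#' @param ratio_noise_sd Additive Gaussian noise on the ratio trace.
#' @param profiles Per-class activity-profile parameters (lists with `A0`,
#'   `Amax`, `tau_rise`, `tau_decay`).
#' @param timepoints Acquisition times in minutes.
#' @param stim_time Stimulus time in minutes (activity onset).
#' @param seed Integer seed; the cohort and its traces are fully
#'   reproducible from `(spec, seed)`.
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n_cells = 10, seed = 1)
#' spec$class_fractions
#' @export
cohort_spec <- function(n_cells = 300,
                        class_fractions = c(responding = 0.72, slow = 0.11,
                                            non_responding = 0.17),
                        basal_median = 3, basal_sdlog = 0.4,
                        tau_jitter_sdlog = 0.15,
                        marker_p = c(responding = 0.55, slow = 0.5,
                                     non_responding = 0.2),
                        ratio_noise_sd = 0.05,
                        profiles = list(
                          responding = list(A0 = 0.2, Amax = 0.9,
                                            tau_rise = 1, tau_decay = Inf),
                          slow = list(A0 = 0.2, Amax = 0.9,
                                      tau_rise = 8, tau_decay = Inf),
                          non_responding = list(A0 = 0.2, Amax = 0.45,
                                                tau_rise = 1.5, tau_decay = 3)),
                        timepoints = seq(0, 45, by = 1),
                        stim_time = 5, seed = 1L) {
  classes <- c("responding", "slow", "non_responding")
  if (n_cells < 1) stop_skars("n_cells must be >= 1", "skars_spec_error")
  if (!all(classes %in% names(class_fractions)))
    stop_skars("class_fractions must name responding, slow, non_responding",
               "skars_spec_error")
  class_fractions <- class_fractions[classes]
  if (abs(sum(class_fractions) - 1) > 1e-9)
    stop_skars("class fractions must sum to 1", "skars_spec_error")
  if (any(class_fractions < 0))
    stop_skars("class fractions must be >= 0", "skars_spec_error")
  if (!all(classes %in% names(profiles)))
    stop_skars("profiles must be given for every class", "skars_spec_error")
  structure(list(n_cells = as.integer(n_cells),
                 class_fractions = class_fractions,
                 basal_median = basal_median, basal_sdlog = basal_sdlog,
                 tau_jitter_sdlog = tau_jitter_sdlog,
                 marker_p = marker_p[classes],
                 ratio_noise_sd = ratio_noise_sd,
                 profiles = profiles[classes],
                 timepoints = timepoints, stim_time = stim_time,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate the planted ground truth of a synthetic cohort
#'
#' Draws per-cell class labels (multinomially, with the spec's fractions),
#' basal ratios, kinetic parameters and cell-cycle marker states. The result
#' is fully determined by `(spec, spec$seed)`.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `skars_cohort`: list with `spec` and `cells`,
#'   a data.frame with one row per cell (`cell_id`, `class`, `basal_ratio`,
#'   `A0`, `Amax`, `t_on`, `tau_rise`, `tau_decay`, `marker_nuclear`).
#' @examples
#' co <- generate_cohort(cohort_spec(n_cells = 5, seed = 2))
#' co$cells
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cells <- with_seed(spec$seed, {
    cls <- sample(names(spec$class_fractions), spec$n_cells, replace = TRUE,
                  prob = spec$class_fractions)
    basal <- stats::rlnorm(spec$n_cells, meanlog = log(spec$basal_median),
                           sdlog = spec$basal_sdlog)
    prof <- spec$profiles[cls]
    # multiplicative log-normal jitter, clamped at +/- 2 sd so every cell's
    # planted kinetics stay inside its class definition
    z <- pmin(pmax(stats::rnorm(spec$n_cells), -2), 2)
    tau <- vapply(prof, `[[`, numeric(1), "tau_rise") *
      exp(spec$tau_jitter_sdlog * z)
    marker <- stats::runif(spec$n_cells) < unname(spec$marker_p[cls])
    data.frame(cell_id = seq_len(spec$n_cells),
               class = cls,
               basal_ratio = basal,
               A0 = vapply(prof, `[[`, numeric(1), "A0"),
               Amax = vapply(prof, `[[`, numeric(1), "Amax"),
               t_on = spec$stim_time,
               tau_rise = tau,
               tau_decay = vapply(prof, `[[`, numeric(1), "tau_decay"),
               marker_nuclear = marker,
               row.names = NULL)
  })
  structure(list(spec = spec, cells = cells), class = "skars_cohort")
}

#' @export
print.skars_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d cells (seed %d)\n",
              nrow(x$cells), x$spec$seed))
  print(table(x$cells$class))
  invisible(x)
}

cell_profile <- function(cell) {
  activity_profile(A0 = cell$A0, Amax = cell$Amax, t_on = cell$t_on,
                   tau_rise = cell$tau_rise, tau_decay = cell$tau_decay)
}

# Noise-free planted ratio trace of one cell: model output rescaled so the
# pre-stimulus level equals the cell's basal ratio.
planted_ratio <- function(cell, params, times) {
  sim <- simulate_relocation(params, cell_profile(cell), times)
  # the model trace starts at its own steady state, so the first point is
  # the model's basal level exactly
  sim$ratio * cell$basal_ratio / sim$ratio[1]
}

#' Simulate the measured trace of one cell
#'
#' Runs the kinetic model for the cell's planted activity profile, rescales
#' the ratio trace to the cell's basal nuclear enrichment and adds Gaussian
#' measurement noise. Nuclear and cytoplasmic sensor intensities consistent
#' with the noisy ratio are emitted, together with the morphological and
#' intensity features used by quality control (nucleus/cell area, nuclear
#' marker fluorescence, whole-cell sensor fluorescence) and the two
#' cell-cycle marker channels.
#'
#' @param cell One-row data.frame from a [generate_cohort()] `cells` table.
#' @param params A [sensor_params()] object.
#' @param times Acquisition times in minutes.
#' @param noise_sd Additive Gaussian noise sd on the ratio.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return A data.frame with one row per time point: `cell_id`, `time_min`,
#'   `nuc_sensor`, `cyto_sensor`, `ratio`, `nuc_marker`, `sensor_cell`,
#'   `nuc_area_px`, `cell_area_px`, `ccm_nuc`, `ccm_cyto`, `full_length`.
#' @export
simulate_cell_trace <- function(cell, params = sensor_params(),
                                times = seq(0, 45, by = 1),
                                noise_sd = 0.05, seed = NULL) {
  if (any(diff(times) <= 0))
    stop_skars("times must be strictly increasing", "skars_invalid_input")
  gen <- function() {
    r <- planted_ratio(cell, params, times) +
      stats::rnorm(length(times), 0, noise_sd)
    r <- pmax(r, 0.05)
    cyto <- 100 * stats::rlnorm(1, 0, 0.1)      # per-cell intensity scale
    nuc_area <- round(50 * stats::rlnorm(length(times), 0, 0.02))
    cell_area <- round(420 * stats::rlnorm(length(times), 0, 0.02))
    nuc_marker <- 800 * stats::rlnorm(length(times), 0, 0.02)
    ccm_hi <- if (isTRUE(cell$marker_nuclear)) 500 else 300
    data.frame(cell_id = cell$cell_id, time_min = times,
               nuc_sensor = r * cyto, cyto_sensor = cyto, ratio = r,
               nuc_marker = nuc_marker,
               sensor_cell = (r * cyto * nuc_area + cyto * (cell_area - nuc_area)) /
                 cell_area,
               nuc_area_px = nuc_area, cell_area_px = cell_area,
               ccm_nuc = ccm_hi + stats::rnorm(length(times), 0, 15),
               ccm_cyto = 300 + stats::rnorm(length(times), 0, 15),
               full_length = TRUE)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Simulate the measured traces of a whole cohort
#'
#' @param cohort A [generate_cohort()] result.
#' @param params A [sensor_params()] object.
#' @param noise_sd Additive ratio noise sd; defaults to the spec's value.
#' @return A long data.frame of per-cell traces (see
#'   [simulate_cell_trace()]), deterministic given the cohort's spec and
#'   seed.
#' @examples
#' co <- generate_cohort(cohort_spec(n_cells = 3, seed = 1))
#' tr <- simulate_cohort_traces(co)
#' head(tr)
#' @export
simulate_cohort_traces <- function(cohort, params = sensor_params(),
                                   noise_sd = NULL) {
  stopifnot(inherits(cohort, "skars_cohort"))
  spec <- cohort$spec
  if (is.null(noise_sd)) noise_sd <- spec$ratio_noise_sd
  with_seed(spec$seed + 1L, {
    out <- lapply(seq_len(nrow(cohort$cells)), function(i)
      simulate_cell_trace(cohort$cells[i, ], params, spec$timepoints,
                          noise_sd = noise_sd))
    do.call(rbind, out)
  })
}
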