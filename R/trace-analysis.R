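# Single-cell trace statistics: quality control, basal-level normalization,
# initial/final response, responder classification, population summaries,
# heat-map ordering, and cell-cycle-marker quadrant analysis.
#
# All responses are unitless because they derive from ratios of camera
# intensities; the basal level B is the mean of the first three ratio
# points, the normalized trace is R(t)/B, the final response FR is one
# minus the mean of the last three normalized points, and the initial
# response IR is one minus the mean of three normalized points shortly
# (3-5 min) after the stimulus.

split_traces <- function(traces) split(traces, traces$cell_id)

#' Quality control of single-cell traces
#'
#' Keeps a trace only if (i) the cell was tracked from the beginning to the
#' end of the movie and (ii) every monitored per-frame feature is stable:
#' the coefficient of variation of nucleus area, cell area, nuclear-marker
#' fluorescence and whole-cell sensor fluorescence must each stay below its
#' bound. Every rejection is logged with the first failing criterion.
#'
#' @param traces Long trace data.frame (see [simulate_cell_trace()]).
#' @param max_cv Named CV bounds; defaults 0.2 for `nuc_area_px`,
#'   `cell_area_px`, `nuc_marker` and `sensor_cell`.
#' @param require_full_length Reject tracks not spanning the whole movie.
#' @return List with `kept` (filtered traces) and `log` (data.frame
#'   `cell_id`, `reason`; empty if nothing was rejected).
#' @export
qc_filter <- function(traces,
                      max_cv = c(nuc_area_px = 0.2, cell_area_px = 0.2,
                                 nuc_marker = 0.2, sensor_cell = 0.2),
                      require_full_length = TRUE) {
  if (any(max_cv <= 0))
    stop_skars("CV bounds must be > 0", "skars_invalid_input")
  reasons <- list()
  keep_ids <- c()
  for (tr in split_traces(traces)) {
    id <- tr$cell_id[1]
    if (require_full_length &&
        ("full_length" %in% names(tr)) && !all(tr$full_length)) {
      reasons[[length(reasons) + 1L]] <-
        data.frame(cell_id = id, reason = "not full length")
      next
    }
    fail <- NULL
    for (feat in names(max_cv)) {
      if (!feat %in% names(tr)) next
      x <- tr[[feat]]
      if (any(is.na(x))) { fail <- paste0(feat, " missing"); break }
      cv <- stats::sd(x) / mean(x)
      if (is.finite(cv) && cv > max_cv[[feat]]) {
        fail <- paste0(feat, " variability"); break
      }
    }
    if (is.null(fail)) keep_ids <- c(keep_ids, id)
    else reasons[[length(reasons) + 1L]] <-
        data.frame(cell_id = id, reason = fail)
  }
  list(kept = traces[traces$cell_id %in% keep_ids, , drop = FALSE],
       log = if (length(reasons)) do.call(rbind, reasons)
             else data.frame(cell_id = integer(0), reason = character(0)))
}

#' Basal level of a ratio trace
#'
#' Mean of the first three time points of the nuclear-to-cytoplasmic ratio.
#'
#' @param ratio Ratio values ordered by time (>= 3 points).
#' @return The basal level B.
#' @examples
#' basal_level(c(3.0, 3.2, 3.1, 2.0))  # 3.1
#' @export
basal_level <- function(ratio) {
  if (length(ratio) < 3L || any(!is.finite(ratio[1:3])))
    stop_skars("need >= 3 finite pre-stimulus ratio points",
               "skars_insufficient_data")
  mean(ratio[1:3])
}

# The three points used for the initial response: those inside
# [stim + window[1], stim + window[2]]; if the sampling puts fewer than 3
# points inside, the 3 points nearest the window are used.
initial_window_idx <- function(times, stim_time, window = c(3, 5)) {
  lo <- stim_time + window[1]; hi <- stim_time + window[2]
  inside <- which(times >= lo & times <= hi)
  if (length(inside) >= 3L) return(inside[1:3])
  d <- pmax(lo - times, times - hi, 0)
  idx <- order(d, times)[1:3]
  sort(idx)
}

#' Initial and final response of one trace
#'
#' The trace is normalized by its basal level; the final response is one
#' minus the mean of the last three normalized points, and the initial
#' response is one minus the mean of three normalized points shortly after
#' the stimulus (by default 3--5 minutes after it). Both are unitless;
#' positive values mean nuclear exit of the sensor.
#'
#' @param times Times in minutes.
#' @param ratio Ratio values at `times`.
#' @param stim_time Stimulus time in minutes.
#' @param initial_window Window (min, max) in minutes after the stimulus for
#'   the initial response.
#' @return Named vector `c(B, IR, FR)`.
#' @examples
#' response_features(0:11, c(1, 1, 1, 1, 1, 1, 1, 1, 0.9, 0.8, 0.7, 0.6),
#'                   stim_time = 5)
#' @export
response_features <- function(times, ratio, stim_time = 0,
                              initial_window = c(3, 5)) {
  if (length(times) != length(ratio) || length(ratio) < 6L)
    stop_skars("need >= 6 matched (time, ratio) points",
               "skars_insufficient_data")
  if (any(!is.finite(ratio)))
    stop_skars("trace contains non-finite ratios", "skars_insufficient_data")
  B <- basal_level(ratio)
  nr <- ratio / B
  n <- length(nr)
  FR <- 1 - mean(nr[(n - 2):n])
  idx <- initial_window_idx(times, stim_time, initial_window)
  IR <- 1 - mean(nr[idx])
  c(B = B, IR = IR, FR = FR)
}

#' Derive the responder threshold from a signaling-dead control
#'
#' Cells carrying a non-docking (or otherwise non-functional) sensor show no
#' kinase-driven relocation, so their final responses sample the
#' no-response noise distribution. The threshold separating responding from
#' non-responding cells is taken as the `q`-th percentile of the control
#' final responses, giving an expected false-positive rate of `100 - q`
#' percent.
#'
#' @param control_fr Final responses of control cells (>= 20 values).
#' @param q Percentile (default 95).
#' @return The threshold, with the control summary attached as attribute
#'   `"control_summary"`.
#' @export
derive_threshold <- function(control_fr, q = 95) {
  if (length(control_fr) < 20L)
    stop_skars(paste("need >= 20 control cells to derive a threshold;",
                     "use a fixed threshold (e.g. 0.2) instead"),
               "skars_insufficient_data")
  theta <- unname(stats::quantile(control_fr, q / 100, type = 7))
  attr(theta, "control_summary") <-
    c(n = length(control_fr), mean = mean(control_fr),
      sd = stats::sd(control_fr), q = q)
  theta
}

#' Classify a cell from its initial and final response
#'
#' A cell whose final response is below the threshold is non-responding.
#' Among responders, a final response more than `slow_factor` times the
#' initial response (default 1.5, i.e. a more than 50% difference) marks a
#' delayed, slow response; otherwise the cell is responding. Boundary
#' values (`FR == theta`, `FR == slow_factor * IR`) classify as responding.
#'
#' @param IR,FR Initial and final response (vectors of equal length).
#' @param theta Responder threshold on the final response.
#' @param slow_factor Slow-response factor (default 1.5).
#' @return Character vector in
#'   `c("responding", "slow", "non_responding")`.
#' @examples
#' classify_response(IR = c(0.3, 0.1, 0.4), FR = c(0.35, 0.3, 0.1),
#'                   theta = 0.2)
#' @export
classify_response <- function(IR, FR, theta, slow_factor = 1.5) {
  stopifnot(length(IR) == length(FR))
  if (any(!is.finite(IR)) || any(!is.finite(FR)))
    stop_skars("IR and FR must be finite", "skars_invalid_input")
  out <- ifelse(FR < theta, "non_responding",
                ifelse(FR > slow_factor * IR, "slow", "responding"))
  out
}

#' Per-cell response features of a trace table
#'
#' Computes, for every cell, the basal level, normalized trace, initial and
#' final response, responder class and (when marker channels are present)
#' the pre-stimulus cell-cycle marker enrichment
#' `E = mean(nuclear - cytoplasmic marker intensity)`.
#'
#' @param traces Long trace data.frame.
#' @param stim_time Stimulus time in minutes.
#' @param theta Responder threshold (e.g. from [derive_threshold()] or the
#'   fixed 0.2 used for cell-wall-stress experiments).
#' @param slow_factor Slow-response factor.
#' @param initial_window Initial-response window, minutes after stimulus.
#' @return List with `features` (one row per cell: `cell_id`, `B`, `IR`,
#'   `FR`, `class`, `marker_E`) and `normalized` (the input traces with a
#'   `norm_ratio` column).
#' @export
compute_trace_features <- function(traces, stim_time = 0, theta = 0.2,
                                   slow_factor = 1.5,
                                   initial_window = c(3, 5)) {
  per_cell <- split_traces(traces)
  feats <- lapply(per_cell, function(tr) {
    tr <- tr[order(tr$time_min), ]
    f <- response_features(tr$time_min, tr$ratio, stim_time, initial_window)
    E <- if (all(c("ccm_nuc", "ccm_cyto") %in% names(tr))) {
      pre <- tr$time_min < stim_time
      if (!any(pre)) pre <- seq_len(min(3L, nrow(tr)))
      mean(tr$ccm_nuc[pre] - tr$ccm_cyto[pre])
    } else NA_real_
    data.frame(cell_id = tr$cell_id[1], B = f[["B"]], IR = f[["IR"]],
               FR = f[["FR"]], marker_E = E)
  })
  features <- do.call(rbind, feats)
  rownames(features) <- NULL
  features$class <- classify_response(features$IR, features$FR, theta,
                                      slow_factor)
  norm <- do.call(rbind, lapply(per_cell, function(tr) {
    tr <- tr[order(tr$time_min), ]
    tr$norm_ratio <- tr$ratio / basal_level(tr$ratio)
    tr
  }))
  rownames(norm) <- NULL
  list(features = features[order(features$cell_id), , drop = FALSE],
       normalized = norm)
}

#' Population summary of ratio traces
#'
#' Median and 25th/75th percentile of the (normalized) ratio at every time
#' point, the standard population display for relocation time courses.
#' Percentiles interpolate linearly between order statistics.
#'
#' @param traces Long trace data.frame.
#' @param value Column to summarize (`"ratio"` or `"norm_ratio"`).
#' @return Data.frame `time_min`, `median`, `p25`, `p75`.
#' @export
population_summary <- function(traces, value = "ratio") {
  if (!value %in% names(traces))
    stop_skars(sprintf("column '%s' not found", value), "skars_invalid_input")
  grids <- tapply(traces$time_min, traces$cell_id, function(x)
    paste(sort(x), collapse = ","))
  if (length(unique(grids)) > 1L)
    stop_skars("traces are not on a common time grid", "skars_alignment_error")
  sp <- split(traces[[value]], traces$time_min)
  tt <- as.numeric(names(sp))
  ord <- order(tt)
  data.frame(time_min = tt[ord],
             median = vapply(sp, stats::median, numeric(1))[ord],
             p25 = vapply(sp, stats::quantile, numeric(1), probs = 0.25)[ord],
             p75 = vapply(sp, stats::quantile, numeric(1), probs = 0.75)[ord],
             row.names = NULL)
}

#' Order cells for the response heat map
#'
#' Cells are grouped in class blocks (responding, slow, non-responding) and
#' sorted by descending final response within each block, ties broken by
#' cell id — the layout used to display single-cell relocation responses,
#' with the basal level carried along as the per-row annotation.
#'
#' @param features Feature table from [compute_trace_features()].
#' @return Data.frame in display order with `cell_id`, `class`, `FR`, `B`
#'   and the block boundaries as attribute `"class_boundaries"` (row index
#'   of the last cell of each class present).
#' @export
sort_for_heatmap <- function(features) {
  lev <- c("responding", "slow", "non_responding")
  blk <- match(features$class, lev)
  ord <- order(blk, -features$FR, features$cell_id)
  out <- features[ord, c("cell_id", "class", "FR", "B"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "class_boundaries") <-
    cumsum(table(factor(out$class, levels = lev)))
  out
}

# Exhaustive 1D Otsu threshold: midpoint maximizing the between-class
# variance of the two groups.
otsu_threshold <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L || diff(range(x)) == 0) return(stats::median(x))
  cand <- (x[-n] + x[-1]) / 2
  best <- -Inf; thr <- cand[1]
  csum <- cumsum(x); tot <- csum[n]
  for (k in seq_len(n - 1L)) {
    w1 <- k / n; w2 <- 1 - w1
    m1 <- csum[k] / k; m2 <- (tot - csum[k]) / (n - k)
    v <- w1 * w2 * (m1 - m2)^2
    if (v > best) { best <- v; thr <- cand[k] }
  }
  thr
}

#' Cell-cycle-marker quadrant analysis
#'
#' Splits cells into four quadrants by crossing the pre-stimulus marker
#' enrichment `E` (nuclear minus cytoplasmic marker intensity; positive
#' means a nuclear marker such as Whi5 in G1) against responder status
#' (final response at or above the threshold). `E` must exceed the marker
#' threshold strictly to count as marker-positive. Returns the quadrant
#' label of every cell, quadrant counts, and the mean normalized trace per
#' quadrant.
#'
#' @param features Feature table from [compute_trace_features()] with
#'   `marker_E`.
#' @param normalized Normalized traces (the `normalized` element of
#'   [compute_trace_features()]).
#' @param tau_m Marker enrichment threshold; a number, or `"otsu"` to place
#'   it automatically between the two enrichment modes.
#' @param theta Responder threshold on the final response.
#' @return List with `features` (input plus `marker_state`, `quadrant`),
#'   `counts` (named quadrant counts), `mean_traces` (data.frame
#'   `quadrant`, `time_min`, `mean_norm_ratio`) and `tau_m`.
#' @export
marker_quadrants <- function(features, normalized, tau_m = 0, theta = 0.2) {
  if (all(is.na(features$marker_E)))
    stop_skars("no pre-stimulus marker measurements available",
               "skars_invalid_input")
  if (identical(tau_m, "otsu")) tau_m <- otsu_threshold(features$marker_E)
  features$marker_state <- ifelse(features$marker_E > tau_m,
                                  "nuclear", "cytoplasmic")
  features$quadrant <- paste0(
    ifelse(features$marker_state == "nuclear", "marker_pos_", "marker_neg_"),
    ifelse(features$FR >= theta, "responding", "non_responding"))
  counts <- table(features$quadrant)
  normalized$quadrant <-
    features$quadrant[match(normalized$cell_id, features$cell_id)]
  mt <- stats::aggregate(norm_ratio ~ quadrant + time_min, data = normalized,
                         FUN = mean)
  names(mt)[names(mt) == "norm_ratio"] <- "mean_norm_ratio"
  mt <- mt[order(mt$quadrant, mt$time_min), ]
  rownames(mt) <- NULL
  list(features = features, counts = counts, mean_traces = mt, tau_m = tau_m)
}
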