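# Shared fixtures and independent oracles.

with_seed_test <- function(seed, expr) {
  set.seed(seed)
  expr
}

default_params <- function() sensor_params()

# Oracle: steady-state ratio by long-horizon numerical integration,
# independent of the algebraic fixed-point solve under test.
ratio_by_integration <- function(params, activity, t_end = 1e4) {
  pr <- activity_profile(form = "constant", A0 = activity)
  y0 <- c(params$total_sensor / 2, 0, params$total_sensor / 2, 0)
  tr <- simulate_relocation(params, pr, times = c(0, t_end / 2, t_end),
                            initial = y0, rtol = 1e-10, atol = 1e-12)
  tr$ratio[3]
}

# Oracle: invert the steady-state ratio by bisection on activity.
activity_by_bisection <- function(params, target_ratio) {
  stats::uniroot(function(a) steady_state_ratio(params, a) - target_ratio,
                 c(0, 1), tol = 1e-9)$root
}

# Oracle: brute-force Minkowski dilation of a binary mask by a digital disk
# (double loop over structuring-element offsets).
brute_dilate <- function(mask, r) {
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, ]
  idx <- which(mask, arr.ind = TRUE)
  for (k in seq_len(nrow(offs))) {
    rr <- idx[, 1] + offs$dy[k]
    cc <- idx[, 2] + offs$dx[k]
    ok <- rr >= 1 & rr <= nrow(mask) & cc >= 1 & cc <= ncol(mask)
    out[cbind(rr[ok], cc[ok])] <- TRUE
  }
  out
}

# Rasterized disk mask on an h x w grid (row = y, col = x).
disk_mask <- function(h, w, cy, cx, r) {
  outer(seq_len(h), seq_len(w), function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}

# A small noise-free movie with known geometry for segmentation tests.
toy_movie <- function(n_cells = 2, n_frames = 3, seed = 1, noise_sd = 0,
                      width = 128L, jitter_px = 1L) {
  spec <- cohort_spec(n_cells = n_cells,
                      timepoints = seq(0, by = 3, length.out = n_frames),
                      stim_time = 0, seed = seed)
  render_frames(generate_cohort(spec),
                frame_spec(width = width, height = width,
                           noise_sd = noise_sd, jitter_px = jitter_px))
}

# Flat synthetic traces with exactly known ratios, for formula tests.
toy_trace <- function(ratios, times = seq_along(ratios) - 1, id = 1L) {
  data.frame(cell_id = id, time_min = times,
             nuc_sensor = ratios * 100, cyto_sensor = 100, ratio = ratios,
             nuc_marker = 800, sensor_cell = 150,
             nuc_area_px = 50, cell_area_px = 420,
             ccm_nuc = 300, ccm_cyto = 300, full_length = TRUE)
}
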