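# Synthetic multi-channel time-lapse rendering with ground-truth masks.
#
# Cells are flat disks (no point-spread function: at a 40x-like scale cells
# are large relative to pixels). Channels emulate a typical SKARS
# acquisition: a nuclear-marker channel (bright nuclei), the sensor channel
# (cytoplasm at a reference intensity, nucleus at reference x planted
# ratio), a cell-body channel standing in for a brightfield-derived cell
# mask, and an optional cell-cycle marker channel.

#' Specification of rendered synthetic frames
#'
#' @param width,height Image size in pixels.
#' @param cell_radius,nuc_radius Ranges (min, max) of cell and nucleus radii
#'   in pixels; nuclei always fit strictly inside their cell.
#' @param background Background intensity (all channels, \[0, 1\] scale).
#' @param noise_sd Per-pixel additive Gaussian noise sd (0 = noise-free).
#' @param jitter_px Per-frame integer jitter of cell positions (pixels),
#'   emulating stage drift / cell wobble.
#' @param sensor_cyto Cytoplasmic sensor intensity; the nuclear sensor
#'   intensity is `sensor_cyto` times the cell's planted ratio.
#' @param nucmarker_int Nuclear-marker intensity inside nuclei.
#' @param body_int Cell-body intensity inside cells.
#' @param ccm_nuc,ccm_cyto Cell-cycle-marker intensities for marker-nuclear
#'   cells (nucleus) and for the cytoplasm / marker-negative cells.
#' @return An object of class `frame_spec`.
#' @export
frame_spec <- function(width = 256L, height = 256L,
                       cell_radius = c(11, 14), nuc_radius = c(4, 5),
                       background = 0.05, noise_sd = 0.01, jitter_px = 1L,
                       sensor_cyto = 0.12, nucmarker_int = 0.8,
                       body_int = 0.7, ccm_nuc = 0.6, ccm_cyto = 0.3) {
  if (nuc_radius[2] >= cell_radius[1])
    stop_skars("nucleus radii must be smaller than cell radii",
               "skars_spec_error")
  structure(list(width = as.integer(width), height = as.integer(height),
                 cell_radius = cell_radius, nuc_radius = nuc_radius,
                 background = background, noise_sd = noise_sd,
                 jitter_px = as.integer(jitter_px),
                 sensor_cyto = sensor_cyto, nucmarker_int = nucmarker_int,
                 body_int = body_int, ccm_nuc = ccm_nuc,
                 ccm_cyto = ccm_cyto),
            class = "frame_spec")
}

disk_pixels <- function(cx, cy, r, width, height) {
  xs <- max(1L, floor(cx - r)):min(width, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(height, ceiling(cy + r))
  g <- expand.grid(x = xs, y = ys)
  g <- g[(g$x - cx)^2 + (g$y - cy)^2 <= r^2, , drop = FALSE]
  cbind(g$x, g$y)
}

place_cells <- function(n, frames, max_attempts = 200L * max(n, 1L)) {
  rmax <- frames$cell_radius[2]
  gap <- 2 + 2 * frames$jitter_px
  margin <- rmax + frames$jitter_px + 1
  xs <- numeric(0); ys <- numeric(0); rs <- numeric(0)
  attempts <- 0L
  while (length(xs) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop_skars(paste("could not place all cells without overlap;",
                       "use fewer or smaller cells or a larger field"),
                 "skars_geometry_error")
    r <- stats::runif(1, frames$cell_radius[1], frames$cell_radius[2])
    x <- stats::runif(1, margin, frames$width - margin)
    y <- stats::runif(1, margin, frames$height - margin)
    if (length(xs) == 0 ||
        all(sqrt((xs - x)^2 + (ys - y)^2) > rs + r + gap)) {
      xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r)
    }
  }
  data.frame(x = xs, y = ys, r_cell = rs)
}

#' Render a synthetic multi-channel time-lapse movie
#'
#' Places the cohort's cells in the field without overlap (rejection
#' sampling), renders each channel at every time point, and emits per-frame
#' ground-truth nucleus and cell label masks. In the sensor channel the mean
#' nuclear-to-cytoplasmic intensity ratio of each cell equals its planted
#' ratio (exactly when `noise_sd = 0`).
#'
#' @param cohort A [generate_cohort()] result.
#' @param frames A [frame_spec()].
#' @param params A [sensor_params()] object used for the planted kinetics.
#' @param channels Channels to render, subset of
#'   `c("nuclear", "sensor", "body", "marker")`.
#' @return An object of class `skars_movie`: list with `images` (named list
#'   of `height x width x n_frames` arrays), `nuclei_masks` and `cell_masks`
#'   (label arrays, cell id = label), `truth` (per cell and frame: planted
#'   position and ratio), `times`.
#' @examples
#' co <- generate_cohort(cohort_spec(n_cells = 2, timepoints = 0:3, seed = 1))
#' mv <- render_frames(co, frame_spec(noise_sd = 0))
#' dim(mv$images$sensor)
#' @export
render_frames <- function(cohort, frames = frame_spec(),
                          params = sensor_params(),
                          channels = c("nuclear", "sensor", "body", "marker")) {
  stopifnot(inherits(cohort, "skars_cohort"), inherits(frames, "frame_spec"))
  channels <- match.arg(channels, several.ok = TRUE)
  spec <- cohort$spec
  cells <- cohort$cells
  n <- nrow(cells)
  times <- spec$timepoints
  nt <- length(times)
  W <- frames$width; H <- frames$height

  with_seed(spec$seed + 2L, {
    geom <- if (n > 0) {
      g <- place_cells(n, frames)
      g$r_nuc <- stats::runif(n, frames$nuc_radius[1], frames$nuc_radius[2])
      g
    } else data.frame(x = numeric(0), y = numeric(0),
                      r_cell = numeric(0), r_nuc = numeric(0))

    ratios <- if (n > 0)
      t(vapply(seq_len(n), function(i)
        planted_ratio(cells[i, ], params, times), numeric(nt)))
    else matrix(0, 0, nt)
    if (n == 1) ratios <- matrix(ratios, 1, nt)

    imgs <- lapply(channels, function(ch) array(0, dim = c(H, W, nt)))
    names(imgs) <- channels
    nuc_masks <- array(0L, dim = c(H, W, nt))
    cell_masks <- array(0L, dim = c(H, W, nt))
    truth <- vector("list", nt)

    for (f in seq_len(nt)) {
      ch_mat <- lapply(channels, function(ch)
        matrix(frames$background, H, W))
      names(ch_mat) <- channels
      nm <- matrix(0L, H, W); cm <- matrix(0L, H, W)
      jvals <- seq.int(-frames$jitter_px, frames$jitter_px)
      jx <- if (f == 1 || n == 0 || length(jvals) == 1L) integer(n) else
        sample(jvals, n, replace = TRUE)
      jy <- if (f == 1 || n == 0 || length(jvals) == 1L) integer(n) else
        sample(jvals, n, replace = TRUE)
      for (i in seq_len(n)) {
        cx <- geom$x[i] + jx[i]; cy <- geom$y[i] + jy[i]
        cp <- disk_pixels(cx, cy, geom$r_cell[i], W, H)
        np <- disk_pixels(cx, cy, geom$r_nuc[i], W, H)
        ci <- cbind(cp[, 2], cp[, 1])   # (row = y, col = x)
        ni <- cbind(np[, 2], np[, 1])
        cm[ci] <- i
        nm[ni] <- i
        if ("body" %in% channels) ch_mat$body[ci] <- frames$body_int
        if ("nuclear" %in% channels)
          ch_mat$nuclear[ni] <- frames$nucmarker_int
        if ("sensor" %in% channels) {
          ch_mat$sensor[ci] <- frames$sensor_cyto
          ch_mat$sensor[ni] <- frames$sensor_cyto * ratios[i, f]
        }
        if ("marker" %in% channels) {
          ch_mat$marker[ci] <- frames$ccm_cyto
          if (isTRUE(cells$marker_nuclear[i]))
            ch_mat$marker[ni] <- frames$ccm_nuc
        }
      }
      for (ch in channels) {
        m <- ch_mat[[ch]]
        if (frames$noise_sd > 0)
          m <- m + matrix(stats::rnorm(H * W, 0, frames$noise_sd), H, W)
        imgs[[ch]][, , f] <- pmin(pmax(m, 0), 1)
      }
      nuc_masks[, , f] <- nm
      cell_masks[, , f] <- cm
      truth[[f]] <- if (n > 0)
        data.frame(cell_id = cells$cell_id, frame = f, time_min = times[f],
                   x = geom$x + jx, y = geom$y + jy,
                   r_cell = geom$r_cell, r_nuc = geom$r_nuc,
                   ratio = ratios[, f])
      else NULL
    }
    structure(list(images = imgs, nuclei_masks = nuc_masks,
                   cell_masks = cell_masks,
                   truth = do.call(rbind, truth), times = times,
                   cells = cells),
              class = "skars_movie")
  })
}

#' Write and read image stacks as multi-page TIFF
#'
#' Intensity stacks are written as 32-bit float TIFF in \[0, 1\]; label
#' stacks as 16-bit integer TIFF.
#'
#' @param x A `height x width x n_frames` numeric (intensity) or integer
#'   (label) array.
#' @param path Output file.
#' @return `read_image_stack()` / `read_label_stack()` return arrays of the
#'   same shape.
#' @export
write_image_stack <- function(x, path) {
  pages <- lapply(seq_len(dim(x)[3]), function(f) x[, , f])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
}

#' @rdname write_image_stack
#' @export
write_label_stack <- function(x, path) {
  if (max(x) > 65535L) stop_skars("too many labels for 16-bit storage",
                                  "skars_invalid_input")
  pages <- lapply(seq_len(dim(x)[3]), function(f) x[, , f] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_label_stack <- function(path) {
  x <- read_image_stack(path)
  array(as.integer(round(x * 65535)), dim = dim(x))
}
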