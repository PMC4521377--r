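# Image quantification: nuclei by thresholding the nuclear-marker channel,
# cell contours by seeded region growing on a cell-body channel, cytoplasm
# rings by subtracting the dilated nucleus, nearest-centroid tracking, and
# per-object intensity extraction. Label maps are integer matrices with 0 =
# background; objects are connected components as labelled by EBImage.

relabel <- function(lab) {
  u <- sort(unique(as.integer(lab[lab > 0])))
  if (length(u) == 0) return(matrix(0L, nrow(lab), ncol(lab)))
  m <- integer(max(u)); m[u] <- seq_along(u)
  out <- lab
  out[lab > 0] <- m[as.integer(lab[lab > 0])]
  matrix(as.integer(out), nrow(lab), ncol(lab))
}

label_centroids <- function(lab) {
  idx <- which(lab > 0, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(label = integer(0), row = numeric(0), col = numeric(0)))
  l <- as.integer(lab[idx])
  data.frame(label = sort(unique(l)),
             row = as.numeric(tapply(idx[, 1], l, mean)),
             col = as.numeric(tapply(idx[, 2], l, mean)))
}

digital_disk <- function(r) {
  d <- seq(-r, r)
  k <- outer(d, d, function(x, y) as.numeric(x^2 + y^2 <= r^2))
  k
}

#' Segment nuclei by thresholding the nuclear-marker channel
#'
#' Pixels above the threshold (Otsu by default, or a fixed value) are
#' grouped into connected components, which are then filtered by area.
#' A constant image yields an empty label map.
#'
#' @param img 2D intensity matrix (values in \[0, 1\] for Otsu).
#' @param threshold Fixed threshold; `NULL` (default) uses Otsu's method.
#' @param min_area,max_area Area filter in pixels (defaults suit nuclei at a
#'   40x-like scale).
#' @return Integer label matrix (0 = background), labels contiguous from 1.
#' @examples
#' img <- matrix(0, 32, 32); img[10:14, 10:14] <- 1
#' max(segment_nuclei(img))
#' @export
segment_nuclei <- function(img, threshold = NULL, min_area = 20,
                           max_area = 2000) {
  stopifnot(is.matrix(img))
  if (diff(range(img)) == 0)
    return(matrix(0L, nrow(img), ncol(img)))
  if (is.null(threshold))
    threshold <- EBImage::otsu(EBImage::Image(img), range = range(img))
  mask <- img > threshold
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(img), ncol(img))
  if (max(lab) == 0) return(lab)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  bad <- which(areas < min_area | areas > max_area)
  if (length(bad)) lab[lab %in% bad] <- 0L
  relabel(lab)
}

#' Expand nuclei to whole-cell regions
#'
#' Grows each nucleus into a cell region by seeded region growing
#' (Voronoi-like propagation, [EBImage::propagate()]) restricted to a
#' cell-body mask obtained by thresholding the cell-body channel. Cell
#' regions are disjoint and always contain their nucleus. A nucleus with no
#' surrounding cell-body signal falls back to a dilated-nucleus disk and is
#' reported in the attached log.
#'
#' @param nuclei Integer label matrix of nuclei (seeds).
#' @param body 2D intensity matrix of the cell-body channel.
#' @param threshold Fixed threshold for the body mask; `NULL` uses Otsu.
#' @param fallback_radius Dilation radius (pixels) for nuclei without
#'   surrounding cell signal.
#' @return Integer label matrix of cells with the same ids as `nuclei`;
#'   attribute `"fallback"` lists ids that used the fallback disk.
#' @export
expand_to_cells <- function(nuclei, body, threshold = NULL,
                            fallback_radius = 8) {
  stopifnot(is.matrix(nuclei), is.matrix(body),
            all(dim(nuclei) == dim(body)))
  if (max(nuclei) == 0) {
    out <- matrix(0L, nrow(nuclei), ncol(nuclei))
    attr(out, "fallback") <- integer(0)
    return(out)
  }
  if (is.null(threshold)) {
    threshold <- if (diff(range(body)) == 0) Inf
    else EBImage::otsu(EBImage::Image(body), range = range(body))
  }
  mask <- body > threshold | nuclei > 0
  cells <- EBImage::propagate(EBImage::Image(body),
                              seeds = EBImage::Image(nuclei),
                              mask = EBImage::Image(mask))
  cells <- matrix(as.integer(EBImage::imageData(cells)),
                  nrow(nuclei), ncol(nuclei))
  # fallback for nuclei whose region did not grow beyond the nucleus
  ids <- sort(unique(nuclei[nuclei > 0]))
  nuc_area <- tabulate(nuclei[nuclei > 0], nbins = max(ids))
  cell_area <- tabulate(cells[cells > 0], nbins = max(ids))
  fb <- ids[cell_area[ids] <= nuc_area[ids]]
  if (length(fb)) {
    kern <- digital_disk(fallback_radius)
    for (id in fb) {
      grown <- EBImage::dilate(EBImage::Image((nuclei == id) * 1), kern)
      grown <- matrix(as.numeric(EBImage::imageData(grown)) > 0,
                      nrow(nuclei), ncol(nuclei))
      free <- grown & (cells == 0 | cells == id)
      cells[free] <- id
    }
    warning(sprintf("%d nucleus(i) had no surrounding cell signal; used fallback disk(s) of radius %g",
                    length(fb), fallback_radius), call. = FALSE)
  }
  attr(cells, "fallback") <- fb
  cells
}

#' Derive cytoplasm rings
#'
#' The cytoplasm object of each cell is the cell object minus the
#' morphological dilation (digital disk of radius `expand_px`) of its own
#' nucleus, i.e. a ring excluding a guard zone around the nucleus. Cells
#' whose cytoplasm comes out empty are reported in the attached attribute
#' and must be excluded from ratio measurements downstream.
#'
#' @param cells,nuclei Integer label matrices with matching ids.
#' @param expand_px Dilation radius in pixels (default 2).
#' @return Integer cytoplasm label matrix; attribute `"empty"` lists ids
#'   with empty cytoplasm.
#' @export
derive_cytoplasm <- function(cells, nuclei, expand_px = 2L) {
  stopifnot(is.matrix(cells), is.matrix(nuclei),
            all(dim(cells) == dim(nuclei)))
  nuc_ids <- sort(unique(nuclei[nuclei > 0]))
  cell_ids <- sort(unique(cells[cells > 0]))
  if (!all(nuc_ids %in% cell_ids))
    stop_skars("nucleus labels missing from the cell label map",
               "skars_pairing_error")
  cyto <- cells
  if (length(nuc_ids)) {
    if (expand_px > 0) {
      kern <- digital_disk(expand_px)
      for (id in nuc_ids) {
        grown <- EBImage::dilate(EBImage::Image((nuclei == id) * 1), kern)
        grown <- matrix(as.numeric(EBImage::imageData(grown)) > 0,
                        nrow(nuclei), ncol(nuclei))
        cyto[grown & cells == id] <- 0L
      }
    } else {
      cyto[nuclei > 0 & cells == nuclei] <- 0L
    }
  }
  present <- tabulate(cyto[cyto > 0], nbins = max(c(cell_ids, 1L)))
  empty <- cell_ids[present[cell_ids] == 0]
  attr(cyto, "empty") <- empty
  cyto
}

#' Track nuclei across frames by nearest centroid
#'
#' Frame-to-frame assignment links each existing track to the nearest
#' unassigned nucleus centroid within a maximum displacement gate; matches
#' are made greedily in order of ascending distance (ties broken by lower
#' label id). Unmatched nuclei start new tracks. Tracks that do not span
#' every frame are marked partial; downstream analysis keeps only cells
#' tracked from the beginning to the end of the movie.
#'
#' @param masks List of integer label matrices (one per frame) or a
#'   `height x width x n_frames` label array.
#' @param max_disp Maximum allowed frame-to-frame displacement in pixels.
#' @return A data.frame with columns `track_id`, `frame`, `label`, `row`,
#'   `col`; attribute `"full_length"` is a named logical vector per track.
#' @export
track_nuclei <- function(masks, max_disp = 10) {
  if (is.array(masks) && length(dim(masks)) == 3)
    masks <- lapply(seq_len(dim(masks)[3]), function(f) masks[, , f])
  nf <- length(masks)
  if (nf < 1) stop_skars("need >= 1 frame", "skars_invalid_input")
  rows <- list()
  last <- data.frame(track_id = integer(0), row = numeric(0),
                     col = numeric(0))
  next_id <- 1L
  for (f in seq_len(nf)) {
    cen <- label_centroids(masks[[f]])
    assigned_tr <- integer(0); assigned_lab <- integer(0)
    if (nrow(cen) > 0 && nrow(last) > 0) {
      d <- outer(last$row, cen$row, "-")^2 + outer(last$col, cen$col, "-")^2
      cand <- which(d <= max_disp^2, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(d[cand], cen$label[cand[, 2]])
        for (k in ord) {
          i <- cand[k, 1]; j <- cand[k, 2]
          if (last$track_id[i] %in% assigned_tr || j %in% assigned_lab) next
          assigned_tr <- c(assigned_tr, last$track_id[i])
          assigned_lab <- c(assigned_lab, j)
          rows[[length(rows) + 1L]] <-
            data.frame(track_id = last$track_id[i], frame = f,
                       label = cen$label[j], row = cen$row[j],
                       col = cen$col[j])
        }
      }
    }
    if (nrow(cen) > 0) {
      for (j in setdiff(seq_len(nrow(cen)), assigned_lab)) {
        rows[[length(rows) + 1L]] <-
          data.frame(track_id = next_id, frame = f, label = cen$label[j],
                     row = cen$row[j], col = cen$col[j])
        next_id <- next_id + 1L
      }
    }
    tab <- do.call(rbind, rows)
    last <- do.call(rbind, lapply(split(tab, tab$track_id), function(d)
      d[which.max(d$frame), c("track_id", "row", "col")]))
    # only tracks seen in the current frame remain eligible next frame?
    # keep all tracks eligible (a one-frame dropout may rejoin if gated in)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  frames_per_track <- tapply(tab$frame, tab$track_id, function(x)
    length(unique(x)))
  full <- frames_per_track == nf
  attr(tab, "full_length") <- full
  attr(tab, "n_frames") <- nf
  tab
}

#' Quantify per-cell intensities along tracks
#'
#' For every tracked cell and frame, measures the mean intensity over the
#' nucleus and cytoplasm masks in each requested channel, together with
#' object areas. Cells with an empty cytoplasm ring in a frame are emitted
#' with `NA` cytoplasm values and flagged.
#'
#' @param tracks Output of [track_nuclei()].
#' @param nuclei_masks,cell_masks Label arrays or lists of label matrices
#'   (per-frame labels as used in `tracks`).
#' @param images Named list of intensity stacks
#'   (`height x width x n_frames`), e.g. `list(sensor = ..., marker = ...)`.
#' @param times Acquisition times in minutes, one per frame.
#' @param expand_px Guard-zone dilation radius for the cytoplasm ring.
#' @return A data.frame with one row per cell and frame: `cell_id`, `frame`,
#'   `time_min`, `nuc_area_px`, `cell_area_px`, `cyto_area_px`,
#'   `nuc_<channel>` and `cyto_<channel>` mean intensities, `full_length`,
#'   and `flag_empty_cyto`.
#' @export
quantify_cells <- function(tracks, nuclei_masks, cell_masks, images, times,
                           expand_px = 2L) {
  as_list <- function(m) if (is.array(m) && length(dim(m)) == 3)
    lapply(seq_len(dim(m)[3]), function(f) m[, , f]) else m
  nuclei_masks <- as_list(nuclei_masks)
  cell_masks <- as_list(cell_masks)
  nf <- attr(tracks, "n_frames")
  full <- attr(tracks, "full_length")
  stopifnot(length(times) == nf, length(nuclei_masks) == nf)
  out <- list()
  for (f in seq_len(nf)) {
    nm <- nuclei_masks[[f]]; cm <- cell_masks[[f]]
    cyto <- derive_cytoplasm(cm, nm, expand_px = expand_px)
    tf <- tracks[tracks$frame == f, , drop = FALSE]
    if (nrow(tf) == 0) next
    nuc_idx <- nm[nm > 0]; cyt_idx <- cyto[cyto > 0]; cell_idx <- cm[cm > 0]
    nbins <- max(c(tf$label, 1L))
    nuc_area <- tabulate(nuc_idx, nbins = nbins)
    cell_area <- tabulate(cell_idx, nbins = nbins)
    cyto_area <- tabulate(cyt_idx, nbins = nbins)
    meas <- data.frame(cell_id = tf$track_id, frame = f,
                       time_min = times[f],
                       nuc_area_px = nuc_area[tf$label],
                       cell_area_px = cell_area[tf$label],
                       cyto_area_px = cyto_area[tf$label])
    for (ch in names(images)) {
      img <- images[[ch]][, , f]
      nsum <- rep(NA_real_, nbins); csum <- rep(NA_real_, nbins)
      ns <- tapply(img[nm > 0], nuc_idx, sum)
      nsum[as.integer(names(ns))] <- ns
      cs <- if (length(cyt_idx)) tapply(img[cyto > 0], cyt_idx, sum) else NULL
      if (!is.null(cs)) csum[as.integer(names(cs))] <- cs
      meas[[paste0("nuc_", ch)]] <- nsum[tf$label] / nuc_area[tf$label]
      meas[[paste0("cyto_", ch)]] <-
        ifelse(cyto_area[tf$label] > 0, csum[tf$label] / cyto_area[tf$label],
               NA_real_)
    }
    meas$flag_empty_cyto <- cyto_area[tf$label] == 0
    out[[f]] <- meas
  }
  res <- do.call(rbind, out)
  res <- res[order(res$cell_id, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res$full_length <- unname(full[as.character(res$cell_id)])
  res
}

#' Build single-cell ratio traces from segmentation measurements
#'
#' Converts a [quantify_cells()] table into the trace layout used by the
#' trace-analysis functions, computing the nuclear-to-cytoplasmic sensor
#' ratio and carrying the quality-control features along.
#'
#' @param meas Output of [quantify_cells()]; must contain `nuc_sensor` and
#'   `cyto_sensor` columns (i.e. a `"sensor"` channel was quantified).
#' @param nuclear_channel,marker_channel Names of the nuclear-marker and
#'   optional cell-cycle-marker channels in `meas`.
#' @return A trace data.frame (see [simulate_cell_trace()] for columns).
#' @export
traces_from_measurements <- function(meas, nuclear_channel = "nuclear",
                                     marker_channel = "marker") {
  stopifnot(all(c("nuc_sensor", "cyto_sensor") %in% names(meas)))
  tr <- data.frame(cell_id = meas$cell_id, time_min = meas$time_min,
                   nuc_sensor = meas$nuc_sensor,
                   cyto_sensor = meas$cyto_sensor,
                   ratio = ifelse(meas$flag_empty_cyto, NA_real_,
                                  meas$nuc_sensor / meas$cyto_sensor))
  nm <- paste0("nuc_", nuclear_channel)
  tr$nuc_marker <- if (nm %in% names(meas)) meas[[nm]] else NA_real_
  tr$sensor_cell <- (meas$nuc_sensor * meas$nuc_area_px +
                       meas$cyto_sensor * meas$cyto_area_px) /
    (meas$nuc_area_px + meas$cyto_area_px)
  tr$nuc_area_px <- meas$nuc_area_px
  tr$cell_area_px <- meas$cell_area_px
  mm <- paste0("nuc_", marker_channel)
  if (mm %in% names(meas)) {
    tr$ccm_nuc <- meas[[mm]]
    tr$ccm_cyto <- meas[[paste0("cyto_", marker_channel)]]
  }
  tr$full_length <- meas$full_length
  tr
}
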