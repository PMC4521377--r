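# Evaluation against ground truth: matching segmented objects to planted
# cells and computing intersection-over-union of label maps.

#' Match tracks to planted ground-truth cells
#'
#' Segmentation labels objects in scan order, so track ids generally do not
#' coincide with the planted cell ids of a synthetic movie. This matches
#' each track to the nearest planted cell centre in the first frame both
#' appear in.
#'
#' @param tracks Output of [track_nuclei()].
#' @param truth The `truth` data.frame of a [render_frames()] movie
#'   (columns `cell_id`, `frame`, `x`, `y`).
#' @return Data.frame `track_id`, `cell_id`, `dist_px` (match distance).
#' @export
match_tracks_to_truth <- function(tracks, truth) {
  first <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(d)
    d[which.min(d$frame), , drop = FALSE]))
  out <- lapply(seq_len(nrow(first)), function(i) {
    tf <- truth[truth$frame == first$frame[i], , drop = FALSE]
    # mask convention: row = y, col = x
    d <- sqrt((tf$y - first$row[i])^2 + (tf$x - first$col[i])^2)
    j <- which.min(d)
    data.frame(track_id = first$track_id[i], cell_id = tf$cell_id[j],
               dist_px = d[j])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Intersection-over-union between two label maps
#'
#' Each object of `seg` is paired with the `truth` object it overlaps most,
#' and the IoU of the pair is reported. Unmatched segmented objects get an
#' IoU of 0.
#'
#' @param seg,truth Integer label matrices.
#' @return Data.frame `seg_label`, `truth_label`, `iou`.
#' @export
label_iou <- function(seg, truth) {
  stopifnot(all(dim(seg) == dim(truth)))
  ids <- sort(unique(seg[seg > 0]))
  out <- lapply(ids, function(id) {
    m <- seg == id
    over <- truth[m]
    over <- over[over > 0]
    if (length(over) == 0)
      return(data.frame(seg_label = id, truth_label = NA_integer_, iou = 0))
    tl <- as.integer(names(which.max(table(over))))
    tm <- truth == tl
    data.frame(seg_label = id, truth_label = tl,
               iou = sum(m & tm) / sum(m | tm))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
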