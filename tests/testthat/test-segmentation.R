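# Nucleus segmentation, cell expansion, cytoplasm rings, tracking,
# quantification.

test_that("blank and constant images yield no nuclei", {
  expect_equal(max(segment_nuclei(matrix(0, 64, 64))), 0)
  expect_equal(max(segment_nuclei(matrix(0.7, 64, 64))), 0)
})

test_that("planted nuclei are found with centroids on the planted centres", {
  img <- matrix(0.05, 96, 96)
  img[disk_mask(96, 96, 30, 25, 5)] <- 0.8
  img[disk_mask(96, 96, 70, 60, 5)] <- 0.8
  lab <- segment_nuclei(img)
  expect_equal(max(lab), 2)
  cen <- skars:::label_centroids(lab)
  got <- cen[order(cen$row), ]
  expect_lt(abs(got$row[1] - 30) + abs(got$col[1] - 25), 2)
  expect_lt(abs(got$row[2] - 70) + abs(got$col[2] - 60), 2)
})

test_that("the area filter removes small objects", {
  img <- matrix(0, 64, 64)
  img[20:22, 20:22] <- 1   # 9 px
  expect_equal(max(segment_nuclei(img, min_area = 20)), 0)
  expect_equal(max(segment_nuclei(img, min_area = 5)), 1)
})

test_that("seeded expansion recovers the planted cell with high overlap", {
  mv <- toy_movie(n_cells = 1, n_frames = 2, noise_sd = 0, jitter_px = 0)
  nuc <- segment_nuclei(mv$images$nuclear[, , 1])
  cells <- expand_to_cells(nuc, mv$images$body[, , 1])
  iou <- label_iou(cells, mv$cell_masks[, , 1])
  expect_gte(iou$iou[1], 0.9)
})

test_that("adjacent cells expand to disjoint regions containing their nuclei", {
  body <- matrix(0.05, 80, 80)
  body[disk_mask(80, 80, 40, 30, 12) | disk_mask(80, 80, 40, 53, 12)] <- 0.7
  nuclei <- matrix(0L, 80, 80)
  nuclei[disk_mask(80, 80, 40, 30, 4)] <- 1L
  nuclei[disk_mask(80, 80, 40, 53, 4)] <- 2L
  cells <- expand_to_cells(nuclei, body)
  expect_true(all(cells[nuclei == 1] == 1))
  expect_true(all(cells[nuclei == 2] == 2))
  # one label per pixel is structural; check both cells are present and
  # roughly balanced
  areas <- tabulate(cells[cells > 0], 2)
  expect_true(all(areas > 200))
})

test_that("a nucleus without cell-body signal falls back to a disk", {
  body <- matrix(0, 64, 64)
  nuclei <- matrix(0L, 64, 64)
  nuclei[disk_mask(64, 64, 32, 32, 4)] <- 1L
  expect_warning(cells <- expand_to_cells(nuclei, body, fallback_radius = 6),
                 "fallback")
  expect_equal(attr(cells, "fallback"), 1L)
  expect_true(all(cells[nuclei == 1] == 1))
  expect_gt(sum(cells == 1), sum(nuclei == 1))
})

test_that("cytoplasm equals cell minus the dilated nucleus (pixel oracle)", {
  h <- 41
  cellm <- disk_mask(h, h, 21, 21, 10)
  nucm <- disk_mask(h, h, 21, 21, 3)
  cells <- matrix(0L, h, h); cells[cellm] <- 1L
  nuclei <- matrix(0L, h, h); nuclei[nucm] <- 1L
  expect_equal(sum(cellm), 317)
  cyto <- derive_cytoplasm(cells, nuclei, expand_px = 2)
  oracle <- cellm & !brute_dilate(nucm, 2)
  expect_identical(cyto == 1, oracle)
  # expand_px = 0: cytoplasm is exactly cell minus nucleus
  cyto0 <- derive_cytoplasm(cells, nuclei, expand_px = 0)
  expect_identical(cyto0 == 1, cellm & !nucm)
})

test_that("a dilation covering the whole cell flags an empty cytoplasm", {
  h <- 31
  cells <- matrix(0L, h, h); cells[disk_mask(h, h, 16, 16, 5)] <- 1L
  nuclei <- matrix(0L, h, h); nuclei[disk_mask(h, h, 16, 16, 4)] <- 1L
  cyto <- derive_cytoplasm(cells, nuclei, expand_px = 4)
  expect_equal(sum(cyto), 0)
  expect_equal(attr(cyto, "empty"), 1L)
})

test_that("mismatched label maps are rejected", {
  cells <- matrix(0L, 10, 10)
  nuclei <- matrix(0L, 10, 10); nuclei[5, 5] <- 3L
  expect_error(derive_cytoplasm(cells, nuclei),
               class = "skars_pairing_error")
})

test_that("a stationary nucleus yields one full-length track", {
  m <- matrix(0L, 32, 32); m[disk_mask(32, 32, 16, 16, 4)] <- 1L
  tr <- track_nuclei(replicate(5, m, simplify = FALSE))
  expect_equal(length(unique(tr$track_id)), 1)
  expect_true(all(attr(tr, "full_length")))
})

test_that("well-separated jittering nuclei are tracked without swaps", {
  mv <- toy_movie(n_cells = 6, n_frames = 5, seed = 10, noise_sd = 0,
                  width = 256L, jitter_px = 1L)
  tr <- track_nuclei(lapply(1:5, function(f) mv$nuclei_masks[, , f]))
  expect_equal(length(unique(tr$track_id)), 6)
  expect_true(all(attr(tr, "full_length")))
  # with ground-truth masks the labels are planted ids: no track may ever
  # change the label it follows
  swaps <- tapply(tr$label, tr$track_id, function(x) length(unique(x)))
  expect_true(all(swaps == 1))
})

test_that("a disappearing nucleus leaves a partial track", {
  m <- matrix(0L, 32, 32); m[disk_mask(32, 32, 16, 16, 4)] <- 1L
  frames <- list(m, m, matrix(0L, 32, 32), matrix(0L, 32, 32))
  tr <- track_nuclei(frames)
  expect_false(any(attr(tr, "full_length")))
})

test_that("uniform images quantify to equal nuclear and cytoplasmic means", {
  h <- 41
  cells <- matrix(0L, h, h); cells[disk_mask(h, h, 21, 21, 10)] <- 1L
  nuclei <- matrix(0L, h, h); nuclei[disk_mask(h, h, 21, 21, 3)] <- 1L
  img <- array(7, dim = c(h, h, 1))
  tr <- track_nuclei(list(nuclei))
  meas <- quantify_cells(tr, list(nuclei), list(cells),
                         list(sensor = img), times = 0)
  expect_equal(meas$nuc_sensor, 7)
  expect_equal(meas$cyto_sensor, 7)
  expect_false(meas$flag_empty_cyto)
})

test_that("measured ratios match planted ratios on a noise-free movie", {
  mv <- toy_movie(n_cells = 5, n_frames = 3, seed = 4, noise_sd = 0,
                  width = 200L)
  nuc <- lapply(1:3, function(f) segment_nuclei(mv$images$nuclear[, , f]))
  cells <- lapply(1:3, function(f)
    expand_to_cells(nuc[[f]], mv$images$body[, , f]))
  trk <- track_nuclei(nuc)
  meas <- quantify_cells(trk, nuc, cells, mv$images["sensor"], mv$times[1:3])
  mp <- match_tracks_to_truth(trk, mv$truth)
  meas$cell_id <- mp$cell_id[match(meas$cell_id, mp$track_id)]
  key <- paste(meas$cell_id, meas$frame)
  planted <- mv$truth$ratio[match(key, paste(mv$truth$cell_id,
                                             mv$truth$frame))]
  ratio <- meas$nuc_sensor / meas$cyto_sensor
  expect_true(all(abs(ratio - planted) / planted < 0.01))
})

test_that("empty-cytoplasm cells are flagged and excluded from the ratio", {
  h <- 31
  cells <- matrix(0L, h, h); cells[disk_mask(h, h, 16, 16, 5)] <- 1L
  nuclei <- matrix(0L, h, h); nuclei[disk_mask(h, h, 16, 16, 4)] <- 1L
  img <- array(3, dim = c(h, h, 1))
  tr <- track_nuclei(list(nuclei))
  meas <- quantify_cells(tr, list(nuclei), list(cells),
                         list(sensor = img), times = 0, expand_px = 4)
  expect_true(meas$flag_empty_cyto)
  expect_true(is.na(meas$cyto_sensor))
  traces <- traces_from_measurements(meas)
  expect_true(is.na(traces$ratio))
})
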