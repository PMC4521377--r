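# Trace statistics: QC, basal level, responses, classification, summaries,
# ordering, marker quadrants.

test_that("basal level is the mean of the first three ratio points", {
  expect_equal(basal_level(c(3.0, 3.2, 3.1, 2, 1)), 3.1)
  expect_equal(basal_level(c(1, 1, 1)), 1)
  expect_error(basal_level(c(1, 2)), class = "skars_insufficient_data")
})

test_that("initial and final responses follow their defining formulas", {
  # normalized last three points 0.6 -> FR = 0.4
  r <- c(1, 1, 1, 1, 1, 0.6, 0.6, 0.6)
  f <- response_features(0:7, r, stim_time = 0)
  expect_equal(f[["FR"]], 0.4)
  # flat normalized trace: IR = FR = 0
  f0 <- response_features(0:7, rep(2, 8), stim_time = 0)
  expect_equal(f0[["IR"]], 0)
  expect_equal(f0[["FR"]], 0)
  # points at 3, 4, 5 min post-stimulus with normalized 0.9, 0.8, 0.7
  r2 <- c(1, 1, 1, 0.9, 0.8, 0.7, 0.5, 0.5, 0.5)
  f2 <- response_features(c(0, 1, 2, 3, 4, 5, 9, 10, 11), r2, stim_time = 0)
  expect_equal(f2[["IR"]], 0.2)
  expect_equal(f2[["FR"]], 0.5)
})

test_that("the initial window picks the three points nearest 3-5 min", {
  # 2-min sampling: only 4 min falls inside; take the 3 nearest in time
  idx <- skars:::initial_window_idx(seq(0, 20, by = 2), stim_time = 0)
  expect_equal(idx, c(2, 3, 4))   # times 2, 4, 6
  idx2 <- skars:::initial_window_idx(0:10, stim_time = 2)
  expect_equal(idx2, c(6, 7, 8))  # times 5, 6, 7
})

test_that("classification applies the threshold and the 1.5x slow rule", {
  expect_equal(classify_response(0.3, 0.35, theta = 0.2), "responding")
  expect_equal(classify_response(0.1, 0.3, theta = 0.2), "slow")
  expect_equal(classify_response(0.4, 0.1, theta = 0.2), "non_responding")
  # boundary conventions: FR == theta and FR == 1.5 * IR are responding
  expect_equal(classify_response(0.2, 0.2, theta = 0.2), "responding")
  expect_equal(classify_response(0.2, 0.3, theta = 0.2), "responding")
  expect_error(classify_response(NA, 0.3, theta = 0.2),
               class = "skars_invalid_input")
})

test_that("the control-derived threshold matches the Gaussian quantile", {
  set.seed(101)
  ctrl <- stats::rnorm(1000, 0, 0.05)
  theta <- derive_threshold(ctrl, q = 95)
  expect_equal(as.numeric(theta), stats::qnorm(0.95) * 0.05,
               tolerance = 0.01 / (stats::qnorm(0.95) * 0.05))
  expect_equal(as.numeric(derive_threshold(rep(0, 50))), 0)
  expect_error(derive_threshold(stats::rnorm(10)),
               class = "skars_insufficient_data")
})

test_that("QC keeps stable full-length traces and logs every rejection", {
  good <- toy_trace(rep(3, 10), id = 1)
  partial <- toy_trace(rep(3, 10), id = 2)
  partial$full_length <- FALSE
  wobbly <- toy_trace(rep(3, 10), id = 3)
  wobbly$nuc_area_px <- c(rep(20, 5), rep(80, 5))   # CV 0.6 >> 0.2
  res <- qc_filter(rbind(good, partial, wobbly))
  expect_equal(unique(res$kept$cell_id), 1)
  expect_equal(res$log$reason[res$log$cell_id == 2], "not full length")
  expect_match(res$log$reason[res$log$cell_id == 3], "nuc_area_px")
})

test_that("responses are invariant to a common intensity rescaling", {
  spec <- cohort_spec(n_cells = 6, seed = 12)
  tr <- simulate_cohort_traces(generate_cohort(spec))
  f1 <- compute_trace_features(tr, stim_time = 5)$features
  tr2 <- tr
  tr2$nuc_sensor <- tr2$nuc_sensor * 7.3
  tr2$cyto_sensor <- tr2$cyto_sensor * 7.3
  tr2$ratio <- tr2$nuc_sensor / tr2$cyto_sensor
  f2 <- compute_trace_features(tr2, stim_time = 5)$features
  expect_equal(f1$IR, f2$IR)
  expect_equal(f1$FR, f2$FR)
  expect_equal(f1$class, f2$class)
})

test_that("population summaries give exact order statistics", {
  traces <- rbind(toy_trace(rep(1, 6), id = 1), toy_trace(rep(2, 6), id = 2),
                  toy_trace(rep(3, 6), id = 3))
  s <- population_summary(traces)
  expect_true(all(s$median == 2))
  expect_true(all(s$p25 == 1.5))
  expect_true(all(s$p75 == 2.5))
  # a single trace is its own summary
  s1 <- population_summary(toy_trace(c(3, 3, 3, 2, 2, 2)))
  expect_equal(s1$median, c(3, 3, 3, 2, 2, 2))
  expect_equal(s1$p25, s1$p75)
  # bracket property on a stochastic cohort
  tr <- simulate_cohort_traces(generate_cohort(cohort_spec(n_cells = 10,
                                                           seed = 3)))
  sb <- population_summary(tr)
  expect_true(all(sb$p25 <= sb$median & sb$median <= sb$p75))
})

test_that("misaligned time grids are rejected", {
  a <- toy_trace(rep(1, 6), id = 1)
  b <- toy_trace(rep(1, 6), times = seq(0, 10, by = 2), id = 2)
  expect_error(population_summary(rbind(a, b)),
               class = "skars_alignment_error")
})

test_that("heat-map ordering sorts by class block then descending response", {
  feats <- data.frame(cell_id = 1:6,
                      B = 3,
                      IR = c(0.3, 0.05, 0.2, 0.1, 0.3, 0.05),
                      FR = c(0.5, 0.1, 0.3, 0.3, 0.5, 0.05),
                      class = c("responding", "non_responding", "responding",
                                "slow", "responding", "non_responding"))
  ord <- sort_for_heatmap(feats)
  expect_equal(ord$cell_id, c(1, 5, 3, 4, 2, 6))
  expect_equal(unname(attr(ord, "class_boundaries")), c(3, 4, 6))
})

test_that("marker enrichment and quadrants follow their conventions", {
  tr <- rbind(toy_trace(c(3, 3, 3, 2, 2, 1.5), times = 0:5, id = 1),
              toy_trace(rep(3, 6), times = 0:5, id = 2))
  # cell 1: nuclear marker (E = 200); cell 2: none (E = 0)
  tr$ccm_nuc[tr$cell_id == 1] <- 500
  tr$ccm_cyto[tr$cell_id == 1] <- 300
  tf <- compute_trace_features(tr, stim_time = 3)
  mq <- marker_quadrants(tf$features, tf$normalized, tau_m = 0, theta = 0.2)
  f <- mq$features
  expect_equal(f$marker_state[f$cell_id == 1], "nuclear")
  # E = 0 at tau_m = 0 is marker-negative (strict > rule)
  expect_equal(f$marker_state[f$cell_id == 2], "cytoplasmic")
  expect_equal(f$quadrant[f$cell_id == 1], "marker_pos_responding")
  expect_equal(f$quadrant[f$cell_id == 2], "marker_neg_non_responding")
  expect_equal(nrow(mq$mean_traces), 2 * 6)
})

test_that("Otsu marker thresholding recovers planted marker states", {
  spec <- cohort_spec(n_cells = 80, seed = 21)
  co <- generate_cohort(spec)
  tr <- simulate_cohort_traces(co)
  tf <- compute_trace_features(tr, stim_time = 5)
  mq <- marker_quadrants(tf$features, tf$normalized, tau_m = "otsu")
  planted <- co$cells$marker_nuclear[match(mq$features$cell_id,
                                           co$cells$cell_id)]
  agree <- mean((mq$features$marker_state == "nuclear") == planted)
  expect_gte(agree, 0.95)
})
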