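# Two-compartment shuttling model: fixed points, trajectories, calibration.

test_that("steady-state ratio has the analytic limits", {
  p <- default_params()
  # no active import: passive exchange equalizes concentrations
  p0 <- sensor_params(k_imp = 0)
  expect_equal(steady_state_ratio(p0, c(0, 0.3, 1)), c(1, 1, 1))
  # zero activity: all sensor unphosphorylated, ratio = 1 + k_imp/k_diff
  expect_equal(steady_state_ratio(p, 0), 3)
  expect_equal(steady_state_ratio(sensor_params(k_imp = 2, k_diff = 0.8), 0),
               1 + 2 / 0.8)
})

test_that("algebraic fixed point agrees with long-horizon integration", {
  p <- default_params()
  for (a in c(0.25, 1)) {
    r_alg <- steady_state_ratio(p, a)
    r_ode <- ratio_by_integration(p, a)
    expect_lt(abs(r_alg - r_ode) / r_alg, 1e-6)
  }
})

test_that("steady-state ratio decreases monotonically with activity", {
  p <- default_params()
  grid <- seq(0, 1, by = 0.05)
  r <- steady_state_ratio(p, grid)
  expect_true(all(diff(r) < 0))
  # non-increasing even when k_phos = 0 (ratio constant)
  r0 <- steady_state_ratio(sensor_params(k_phos = 0), grid)
  expect_true(all(diff(r0) <= 1e-12))
})

test_that("fast phospho-turnover recovers the closed-form ratio", {
  # when (de)phosphorylation is fast relative to exchange, both compartments
  # carry the same unphosphorylated fraction f_u = k_dephos/(k_phos*A +
  # k_dephos) and the ratio tends to 1 + (k_imp/k_diff) * f_u
  for (a in c(0, 0.3, 0.7, 1)) {
    err <- sapply(c(1, 100), function(m) {
      p <- sensor_params(k_phos = 2 * m, k_dephos = 0.5 * m)
      f_u <- p$k_dephos / (p$k_phos * a + p$k_dephos)
      cf <- 1 + (p$k_imp / p$k_diff) * f_u
      abs(steady_state_ratio(p, a) - cf) / cf
    })
    expect_lt(err[2], 1e-3)
    expect_lte(err[2], err[1])   # error shrinks as turnover speeds up
  }
  # exact (not just limiting) at activity 0 for arbitrary rates
  p2 <- sensor_params(k_imp = 3, k_diff = 0.7)
  expect_equal(steady_state_ratio(p2, 0), 1 + 3 / 0.7, tolerance = 1e-12)
})

test_that("invalid parameters and activities are rejected", {
  expect_error(sensor_params(k_phos = -1), class = "skars_invalid_parameter")
  expect_error(sensor_params(vol_ratio = 0), class = "skars_invalid_parameter")
  expect_error(sensor_params(k_imp = NaN), class = "skars_invalid_parameter")
  expect_error(steady_state_ratio(default_params(), 1.2),
               class = "skars_invalid_input")
  expect_error(steady_state_ratio(default_params(), NA_real_),
               class = "skars_invalid_input")
})

test_that("a constant profile started at its steady state stays flat", {
  p <- default_params()
  pr <- activity_profile(form = "constant", A0 = 0.4)
  tr <- simulate_relocation(p, pr, times = seq(0, 30, by = 1))
  expect_equal(tr$ratio, rep(steady_state_ratio(p, 0.4), 31),
               tolerance = 1e-6)
})

test_that("activity step up gives a monotone decay to the new fixed point", {
  p <- default_params()
  pr <- activity_profile(A0 = 0, Amax = 1, t_on = 0, tau_rise = 0.01)
  tr <- simulate_relocation(p, pr, times = seq(0, 40, by = 0.5))
  expect_true(all(diff(tr$ratio) < 1e-8))
  expect_equal(tr$ratio[length(tr$ratio)], steady_state_ratio(p, 1),
               tolerance = 1e-4)
})

test_that("activity shutoff recovers the basal enrichment within minutes", {
  p <- default_params()
  y1 <- skars:::steady_state_amounts(p, 1)
  pr <- activity_profile(form = "constant", A0 = 0)
  tr <- simulate_relocation(p, pr, times = seq(0, 30, by = 0.1),
                            initial = unname(y1))
  r1 <- tr$ratio[1]
  basal <- steady_state_ratio(p, 0)
  t90 <- tr$time_min[min(which(tr$ratio >= r1 + 0.9 * (basal - r1)))]
  expect_gte(t90, 2)
  expect_lte(t90, 15)
  expect_equal(tr$ratio[nrow(tr)], basal, tolerance = 1e-3)
})

test_that("total sensor is conserved along trajectories", {
  p <- default_params()
  profiles <- list(
    activity_profile(A0 = 0.2, Amax = 0.9, t_on = 5, tau_rise = 1.5),
    activity_profile(A0 = 0.1, Amax = 0.8, t_on = 2, tau_rise = 4,
                     tau_decay = 6),
    activity_profile(form = "constant", A0 = 0.5))
  for (pr in profiles) {
    tr <- simulate_relocation(p, pr, times = seq(0, 60, by = 1))
    expect_lt(attr(tr, "conservation_drift"), 1e-6)
  }
})

test_that("compiled and R integration engines agree", {
  p <- sensor_params(k_phos = 1.3, k_dephos = 0.7, k_imp = 1.4, k_diff = 0.6)
  pr <- activity_profile(A0 = 0.1, Amax = 0.8, t_on = 4, tau_rise = 2,
                         tau_decay = 12)
  a <- simulate_relocation(p, pr, 0:25, engine = "compiled")
  b <- simulate_relocation(p, pr, 0:25, engine = "R")
  expect_equal(a$ratio, b$ratio, tolerance = 1e-7)
})

test_that("activity profiles stay in [0, 1] and honor their parameters", {
  pr <- activity_profile(A0 = 0.2, Amax = 0.9, t_on = 5, tau_rise = 1.5)
  t <- seq(-10, 100, by = 0.25)
  a <- activity_at(pr, t)
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(activity_at(pr, 4.99), 0.2)
  expect_equal(activity_at(pr, 1e5), 0.9, tolerance = 1e-6)
  # transient profile returns to baseline
  tpr <- activity_profile(A0 = 0.2, Amax = 0.6, t_on = 0, tau_rise = 1,
                          tau_decay = 3)
  expect_equal(activity_at(tpr, 1e4), 0.2, tolerance = 1e-6)
  expect_error(activity_profile(A0 = 1.4), class = "skars_invalid_parameter")
})
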