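# Two-compartment shuttling model.
#
# State: amounts of four species (nucleus volume 1, cytoplasm volume
# vol_ratio): U_n, P_n (unphosphorylated / phosphorylated nuclear) and
# U_c, P_c (cytoplasmic). Phosphorylation (rate k_phos * A(t)) and
# dephosphorylation (k_dephos) are first order on amounts and identical in
# both compartments. Passive exchange moves both species down the
# concentration gradient with flux k_diff * (c_n - c_c); active import
# moves unphosphorylated sensor into the nucleus with flux k_imp * u_c,
# where u_c is the cytoplasmic concentration. Total amount is conserved.

model_rhs <- function(t, y, parms) {
  p <- parms$p
  a <- parms$A(t)
  V <- p$vol_ratio
  un <- y[1L]; pn <- y[2L]
  uc <- y[3L] / V; pc <- y[4L] / V
  j_u <- p$k_diff * (uc - un)          # net passive flux of U into nucleus
  j_p <- p$k_diff * (pc - pn)
  imp <- p$k_imp * uc
  kp <- p$k_phos * a
  dUn <- -kp * y[1L] + p$k_dephos * y[2L] + imp + j_u
  dPn <-  kp * y[1L] - p$k_dephos * y[2L] + j_p
  dUc <- -kp * y[3L] + p$k_dephos * y[4L] - imp - j_u
  dPc <-  kp * y[3L] - p$k_dephos * y[4L] - j_p
  list(c(dUn, dPn, dUc, dPc))
}

state_ratio <- function(y, vol_ratio) {
  nuc <- y[, 1L] + y[, 2L]
  cyt <- (y[, 3L] + y[, 4L]) / vol_ratio
  nuc / cyt
}

# Algebraic fixed point for constant activity: solve the linear steady-state
# system with the conservation constraint replacing one rate equation.
steady_state_amounts <- function(params, activity) {
  p <- params
  V <- p$vol_ratio
  kp <- p$k_phos * activity
  kd <- p$k_dephos
  M <- rbind(
    c(-kp - p$k_diff,  kd,             (p$k_imp + p$k_diff) / V,  0),
    c(kp,             -kd - p$k_diff,  0,                         p$k_diff / V),
    c(p$k_diff,        0,             -kp - (p$k_imp + p$k_diff) / V, kd),
    c(1, 1, 1, 1))
  b <- c(0, 0, 0, p$total_sensor)
  y <- tryCatch(solve(M, b), error = function(e)
    stop_skars(paste0("degenerate steady state (singular system): ",
                      conditionMessage(e)), "skars_invalid_parameter"))
  if (any(y < -1e-9 * p$total_sensor))
    stop_skars("steady state has negative amounts; check parameters",
               "skars_invalid_parameter")
  stats::setNames(pmax(y, 0), c("U_n", "P_n", "U_c", "P_c"))
}

#' Steady-state nuclear-to-cytoplasmic ratio
#'
#' Nuclear:cytoplasmic concentration ratio of the sensor at the unique fixed
#' point of the shuttling model for a constant kinase activity. At zero
#' activity the ratio is exactly `1 + k_imp/k_diff`; with no active import
#' (`k_imp = 0`) passive exchange equalizes concentrations and the ratio is 1
#' for any activity. The ratio decreases monotonically with activity
#' (strictly, when `k_imp > 0` and `k_phos > 0`).
#'
#' @param params A [sensor_params()] object.
#' @param activity Kinase activity (fraction of active kinase), vector of
#'   values in \[0, 1\].
#' @return Numeric vector of ratios, one per activity.
#' @examples
#' p <- sensor_params()
#' steady_state_ratio(p, c(0, 0.5, 1))
#' @export
steady_state_ratio <- function(params, activity) {
  validate_sensor_params(params)
  if (!is.numeric(activity) || any(!is.finite(activity)) ||
      any(activity < 0 | activity > 1))
    stop_skars("activity must be in [0, 1]", "skars_invalid_input")
  vapply(activity, function(a) {
    y <- steady_state_amounts(params, a)
    (y[1L] + y[2L]) / ((y[3L] + y[4L]) / params$vol_ratio)
  }, numeric(1))
}

#' Simulate sensor relocation for an activity time course
#'
#' Integrates the shuttling model for a time-varying kinase activity and
#' returns the nuclear-to-cytoplasmic concentration ratio at the requested
#' times. By default the trajectory starts from the steady state at the
#' profile's baseline activity, so a constant profile yields a flat trace.
#'
#' @param params A [sensor_params()] object.
#' @param profile An [activity_profile()].
#' @param times Strictly increasing times in minutes.
#' @param initial Either `"steady"` (steady state at the activity evaluated
#'   at `times[1]`) or a non-negative numeric vector of the four species
#'   amounts `(U_n, P_n, U_c, P_c)`.
#' @param rtol,atol Integrator tolerances passed to [deSolve::lsoda()].
#' @param engine `"compiled"` (C right-hand side, default) or `"R"`; the two
#'   implement the same equations and agree to integrator tolerance.
#' @return A data.frame with columns `time_min`, `activity` and `ratio`.
#'   The species trajectory is attached as attribute `"states"` and the
#'   relative conservation drift of total sensor as `"conservation_drift"`.
#' @examples
#' p <- sensor_params()
#' pr <- activity_profile(A0 = 0, Amax = 1, t_on = 0, tau_rise = 0.5)
#' tr <- simulate_relocation(p, pr, times = 0:20)
#' head(tr)
#' @export
simulate_relocation <- function(params, profile, times,
                                initial = "steady",
                                rtol = 1e-8, atol = 1e-8,
                                engine = c("compiled", "R")) {
  validate_sensor_params(params)
  engine <- match.arg(engine)
  stopifnot(inherits(profile, "activity_profile"))
  if (length(times) < 2L || any(diff(times) <= 0))
    stop_skars("times must be strictly increasing, length >= 2",
               "skars_invalid_input")
  if (identical(initial, "steady")) {
    y0 <- steady_state_amounts(params, activity_at(profile, times[1L]))
  } else {
    if (!is.numeric(initial) || length(initial) != 4L || any(initial < 0))
      stop_skars("initial must be \"steady\" or 4 non-negative amounts",
                 "skars_invalid_input")
    y0 <- stats::setNames(as.numeric(initial), c("U_n", "P_n", "U_c", "P_c"))
  }
  solve_call <- if (engine == "compiled") {
    cparms <- c(params$k_phos, params$k_dephos, params$k_imp, params$k_diff,
                params$vol_ratio, profile$A0, profile$Amax, profile$t_on,
                profile$tau_rise, profile$tau_decay,
                if (profile$form == "rise") 1 else 0)
    quote(deSolve::lsoda(y0, times, func = "skars_derivs",
                         parms = cparms, dllname = "skars",
                         initfunc = "skars_initmod",
                         rtol = rtol, atol = atol * params$total_sensor,
                         hmax = max(diff(times))))
  } else {
    afun <- function(t) activity_at(profile, t)
    quote(deSolve::lsoda(y0, times, model_rhs,
                         parms = list(p = params, A = afun),
                         rtol = rtol, atol = atol * params$total_sensor,
                         hmax = max(diff(times))))
  }
  out <- tryCatch(
    eval(solve_call),
    warning = function(w)
      stop_skars(paste0("ODE integration failed: ", conditionMessage(w)),
                 "skars_simulation_error"),
    error = function(e)
      stop_skars(paste0("ODE integration failed: ", conditionMessage(e)),
                 "skars_simulation_error"))
  y <- unname(out[, 2:5, drop = FALSE])
  total <- rowSums(y)
  drift <- max(abs(total - params$total_sensor)) / params$total_sensor
  res <- data.frame(time_min = times,
                    activity = activity_at(profile, times),
                    ratio = state_ratio(y, params$vol_ratio))
  attr(res, "states") <- y
  attr(res, "conservation_drift") <- drift
  res
}

#' Build a steady-state calibration curve
#'
#' Tabulates the steady-state ratio over a grid of activities, giving the
#' monotone curve used to translate measured nuclear enrichment into kinase
#' activity. Over the physiological range the relationship is close to
#' linear, which is what makes the sensor a quantitative reporter.
#'
#' @param params A [sensor_params()] object.
#' @param activity_grid Grid of activities covering \[0, 1\], at least 11
#'   points.
#' @return An object of class `calibration_curve`: a data.frame with columns
#'   `activity` and `ratio`, strictly decreasing in activity.
#' @examples
#' cal <- build_calibration(sensor_params())
#' range(cal$ratio)
#' @export
build_calibration <- function(params, activity_grid = seq(0, 1, length.out = 21)) {
  if (length(activity_grid) < 11L)
    stop_skars("activity grid needs >= 11 points", "skars_invalid_input")
  activity_grid <- sort(activity_grid)
  if (min(activity_grid) > 0 || max(activity_grid) < 1)
    stop_skars("activity grid must cover [0, 1]", "skars_invalid_input")
  ratio <- steady_state_ratio(params, activity_grid)
  if (any(diff(ratio) >= 0))
    stop_skars(paste("calibration curve is not strictly decreasing;",
                     "the sensor is insensitive for these parameters",
                     "(e.g. k_imp = 0 or k_phos = 0)"),
               "skars_calibration_error")
  structure(data.frame(activity = activity_grid, ratio = ratio),
            class = c("calibration_curve", "data.frame"))
}

#' Infer steady-state kinase activity from a measured ratio
#'
#' Inverts a [build_calibration()] curve by monotone linear interpolation.
#' Measured ratios can fall outside the model's range because of noise;
#' ratios above the basal (maximum) ratio map to activity 0 and ratios below
#' the full-activity (minimum) ratio map to 1, with a warning reporting how
#' many values were clipped.
#'
#' @param ratio Measured nuclear-to-cytoplasmic ratio(s).
#' @param curve A `calibration_curve`.
#' @return Activities in \[0, 1\], same length as `ratio`.
#' @examples
#' cal <- build_calibration(sensor_params())
#' infer_activity_steady(c(3, 2, 1.5), cal)
#' @export
infer_activity_steady <- function(ratio, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (!is.numeric(ratio) || any(!is.finite(ratio)))
    stop_skars("ratio must be finite numeric", "skars_invalid_input")
  n_clip <- sum(ratio > max(curve$ratio) | ratio < min(curve$ratio))
  if (n_clip > 0)
    warning(sprintf("%d ratio value(s) outside the calibration range; clipped to [0, 1]",
                    n_clip), call. = FALSE)
  # curve is decreasing in activity: interpolate activity against ratio
  a <- stats::approx(x = curve$ratio, y = curve$activity, xout = ratio,
                     rule = 2)$y
  pmin(pmax(a, 0), 1)
}

# Fixed, deterministic multi-start list for the profile fit (A0, Amax,
# tau_rise in minutes); chosen to bracket fast, intermediate and slow
# responses.
fit_starts <- function() {
  list(c(A0 = 0.1, Amax = 0.8, tau_rise = 2),
       c(A0 = 0.3, Amax = 0.5, tau_rise = 8),
       c(A0 = 0.05, Amax = 0.95, tau_rise = 1))
}

#' Fit a kinase activity time course to a measured ratio trace
#'
#' Estimates the parameters of a `"rise"` [activity_profile()] (baseline
#' `A0`, plateau `Amax`, rise timescale `tau_rise`, optionally a decay
#' timescale) by bounded least squares on the difference between the
#' simulated and measured nuclear-to-cytoplasmic ratio. The sensor rate
#' constants are fixed inputs; only the activity profile is optimized.
#' Three fixed starting points guard against local minima, so the fit is
#' deterministic.
#'
#' With `normalize = TRUE` both the measured and the simulated trace are
#' divided by their own basal level (mean of the first three points) before
#' comparison, which makes the fit applicable to traces that were rescaled
#' per cell (as single-cell data normally are).
#'
#' @param times Times in minutes, strictly increasing, length >= 5.
#' @param ratio Measured ratio at `times` (single-cell or population-median
#'   trace).
#' @param params A [sensor_params()] object (held fixed).
#' @param t_on Stimulus onset time in minutes (held fixed).
#' @param fit_decay If `TRUE`, also fit `tau_decay` (transient responses).
#' @param normalize Compare basal-normalized traces instead of absolute
#'   ratios.
#' @param fix_A0 Optional fixed baseline activity. In normalized mode the
#'   absolute scale is divided out and `A0` is only weakly identified
#'   (different baselines can produce nearly the same normalized shape), so
#'   pinning it — e.g. to the unstimulated activity obtained from a
#'   steady-state dose-response inversion — makes the fit well-posed.
#' @param tau_bounds Bounds for timescales, minutes.
#' @return An object of class `activity_fit`: list with elements `profile`
#'   (the fitted [activity_profile()]), `par`, `residual_norm` (root mean
#'   squared residual), `sse`, `converged`, `fitted` (data.frame `time_min`,
#'   `ratio`, `fitted_ratio`, `activity`).
#' @examples
#' p <- sensor_params()
#' pr <- activity_profile(A0 = 0.2, Amax = 0.9, t_on = 5, tau_rise = 1.5)
#' tr <- simulate_relocation(p, pr, times = 0:30)
#' fit <- fit_activity_timecourse(tr$time_min, tr$ratio, p, t_on = 5)
#' fit$par
#' @export
fit_activity_timecourse <- function(times, ratio, params, t_on = 0,
                                    fit_decay = FALSE, normalize = FALSE,
                                    fix_A0 = NULL, tau_bounds = c(0.1, 60)) {
  validate_sensor_params(params)
  if (length(times) < 5L)
    stop_skars("need >= 5 time points to fit an activity profile",
               "skars_fit_error")
  if (length(ratio) != length(times) || any(!is.finite(ratio)))
    stop_skars("ratio must be finite and match times", "skars_fit_error")
  target <- if (normalize) ratio / mean(ratio[1:3]) else ratio

  make_profile <- function(th) {
    activity_profile(A0 = if (is.null(fix_A0)) th[["A0"]] else fix_A0,
                     Amax = th[["Amax"]], t_on = t_on,
                     tau_rise = exp(th[["log_tau"]]),
                     tau_decay = if (fit_decay) exp(th[["log_tau_decay"]]) else Inf)
  }
  objective <- function(th) {
    pr <- make_profile(th)
    sim <- tryCatch(
      simulate_relocation(params, pr, times, rtol = 1e-6, atol = 1e-8)$ratio,
      error = function(e) NULL)
    if (is.null(sim)) return(1e6)
    if (normalize) sim <- sim / mean(sim[1:3])
    sum((sim - target)^2)
  }

  lo <- c(A0 = 0, Amax = 0, log_tau = log(tau_bounds[1]))
  hi <- c(A0 = 1, Amax = 1, log_tau = log(tau_bounds[2]))
  starts <- lapply(fit_starts(), function(s)
    c(A0 = s[["A0"]], Amax = s[["Amax"]], log_tau = log(s[["tau_rise"]])))
  if (!is.null(fix_A0)) {
    lo <- lo[-1]; hi <- hi[-1]
    starts <- lapply(starts, function(s) s[-1])
  }
  if (fit_decay) {
    lo <- c(lo, log_tau_decay = log(tau_bounds[1]))
    hi <- c(hi, log_tau_decay = log(10 * tau_bounds[2]))
    starts <- lapply(starts, function(s) c(s, log_tau_decay = log(30)))
  }

  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, objective, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 200, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop_skars("activity-profile fit failed from every starting point",
               "skars_fit_error")

  profile <- make_profile(best$par)
  sim <- simulate_relocation(params, profile, times)
  fitted_ratio <- if (normalize) sim$ratio / mean(sim$ratio[1:3]) else sim$ratio
  converged <- best$convergence == 0
  if (!converged)
    warning("optimizer did not report convergence; returning best-so-far parameters",
            call. = FALSE)
  par <- c(A0 = if (is.null(fix_A0)) unname(best$par[["A0"]]) else fix_A0,
           Amax = unname(best$par[["Amax"]]),
           tau_rise = exp(unname(best$par[["log_tau"]])))
  if (fit_decay)
    par <- c(par, tau_decay = exp(unname(best$par[["log_tau_decay"]])))
  structure(list(profile = profile, par = par,
                 sse = best$value,
                 residual_norm = sqrt(best$value / length(times)),
                 converged = converged,
                 fitted = data.frame(time_min = times, ratio = target,
                                     fitted_ratio = fitted_ratio,
                                     activity = sim$activity)),
            class = "activity_fit")
}

#' @export
print.activity_fit <- function(x, ...) {
  cat("Activity time-course fit:\n")
  print(round(x$par, 4))
  cat(sprintf("  RMS residual = %.4g, converged = %s\n",
              x$residual_norm, x$converged))
  invisible(x)
}
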