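#' Sensor model parameters
#'
#' Rate constants and compartment geometry of the two-compartment relocation
#' sensor model. Phosphorylation and dephosphorylation occur with the same
#' rate constants in the nucleus and in the cytoplasm; the sensor exchanges
#' passively between compartments, and only the unphosphorylated species is
#' actively imported into the nucleus.
#'
#' The defaults are calibration-constrained rather than measured: with
#' `k_imp/k_diff = 2` the basal (zero-activity) nuclear enrichment is exactly
#' 3-fold, and the phospho-turnover rates place relocation and recovery on
#' the 2--10 minute scale typical of these reporters.
#'
#' @param k_phos Per-minute phosphorylation rate of the sensor at full kinase
#'   activity (the effective rate is `k_phos * activity`).
#' @param k_dephos Per-minute constitutive dephosphorylation rate.
#' @param k_imp Per-minute active nuclear import rate; acts on the
#'   cytoplasmic concentration of unphosphorylated sensor only.
#' @param k_diff Per-minute passive exchange rate; the flux is proportional
#'   to the nucleus--cytoplasm concentration difference and acts on both
#'   phospho-species in both directions.
#' @param vol_ratio Cytoplasm-to-nucleus volume ratio (dimensionless).
#' @param total_sensor Total sensor amount (arbitrary units); conserved.
#' @return An object of class `sensor_params`.
#' @examples
#' p <- sensor_params()
#' steady_state_ratio(p, 0)   # 3: basal three-fold nuclear enrichment
#' @export
sensor_params <- function(k_phos = 2, k_dephos = 0.5, k_imp = 1,
                          k_diff = 0.5, vol_ratio = 7, total_sensor = 100) {
  p <- list(k_phos = k_phos, k_dephos = k_dephos, k_imp = k_imp,
            k_diff = k_diff, vol_ratio = vol_ratio,
            total_sensor = total_sensor)
  validate_sensor_params(p)
  structure(p, class = "sensor_params")
}

validate_sensor_params <- function(p) {
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num))
    stop_skars("all sensor parameters must be finite numeric scalars",
               "skars_invalid_parameter")
  rates <- c("k_phos", "k_dephos", "k_imp", "k_diff")
  if (any(unlist(p[rates]) < 0))
    stop_skars("rate constants must be >= 0", "skars_invalid_parameter")
  if (p$vol_ratio <= 0 || p$total_sensor <= 0)
    stop_skars("vol_ratio and total_sensor must be > 0",
               "skars_invalid_parameter")
  invisible(p)
}

#' @export
print.sensor_params <- function(x, ...) {
  cat("Sensor model parameters (per-minute rates):\n")
  cat(sprintf("  k_phos = %g, k_dephos = %g, k_imp = %g, k_diff = %g\n",
              x$k_phos, x$k_dephos, x$k_imp, x$k_diff))
  cat(sprintf("  vol_ratio (cyt:nuc) = %g, total_sensor = %g\n",
              x$vol_ratio, x$total_sensor))
  invisible(x)
}

#' Parametric kinase activity profile
#'
#' Kinase activity is the fraction of the kinase pool in the active state,
#' a dimensionless number in \[0, 1\] as a function of time (minutes).
#' Two families are provided. `"constant"` holds activity at `A0`.
#' `"rise"` holds `A0` until the onset time and then relaxes exponentially
#' towards the plateau `Amax`:
#' \deqn{A(t) = A_0 + (A_{max} - A_0)\,(1 - e^{-(t - t_{on})/\tau_{rise}})
#'   \, e^{-(t - t_{on})/\tau_{decay}}}
#' for \eqn{t \ge t_{on}}. A finite `tau_decay` produces a transient pulse
#' that returns to baseline; `tau_decay = Inf` (default) gives a sustained
#' step response.
#'
#' @param form `"rise"` or `"constant"`.
#' @param A0 Baseline activity in \[0, 1\].
#' @param Amax Plateau activity in \[0, 1\] (ignored for `"constant"`).
#' @param t_on Onset time in minutes.
#' @param tau_rise Rise timescale in minutes (> 0).
#' @param tau_decay Decay timescale in minutes (> 0); `Inf` for no decay.
#' @return An object of class `activity_profile`.
#' @examples
#' pr <- activity_profile(A0 = 0.2, Amax = 0.9, t_on = 5, tau_rise = 1.5)
#' activity_at(pr, c(0, 5, 8, 30))
#' @export
activity_profile <- function(form = c("rise", "constant"), A0 = 0.2,
                             Amax = 0.9, t_on = 0, tau_rise = 1.5,
                             tau_decay = Inf) {
  form <- match.arg(form)
  if (!all(is.finite(c(A0, Amax))) || A0 < 0 || A0 > 1 || Amax < 0 || Amax > 1)
    stop_skars("A0 and Amax must be finite and in [0, 1]",
               "skars_invalid_parameter")
  if (!is.finite(t_on))
    stop_skars("t_on must be finite", "skars_invalid_parameter")
  if (tau_rise <= 0 || tau_decay <= 0)
    stop_skars("tau_rise and tau_decay must be > 0", "skars_invalid_parameter")
  structure(list(form = form, A0 = A0, Amax = Amax, t_on = t_on,
                 tau_rise = tau_rise, tau_decay = tau_decay),
            class = "activity_profile")
}

#' Evaluate an activity profile
#'
#' @param profile An [activity_profile()].
#' @param t Times in minutes (vector).
#' @return Activity values in \[0, 1\], same length as `t`.
#' @export
activity_at <- function(profile, t) {
  stopifnot(inherits(profile, "activity_profile"))
  if (profile$form == "constant") return(rep(profile$A0, length(t)))
  dt <- t - profile$t_on
  a <- rep(profile$A0, length(t))
  on <- dt >= 0
  decay <- if (is.finite(profile$tau_decay))
    exp(-dt[on] / profile$tau_decay) else 1
  a[on] <- profile$A0 + (profile$Amax - profile$A0) *
    (1 - exp(-dt[on] / profile$tau_rise)) * decay
  pmin(pmax(a, 0), 1)
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("Activity profile [%s]: A0 = %g, Amax = %g, t_on = %g min,",
              x$form, x$A0, x$Amax, x$t_on))
  cat(sprintf(" tau_rise = %g min, tau_decay = %g min\n",
              x$tau_rise, x$tau_decay))
  invisible(x)
}
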