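#' Fit the membrane time constant at a hyperpolarizing step onset
#'
#' Fits `V(t) = V_inf + sum_i A_i * exp(-t / tau_i)` over the segment from
#' the step onset to the (auto-detected) peak of the deflection, with one or
#' two exponential components chosen by corrected AIC. The reported
#' membrane time constant is the amplitude-weighted mean
#' `sum(|A_i| tau_i) / sum(|A_i|)`. The fit window deliberately stops at the
#' first extremum of the deflection so that slow inward rectification (sag)
#' does not contaminate the estimate.
#'
#' @param trace a [voltage_trace()] containing a negative current step
#' @param step_onset step onset time (ms)
#' @param window_end end of the fit segment (ms from onset); `NULL`
#'   auto-detects the deflection peak
#' @param max_components 1 or 2
#' @return list with `tau_m` (ms), `fit_components` (data.frame of
#'   `amplitude` mV and `tau` ms), `n_components`, `v_inf` (mV), `aicc`
#' @export
fit_tau <- function(trace, step_onset, window_end = NULL, max_components = 2) {
  stopifnot(inherits(trace, "voltage_trace"), max_components %in% 1:2)
  dt <- trace$dt
  i0 <- round(step_onset / dt) + 1
  v <- trace$samples
  if (is.null(window_end)) {
    # first local extremum of the deflection (minimum for a negative step),
    # searched on a lightly smoothed copy to ignore sample noise
    seg <- v[i0:length(v)]
    k <- max(1, round(0.5 / dt))
    sm <- stats::filter(seg, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
    sm[is.na(sm)] <- seg[is.na(sm)]
    iext <- which.max(abs(sm - sm[1]))
    window_end <- (iext - 1) * dt
  }
  i1 <- i0 + round(window_end / dt)
  i1 <- min(i1, length(v))
  if ((i1 - i0) * dt < 5)
    stop("onset-to-peak segment shorter than 5 ms; cannot fit tau")
  tt <- (seq(i0, i1) - i0) * dt
  vv <- v[i0:i1]
  if (vv[length(vv)] > vv[1] + 0.5)
    stop("segment is positive-going; fit_tau expects a hyperpolarizing step")

  v_inf0 <- vv[length(vv)]
  a0 <- vv[1] - v_inf0
  tau0 <- window_end / 3
  fits <- list()
  tau_max <- 3 * window_end  # a slower component is not resolvable
  f1 <- tryCatch(minpack.lm::nlsLM(
    vv ~ vinf + a1 * exp(-tt / t1),
    start = list(vinf = v_inf0, a1 = a0, t1 = tau0),
    lower = c(-Inf, -Inf, dt), upper = c(Inf, Inf, tau_max),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(f1)) fits$one <- f1
  if (max_components == 2) {
    f2 <- tryCatch(minpack.lm::nlsLM(
      vv ~ vinf + a1 * exp(-tt / t1) + a2 * exp(-tt / t2),
      start = list(vinf = v_inf0, a1 = a0 * 0.6, t1 = tau0 / 3,
                   a2 = a0 * 0.4, t2 = tau0 * 2),
      lower = c(-Inf, -Inf, dt, -Inf, dt),
      upper = c(Inf, Inf, tau_max, Inf, tau_max),
      control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (!is.null(f2)) fits$two <- f2
  }
  if (!length(fits)) stop("exponential fit failed to converge")

  aicc <- vapply(fits, function(f) {
    k <- length(stats::coef(f)) + 1
    n <- length(vv)
    stats::AIC(f) + 2 * k * (k + 1) / (n - k - 1)
  }, numeric(1))
  best <- fits[[which.min(aicc)]]
  cf <- stats::coef(best)
  # identifiability guard: a second component carrying under 2% of the
  # amplitude, or pinned at the tau bound, is noise fitting - keep the
  # single exponential instead
  if (length(cf) == 5 && !is.null(fits$one)) {
    amps <- abs(cf[c("a1", "a2")])
    taus <- cf[c("t1", "t2")]
    if (min(amps) / sum(amps) < 0.02 || max(taus) > 0.99 * tau_max) {
      best <- fits$one
      cf <- stats::coef(best)
    }
  }
  if (length(cf) == 3) {
    comp <- data.frame(amplitude = cf[["a1"]], tau = cf[["t1"]])
  } else {
    comp <- data.frame(amplitude = c(cf[["a1"]], cf[["a2"]]),
                       tau = c(cf[["t1"]], cf[["t2"]]))
    comp <- comp[order(comp$tau), ]
  }
  tau_m <- sum(abs(comp$amplitude) * comp$tau) / sum(abs(comp$amplitude))
  list(tau_m = tau_m, fit_components = comp, n_components = nrow(comp),
       v_inf = cf[["vinf"]], aicc = min(aicc))
}

#' Input resistance from a V-I plot
#'
#' Least-squares slope of steady-state voltage deflection against injected
#' current, in megaohms (mV/pA = GOhm, so the slope is scaled by 1000).
#'
#' @param currents injected currents (pA)
#' @param deflections steady-state voltage deflections (mV)
#' @return input resistance (MOhm)
#' @export
input_resistance <- function(currents, deflections) {
  stopifnot(length(currents) == length(deflections), length(currents) >= 2)
  if (length(unique(currents)) < 2)
    stop("need at least two distinct current amplitudes")
  slope <- stats::coef(stats::lm(deflections ~ currents))[["currents"]]
  slope * 1000  # mV/pA -> MOhm
}

#' Capacitance and estimated membrane surface area
#'
#' `C_m = tau_m / R_in` (ms / MOhm = nF, reported in pF). The surface area
#' follows from an assumed specific membrane capacitance: at 1 uF/cm^2 one
#' picofarad of membrane corresponds to 100 um^2.
#'
#' @param tau_m membrane time constant (ms)
#' @param r_in input resistance (MOhm)
#' @param specific_capacitance assumed specific capacitance (uF/cm^2)
#' @return list with `c_m` (pF) and `est_surface_area` (um^2)
#' @export
capacitance_and_area <- function(tau_m, r_in, specific_capacitance = 1.0) {
  stopifnot(tau_m > 0, r_in > 0, specific_capacitance > 0)
  c_m <- tau_m / r_in * 1000  # nF -> pF
  area <- c_m / specific_capacitance * 100  # pF / (uF/cm^2) -> um^2
  list(c_m = c_m, est_surface_area = area)
}

#' Full passive characterization from a family of current steps
#'
#' Runs hyperpolarizing steps through [fit_tau()] (most negative step) and
#' [input_resistance()] (steady-state deflections of all steps), then
#' derives capacitance and surface area.
#'
#' @param traces list of [voltage_trace()] sweeps with `step_pA`,
#'   `step_onset`, `step_duration` in `meta`
#' @param specific_capacitance uF/cm^2
#' @param steady_window window before step end used for the steady-state
#'   deflection (ms)
#' @return one-row data.frame with `tau_m`, `n_components`, `r_in`, `c_m`,
#'   `est_surface_area`
#' @export
passive_properties <- function(traces, specific_capacitance = 1.0,
                               steady_window = 20) {
  amps <- vapply(traces, function(tr) tr$meta$step_pA, numeric(1))
  defl <- vapply(traces, function(tr) {
    onset <- tr$meta$step_onset; dur <- tr$meta$step_duration; dt <- tr$dt
    base <- mean(tr$samples[seq_len(max(1, round(onset / dt)))])
    j1 <- round((onset + dur - steady_window) / dt) + 1
    j2 <- round((onset + dur) / dt)
    mean(tr$samples[j1:j2]) - base
  }, numeric(1))
  r_in <- input_resistance(amps, defl)
  neg <- which.min(amps)
  ft <- fit_tau(traces[[neg]], traces[[neg]]$meta$step_onset)
  ca <- capacitance_and_area(ft$tau_m, r_in, specific_capacitance)
  data.frame(tau_m = ft$tau_m, n_components = ft$n_components, r_in = r_in,
             c_m = ca$c_m, est_surface_area = ca$est_surface_area)
}
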