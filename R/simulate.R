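#' Step stimulation protocol
#'
#' @param mode `"current-clamp"` or `"voltage-clamp"`
#' @param baseline holding current (pA) or holding potential (mV)
#' @param steps vector of step amplitudes: injected current (pA, absolute,
#'   added to baseline) or command potentials (mV, absolute)
#' @param step_duration step length (ms)
#' @param pre_duration,post_duration baseline lengths before/after the step (ms)
#' @param dt integration step (ms)
#' @param seed integer seed for any stochastic component
#' @return a `step_protocol` list
#' @export
step_protocol <- function(mode = c("current-clamp", "voltage-clamp"),
                          baseline = 0, steps = 0, step_duration = 1000,
                          pre_duration = 100, post_duration = 100,
                          dt = 0.005, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(dt > 0, step_duration > 0, pre_duration >= 0, post_duration >= 0,
            all(is.finite(steps)))
  structure(list(mode = mode, baseline = baseline, steps = steps,
                 step_duration = step_duration, pre_duration = pre_duration,
                 post_duration = post_duration, dt = dt,
                 seed = as.integer(seed)),
            class = "step_protocol")
}

#' Uniformly sampled membrane-potential trace
#'
#' @param samples membrane potential (mV)
#' @param dt sampling interval (ms)
#' @param stimulus injected current per sample (pA) or a constant
#' @param temperature recording temperature label (degrees C)
#' @param meta free-form provenance list
#' @return a `voltage_trace` object
#' @export
voltage_trace <- function(samples, dt, stimulus = 0, temperature = NA_real_,
                          meta = list()) {
  stopifnot(dt > 0, all(is.finite(samples)))
  if (length(stimulus) == 1) stimulus <- rep(stimulus, length(samples))
  stopifnot(length(stimulus) == length(samples))
  structure(list(samples = as.numeric(samples), dt = dt,
                 stimulus = as.numeric(stimulus), temperature = temperature,
                 meta = meta),
            class = "voltage_trace")
}

#' Uniformly sampled membrane-current trace
#'
#' @param samples current (nA)
#' @param dt sampling interval (ms)
#' @param command list with `holding` (mV), `test` (mV), `step_onset` (ms),
#'   `step_duration` (ms)
#' @param meta free-form provenance list
#' @return a `current_trace` object
#' @export
current_trace <- function(samples, dt, command, meta = list()) {
  stopifnot(dt > 0, all(is.finite(samples)),
            all(c("holding", "test", "step_onset", "step_duration") %in%
                  names(command)))
  structure(list(samples = as.numeric(samples), dt = dt, command = command,
                 meta = meta),
            class = "current_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf("<voltage_trace> %d samples, dt = %g ms (%.1f ms), %g..%g mV\n",
              length(x$samples), x$dt, length(x$samples) * x$dt,
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' Time axis of a trace (ms)
#' @param trace a `voltage_trace` or `current_trace`
#' @return numeric vector of sample times starting at 0
#' @export
trace_time <- function(trace) {
  (seq_along(trace$samples) - 1) * trace$dt
}

build_stimulus <- function(protocol, amplitude) {
  n_pre <- round(protocol$pre_duration / protocol$dt)
  n_step <- round(protocol$step_duration / protocol$dt)
  n_post <- round(protocol$post_duration / protocol$dt)
  if (protocol$mode == "current-clamp") {
    c(rep(protocol$baseline, n_pre),
      rep(protocol$baseline + amplitude, n_step),
      rep(protocol$baseline, n_post))
  } else {
    c(rep(protocol$baseline, n_pre), rep(amplitude, n_step),
      rep(protocol$baseline, n_post))
  }
}

#' Simulate current-clamp recordings
#'
#' Integrates the single-compartment model under each current step of the
#' protocol. Gating rates are scaled by `q10_rates^((T - Tref)/10)` and all
#' conductances by `q10_conductance^((T - Tref)/10)`. Output is recorded at
#' 100 kHz (`dt_out = 0.01` ms) regardless of the integration step.
#'
#' @param params a [neuron_model_params()] object
#' @param protocol a [step_protocol()] in current-clamp mode
#' @param temperature bath temperature (degrees C)
#' @param noise_sd standard deviation of optional Gaussian current noise
#'   (pA, applied per integration step; 0 disables it)
#' @param dt_out output sampling interval (ms); must be a multiple of
#'   `protocol$dt`
#' @return a list of [voltage_trace()] objects, one per step amplitude,
#'   named by amplitude
#' @export
simulate_current_clamp <- function(params, protocol, temperature = 24,
                                   noise_sd = 0, dt_out = 0.01) {
  stopifnot(inherits(params, "neuron_model_params"),
            inherits(protocol, "step_protocol"),
            protocol$mode == "current-clamp", protocol$dt <= 0.02)
  record_every <- round(dt_out / protocol$dt)
  stopifnot(abs(record_every * protocol$dt - dt_out) < 1e-9, record_every >= 1)
  out <- lapply(seq_along(protocol$steps), function(i) {
    amp <- protocol$steps[i]
    stim <- build_stimulus(protocol, amp)
    if (noise_sd > 0) {
      set.seed(protocol$seed + i - 1L)
      stim <- stim + stats::rnorm(length(stim), 0, noise_sd)
    }
    sim <- .hh_simulate(params, stim, protocol$dt, record_every, temperature,
                        "current-clamp")
    voltage_trace(sim$samples, sim$dt, sim$stimulus, temperature,
                  meta = list(preset = params$label, step_pA = amp,
                              step_onset = protocol$pre_duration,
                              step_duration = protocol$step_duration,
                              seed = protocol$seed))
  })
  names(out) <- as.character(protocol$steps)
  out
}

#' Simulate a spontaneous (unstimulated) recording
#'
#' @param params a [neuron_model_params()] object
#' @param duration sweep length (ms)
#' @param temperature bath temperature (degrees C)
#' @param dt integration step (ms)
#' @param ... passed to [simulate_current_clamp()]
#' @return a single [voltage_trace()]
#' @export
simulate_spontaneous <- function(params, duration = 2000, temperature = 24,
                                 dt = 0.005, ...) {
  pr <- step_protocol("current-clamp", baseline = 0, steps = 0,
                      step_duration = duration, pre_duration = 0,
                      post_duration = 0, dt = dt)
  simulate_current_clamp(params, pr, temperature, ...)[[1]]
}

#' Simulate voltage-clamp recordings
#'
#' Perfect-clamp currents at the commanded potentials. With
#' `na_disabled = TRUE` the Na+ conductance is silenced, emulating
#' pharmacological isolation of K+ currents (TTX/Cd2+); with
#' `leak_subtract = TRUE` the leak current is removed from the output,
#' emulating acquisition-side leak subtraction.
#'
#' @param params a [neuron_model_params()] object
#' @param protocol a [step_protocol()] in voltage-clamp mode; `steps` are
#'   absolute command potentials (mV)
#' @param temperature bath temperature (degrees C)
#' @param na_disabled silence the Na+ conductance
#' @param leak_subtract remove the leak current from the output
#' @param dt_out output sampling interval (ms)
#' @return a list of [current_trace()] objects (nA), named by test potential
#' @export
simulate_voltage_clamp <- function(params, protocol, temperature = 24,
                                   na_disabled = TRUE, leak_subtract = FALSE,
                                   dt_out = 0.01) {
  stopifnot(inherits(params, "neuron_model_params"),
            inherits(protocol, "step_protocol"),
            protocol$mode == "voltage-clamp")
  record_every <- round(dt_out / protocol$dt)
  stopifnot(abs(record_every * protocol$dt - dt_out) < 1e-9, record_every >= 1)
  out <- lapply(protocol$steps, function(v_test) {
    stim <- build_stimulus(protocol, v_test)
    sim <- .hh_simulate(params, stim, protocol$dt, record_every, temperature,
                        "voltage-clamp", na_disabled = na_disabled,
                        leak_subtract = leak_subtract)
    current_trace(sim$samples / 1000, sim$dt,
                  command = list(holding = protocol$baseline, test = v_test,
                                 step_onset = protocol$pre_duration,
                                 step_duration = protocol$step_duration),
                  meta = list(preset = params$label,
                              na_disabled = na_disabled,
                              leak_subtract = leak_subtract))
  })
  names(out) <- as.character(protocol$steps)
  out
}

#' Purely passive (RC) model cell
#'
#' All active conductances zero; useful for parameter-recovery checks of the
#' passive-property estimators.
#'
#' @param capacitance membrane capacitance (pF)
#' @param g_leak leak conductance (nS); `1000 / R_in(MOhm)`
#' @param e_leak leak reversal (mV)
#' @return a [neuron_model_params()] object
#' @export
passive_cell <- function(capacitance = 100, g_leak = 5, e_leak = -70) {
  base <- make_preset("RAPN-like")
  for (ch in c("nav", "kv_low", "kv3", "kv_a")) base[[ch]]$g <- 0
  base$capacitance <- capacitance
  base$leak <- list(g = g_leak, e = e_leak)
  base$bias_current <- 0
  base$label <- "passive"
  base
}

#' Write / read a trace as delimited text with a JSON sidecar
#'
#' Two-column text (time ms, value mV or nA) plus `<path>.json` holding dt,
#' units, protocol metadata and temperature.
#'
#' @param trace a `voltage_trace` or `current_trace`
#' @param path output file path
#' @return `path`, invisibly (`write_trace`); the reconstructed trace
#'   (`read_trace`)
#' @export
write_trace <- function(trace, path) {
  value <- trace$samples
  utils::write.table(
    data.frame(time_ms = trace_time(trace), value = value),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- list(dt = trace$dt,
               class = class(trace),
               units = if (inherits(trace, "voltage_trace")) "mV" else "nA",
               temperature = if (!is.null(trace$temperature))
                 trace$temperature else NULL,
               command = trace$command, stimulus_constant =
                 if (!is.null(trace$stimulus) &&
                     length(unique(trace$stimulus)) == 1)
                   trace$stimulus[1] else NULL,
               meta = trace$meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (identical(side$class[1], "voltage_trace")) {
    voltage_trace(tab$value, side$dt,
                  stimulus = if (!is.null(side$stimulus_constant))
                    side$stimulus_constant else 0,
                  temperature = side$temperature %||% NA_real_,
                  meta = as.list(side$meta))
  } else {
    current_trace(tab$value, side$dt, command = as.list(side$command),
                  meta = as.list(side$meta))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
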