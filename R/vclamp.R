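#' Subtract two voltage-clamp sweeps (drug-sensitive current)
#'
#' Samplewise `pre - post`, the standard isolation of a drug-sensitive
#' current from sweeps recorded before and after wash-in. The two sweeps
#' must share dt, length and command protocol.
#'
#' @param pre,post [current_trace()] objects
#' @return a [current_trace()] of the difference, with both parents recorded
#'   in `meta`
#' @export
subtract_currents <- function(pre, post) {
  stopifnot(inherits(pre, "current_trace"), inherits(post, "current_trace"))
  if (pre$dt != post$dt || length(pre$samples) != length(post$samples))
    stop("protocol mismatch: dt or length differ")
  if (!isTRUE(all.equal(pre$command, post$command)))
    stop("protocol mismatch: command protocols differ")
  current_trace(pre$samples - post$samples, pre$dt, pre$command,
                meta = list(parents = list(pre = pre$meta, post = post$meta),
                            derived = "pre - post"))
}

#' Voltage-clamp step metrics: A-type peak, sustained current, inactivation
#'
#' The transient (A-type) peak is the maximum current within an early window
#' after step onset; its time is measured from the onset. The sustained
#' current is the value `sustained_time` after onset (mean over a +/-
#' `sustained_halfwidth` window for noise robustness). The degree of
#' inactivation is the current `inactivation_lag` ms after the A-type peak
#' divided by the peak. When the early maximum sits at the end of the window the
#' current is treated as non-peaking and the A-type fields are `NA` with
#' `inactivation_ratio = 1`.
#'
#' @param trace a [current_trace()] with command metadata
#' @param inactivation_lag lag after the transient peak (ms)
#' @param sustained_time time after onset of the sustained measure (ms)
#' @param peak_window early search window after onset (ms)
#' @param sustained_halfwidth half-width of the averaging window (ms)
#' @return one-row data.frame: `a_type_peak` (nA), `time_to_peak` (ms),
#'   `i_sustained` (nA), `inactivation_ratio`
#' @export
vclamp_metrics <- function(trace, inactivation_lag = 8, sustained_time = 200,
                           peak_window = 20, sustained_halfwidth = 0.5) {
  stopifnot(inherits(trace, "current_trace"))
  dt <- trace$dt
  onset <- trace$command$step_onset
  if (trace$command$step_duration < sustained_time)
    stop("step shorter than the sustained-current time")
  i_on <- round(onset / dt) + 1
  i_end <- min(round((onset + peak_window) / dt) + 1, length(trace$samples))
  seg <- trace$samples[i_on:i_end]
  ipk <- which.max(seg)
  i_sus_c <- round((onset + sustained_time) / dt) + 1
  hw <- max(0, round(sustained_halfwidth / dt))
  i_sus <- mean(trace$samples[max(1, i_sus_c - hw):
                                min(length(trace$samples), i_sus_c + hw)])
  if (ipk == length(seg)) {
    return(data.frame(a_type_peak = NA_real_, time_to_peak = NA_real_,
                      i_sustained = i_sus, inactivation_ratio = 1))
  }
  t_peak <- (ipk - 1) * dt
  i_lag <- i_on + ipk - 1 + round(inactivation_lag / dt)
  ratio <- trace$samples[min(i_lag, length(trace$samples))] / seg[ipk]
  data.frame(a_type_peak = seg[ipk], time_to_peak = t_peak,
             i_sustained = i_sus, inactivation_ratio = ratio)
}
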