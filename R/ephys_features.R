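#' Centered-difference voltage derivative
#'
#' dV/dt in mV/ms (numerically equal to V/s) from the raw samples; the two
#' edge samples reuse one-sided differences. An optional Savitzky-Golay
#' style smoothing (quadratic, odd window) can be applied first.
#'
#' @param trace a [voltage_trace()]
#' @param smooth_window odd window length for polynomial smoothing;
#'   0 (default) leaves the raw samples untouched
#' @return numeric vector, one value per sample
#' @export
dvdt <- function(trace, smooth_window = 0) {
  v <- trace$samples
  if (smooth_window > 0) {
    stopifnot(smooth_window %% 2 == 1, smooth_window >= 5)
    half <- (smooth_window - 1) / 2
    x <- -half:half
    # quadratic least-squares smoother coefficients
    X <- cbind(1, x, x^2)
    w <- (X %*% solve(crossprod(X), c(1, 0, 0)))[, 1]
    v <- as.numeric(stats::filter(v, rev(w), sides = 2))
    v[seq_len(half)] <- trace$samples[seq_len(half)]
    v[(length(v) - half + 1):length(v)] <-
      trace$samples[(length(v) - half + 1):length(v)]
  }
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * trace$dt)
  d[1] <- (v[2] - v[1]) / trace$dt
  d[n] <- (v[n] - v[n - 1]) / trace$dt
  d
}

#' Detect action potentials in a voltage trace
#'
#' A spike is a local maximum exceeding `min_peak` that is preceded by a
#' depolarization-rate crossing of `dvdt_threshold`. The spike threshold
#' index is the first sample at which the centered-difference dV/dt reaches
#' `dvdt_threshold` during the rise to that peak. Secondary local maxima
#' between a threshold crossing and repolarization below threshold voltage
#' are merged into one event (the largest peak wins).
#'
#' @param trace a [voltage_trace()]
#' @param dvdt_threshold depolarization-rate criterion (V/s)
#' @param min_peak minimum peak voltage (mV)
#' @return data.frame with columns `threshold_index`, `peak_index`,
#'   `threshold_mv`, `peak_mv` (one row per spike, ordered in time)
#' @export
detect_spikes <- function(trace, dvdt_threshold = 10, min_peak = 0) {
  stopifnot(inherits(trace, "voltage_trace"), dvdt_threshold > 0)
  v <- trace$samples
  if (length(v) < 3) stop("trace too short for spike detection")
  d <- dvdt(trace)
  n <- length(v)
  peaks <- which(v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]) + 1
  peaks <- peaks[v[peaks] >= min_peak]
  if (!length(peaks)) {
    return(data.frame(threshold_index = integer(), peak_index = integer(),
                      threshold_mv = numeric(), peak_mv = numeric()))
  }
  crossings <- which(d[-1] >= dvdt_threshold & d[-n] < dvdt_threshold) + 1
  thr_idx <- integer(0); pk_idx <- integer(0)
  last_thr <- -1L
  for (p in peaks) {
    cr <- crossings[crossings <= p]
    if (!length(cr)) next
    thr <- cr[length(cr)]
    # merge: if this peak shares the threshold crossing with the previous
    # event keep whichever peak is taller
    if (length(thr_idx) && thr == last_thr) {
      if (v[p] > v[pk_idx[length(pk_idx)]]) pk_idx[length(pk_idx)] <- p
      next
    }
    thr_idx <- c(thr_idx, thr); pk_idx <- c(pk_idx, p)
    last_thr <- thr
  }
  data.frame(threshold_index = thr_idx, peak_index = pk_idx,
             threshold_mv = v[thr_idx], peak_mv = v[pk_idx])
}

interp_crossing <- function(t1, t2, v1, v2, level) {
  t1 + (level - v1) / (v2 - v1) * (t2 - t1)
}

#' Extract waveform features of one action potential
#'
#' Half-width is measured between the two linearly interpolated crossings of
#' the voltage halfway between threshold and peak; the maximum
#' depolarization and repolarization rates are the extrema of the
#' centered-difference dV/dt over the spike (threshold to AHP); the AHP is
#' the voltage minimum in a post-peak window ending at the next spike
#' threshold or `ahp_window` ms after the peak, whichever comes first.
#' Amplitude is measured from the configured reference: spike threshold
#' (default, matching peak-minus-threshold arithmetic) or the AHP trough.
#'
#' @param trace a [voltage_trace()]
#' @param spike one row of the [detect_spikes()] table (or a list with
#'   `threshold_index` and `peak_index`)
#' @param next_threshold_index threshold index of the following spike, if
#'   any (bounds the AHP search)
#' @param ahp_window maximum AHP search window after the peak (ms)
#' @param amplitude_reference `"threshold"` or `"ahp"`
#' @return data.frame with one row: `threshold`, `peak`, `peak_time`,
#'   `amplitude`, `amplitude_from_ahp`, `half_width`, `ahp`,
#'   `max_depol_rate`, `max_repol_rate` (both rates positive, V/s)
#' @export
extract_ap_features <- function(trace, spike, next_threshold_index = NA,
                                ahp_window = 50,
                                amplitude_reference = c("threshold", "ahp")) {
  amplitude_reference <- match.arg(amplitude_reference)
  v <- trace$samples; dt <- trace$dt; n <- length(v)
  it <- spike$threshold_index; ip <- spike$peak_index
  stopifnot(it >= 1, ip <= n, it < ip)
  thr <- v[it]; peak <- v[ip]
  v_half <- thr + (peak - thr) / 2

  # rising crossing of v_half between threshold and peak
  ir <- it + which(v[(it + 1):ip] >= v_half)[1]
  t_rise <- interp_crossing((ir - 2) * dt, (ir - 1) * dt, v[ir - 1], v[ir],
                            v_half)
  # falling crossing after the peak
  after <- v[(ip + 1):n]
  jf <- which(after <= v_half)[1]
  if (is.na(jf)) stop("waveform never recrosses the half-height level ",
                      "(truncated spike)")
  jf <- ip + jf
  t_fall <- interp_crossing((jf - 2) * dt, (jf - 1) * dt, v[jf - 1], v[jf],
                            v_half)
  half_width <- t_fall - t_rise

  ahp_end <- min(ip + round(ahp_window / dt),
                 if (is.na(next_threshold_index)) n else next_threshold_index,
                 n)
  ahp <- min(v[ip:ahp_end])
  i_ahp <- ip - 1 + which.min(v[ip:ahp_end])

  d <- dvdt(trace)
  max_depol <- max(d[it:ip])
  max_repol <- -min(d[ip:ahp_end])

  amplitude <- peak - thr
  amplitude_from_ahp <- peak - ahp
  data.frame(threshold = thr, peak = peak, peak_time = (ip - 1) * dt,
             amplitude = if (amplitude_reference == "threshold") amplitude
                         else amplitude_from_ahp,
             amplitude_from_ahp = amplitude_from_ahp,
             half_width = half_width, ahp = ahp,
             ahp_time = (i_ahp - 1) * dt,
             max_depol_rate = max_depol, max_repol_rate = max_repol)
}

#' Per-spike feature table for a whole trace
#'
#' Runs [detect_spikes()] then [extract_ap_features()] on every spike whose
#' full waveform (threshold to AHP window) lies inside the trace.
#'
#' @inheritParams detect_spikes
#' @inheritParams extract_ap_features
#' @param discard_ms initial transient to skip (ms)
#' @return data.frame of per-spike features plus `spont_rate_hz`, the spike
#'   count over the analysed duration, as an attribute
#' @export
trace_ap_features <- function(trace, dvdt_threshold = 10, min_peak = 0,
                              ahp_window = 50,
                              amplitude_reference = "threshold",
                              discard_ms = 0) {
  spikes <- detect_spikes(trace, dvdt_threshold, min_peak)
  keep <- spikes$peak_index * trace$dt >= discard_ms
  spikes <- spikes[keep, , drop = FALSE]
  n <- length(trace$samples)
  rows <- list()
  for (i in seq_len(nrow(spikes))) {
    nxt <- if (i < nrow(spikes)) spikes$threshold_index[i + 1] else NA
    end_needed <- min(spikes$peak_index[i] + round(5 / trace$dt), n)
    if (spikes$peak_index[i] + 2 >= n) next
    ft <- tryCatch(
      extract_ap_features(trace, spikes[i, ], next_threshold_index = nxt,
                          ahp_window = ahp_window,
                          amplitude_reference = amplitude_reference),
      error = function(e) NULL)
    if (!is.null(ft)) rows[[length(rows) + 1]] <- ft
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- extract_ap_features(
    voltage_trace(c(0, 1, 0), 1), list(threshold_index = 1, peak_index = 2)
  )[0, ]
  dur_s <- (n * trace$dt - discard_ms) / 1000
  attr(out, "spont_rate_hz") <- nrow(spikes) / dur_s
  out
}

#' Average spike-aligned waveforms
#'
#' Aligns spikes on their peak sample and averages pointwise; spikes whose
#' window would fall outside the trace are dropped.
#'
#' @param trace a [voltage_trace()]
#' @param spikes a [detect_spikes()] table
#' @param window half-window on each side of the peak (ms)
#' @return a [voltage_trace()] of length `2 * window/dt + 1`
#' @export
average_aps <- function(trace, spikes, window = 5) {
  if (nrow(spikes) == 0) stop("no spikes to average")
  k <- round(window / trace$dt)
  n <- length(trace$samples)
  ok <- spikes$peak_index - k >= 1 & spikes$peak_index + k <= n
  if (!any(ok)) stop("no spike has a complete window inside the trace")
  mats <- vapply(spikes$peak_index[ok],
                 function(ip) trace$samples[(ip - k):(ip + k)],
                 numeric(2 * k + 1))
  voltage_trace(rowMeans(mats), trace$dt, stimulus = 0,
                temperature = trace$temperature,
                meta = c(trace$meta, list(n_averaged = sum(ok))))
}

#' Firing-rate analysis over a family of current steps (F-I curve)
#'
#' For each sweep: the rate is the spike count within the step divided by
#' the step duration; the instantaneous frequency is the reciprocal of the
#' first interspike interval and the steady-state frequency the reciprocal
#' of the last. Sweeps with fewer than two spikes get `NA` frequencies
#' (undefined, not zero).
#'
#' @param traces list of [voltage_trace()] objects, each with `step_pA`,
#'   `step_onset` and `step_duration` in its `meta`
#' @param dvdt_threshold,min_peak passed to [detect_spikes()]
#' @return data.frame with columns `current_pa`, `rate_hz`,
#'   `instantaneous_hz`, `steady_state_hz`, `n_spikes`
#' @export
fi_analysis <- function(traces, dvdt_threshold = 10, min_peak = 0) {
  amps <- vapply(traces, function(tr) tr$meta$step_pA, numeric(1))
  if (anyDuplicated(amps))
    stop("duplicate step amplitudes: tag sweeps unambiguously")
  rows <- lapply(traces, function(tr) {
    onset <- tr$meta$step_onset; dur <- tr$meta$step_duration
    spikes <- detect_spikes(tr, dvdt_threshold, min_peak)
    t_peak <- (spikes$peak_index - 1) * tr$dt
    inside <- t_peak >= onset & t_peak < onset + dur
    tp <- t_peak[inside]
    inst <- if (length(tp) >= 2) 1000 / (tp[2] - tp[1]) else NA_real_
    ss <- if (length(tp) >= 2)
      1000 / (tp[length(tp)] - tp[length(tp) - 1]) else NA_real_
    data.frame(current_pa = tr$meta$step_pA,
               rate_hz = length(tp) / (dur / 1000),
               instantaneous_hz = inst, steady_state_hz = ss,
               n_spikes = length(tp))
  })
  out <- do.call(rbind, rows)
  out[order(out$current_pa), , drop = FALSE]
}

#' Fold change and percent change between paired measurements
#'
#' @param pre_value,post_value scalars (pre must be nonzero)
#' @return `post/pre` (`fold_change`) or `100 * (post - pre)/pre`
#'   (`percent_change`)
#' @export
fold_change <- function(pre_value, post_value) {
  if (any(pre_value == 0)) stop("pre_value must be nonzero")
  post_value / pre_value
}

#' @rdname fold_change
#' @export
percent_change <- function(pre_value, post_value) {
  100 * (post_value - pre_value) / pre_value
}
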