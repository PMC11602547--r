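#' Detector parameters for spontaneous inward currents
#'
#' @param low_pass_Hz low-pass filter cutoff (2nd-order Butterworth,
#'   zero-phase), Hz.
#' @param baseline_window_s rolling-median baseline window, s.
#' @param k threshold in robust (MAD-scaled) noise SDs below baseline.
#' @param min_duration_s minimum duration at half amplitude for the SLIC
#'   class; shorter events are classed synaptic-like.
#' @param merge_gap_s sub-threshold gaps shorter than this are merged.
#' @export
detector_params <- function(low_pass_Hz = 20, baseline_window_s = 10,
                            k = 4, min_duration_s = 0.2,
                            merge_gap_s = 0.2) {
  stopifnot(low_pass_Hz > 0, baseline_window_s > 0, k > 0,
            min_duration_s > 0, merge_gap_s > 0)
  structure(list(low_pass_Hz = low_pass_Hz,
                 baseline_window_s = baseline_window_s, k = k,
                 min_duration_s = min_duration_s,
                 merge_gap_s = merge_gap_s),
            class = "detector_params")
}

#' Detect spontaneous inward currents in a holding-current trace
#'
#' Low-pass filters the trace, estimates a slow baseline by rolling
#' median, scales the residual noise by its MAD, and marks contiguous
#' stretches more than `k` robust SDs below baseline as events (gaps
#' shorter than the merge gap are bridged).  Events lasting at least
#' `min_duration_s` at half amplitude are classed `"SLIC"`, shorter ones
#' `"synaptic"`.  Amplitudes are baseline-to-peak, reported positive,
#' from the filtered trace (primary) and the raw trace.  Onsets are
#' back-projected from the threshold crossing to the last sample within
#' 10% of the peak deflection, so they do not lag the threshold.
#'
#' @param trace holding-current trace, pA (inward negative).
#' @param fs sampling rate, Hz.
#' @param params a [detector_params()] object.
#' @return An `event_series` data frame: `onset`, `peak_time` (s),
#'   `amplitude` (pA, filtered), `amplitude_raw` (pA), `halfwidth` (s),
#'   `class`; attributes `duration_s`, `noise_sd`, `n_slic`.
#' @export
detect_events <- function(trace, fs, params = detector_params()) {
  if (!all(is.finite(trace))) stop("trace contains non-finite samples")
  n <- length(trace)
  stopifnot(n > params$baseline_window_s * fs / 2)
  bf <- signal::butter(2, min(params$low_pass_Hz / (fs / 2), 0.99),
                       type = "low")
  filt <- as.numeric(signal::filtfilt(bf, trace))
  k_med <- min(n, round(params$baseline_window_s * fs))
  if (k_med %% 2 == 0) k_med <- k_med - 1
  baseline <- stats::runmed(filt, k_med, endrule = "median")
  resid <- filt - baseline
  noise_sd <- mad(resid)
  thr <- -params$k * max(noise_sd, .Machine$double.eps)
  below <- resid < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # bridge sub-threshold gaps shorter than merge_gap
  if (nrow(runs) > 1) {
    gap <- (runs$start[-1] - runs$end[-nrow(runs)]) / fs
    keep <- gap >= params$merge_gap_s
    grp <- cumsum(c(TRUE, keep))
    runs <- data.frame(start = tapply(runs$start, grp, min),
                       end = tapply(runs$end, grp, max))
  }
  ev <- lapply(seq_len(nrow(runs)), function(i) {
    s <- runs$start[i]; e <- runs$end[i]
    seg <- resid[s:e]
    pk <- s + which.min(seg) - 1
    amp <- -resid[pk]
    # half-amplitude duration around the peak
    half <- resid < -amp / 2
    hs <- pk; while (hs > 1 && half[hs - 1]) hs <- hs - 1
    he <- pk; while (he < n && half[he + 1]) he <- he + 1
    # onset: walk back from the peak to the last sample within 10% of it
    on <- pk
    while (on > 1 && resid[on - 1] < -0.1 * amp) on <- on - 1
    raw_amp <- baseline[pk] - min(trace[max(1, hs):min(n, he)])
    data.frame(onset = on / fs, peak_time = pk / fs, amplitude = amp,
               amplitude_raw = raw_amp, halfwidth = (he - hs + 1) / fs)
  })
  ev <- if (length(ev)) do.call(rbind, ev) else
    data.frame(onset = numeric(0), peak_time = numeric(0),
               amplitude = numeric(0), amplitude_raw = numeric(0),
               halfwidth = numeric(0))
  ev$class <- ifelse(ev$halfwidth >= params$min_duration_s,
                     "SLIC", "synaptic")
  structure(ev, duration_s = n / fs, noise_sd = noise_sd,
            n_slic = sum(ev$class == "SLIC"),
            class = c("event_series", "data.frame"))
}

#' Nernst-predicted current deflection for a K+ transient
#'
#' The current evoked at fixed holding potential by a change of
#' extracellular K+ from `k_e` to `k_e_new`:
#' `dI = (1/Rm) (RT/F) ln(k_e_new / k_e)`, i.e. the shift of the K+
#' equilibrium potential divided by the membrane resistance.  The
#' holding potential cancels.  Positive for a K+ rise (growing inward
#' current magnitude).
#'
#' @param rm membrane resistance, MOhm.
#' @param k_e,k_e_new resting and evoked extracellular K+, mM.
#' @param temperature_K temperature, K.
#' @return Deflection amplitude in pA.
#' @examples
#' predicted_delta_I(100, 2.5, 5)    # approx 176 pA
#' predicted_delta_I(400, 2.5, 3.0)  # approx 11.6 pA
#' @export
predicted_delta_I <- function(rm, k_e, k_e_new, temperature_K = 295) {
  if (any(k_e <= 0) || any(k_e_new <= 0))
    stop("K+ concentrations must be strictly positive")
  stopifnot(all(rm > 0))
  1000 * rt_over_f_mV(temperature_K) * log(k_e_new / k_e) / rm
}

#' Regress SLIC amplitude on membrane and K+ covariates
#'
#' Ordinary least-squares regressions of event amplitude on the evoked
#' peak \[K+\]e (event level) and of per-cell mean amplitude on membrane
#' resistance and inward conductance (cell level), mirroring the
#' observation that SLIC amplitude tracks the cell's passive properties
#' rather than the size of the K+ transient.
#'
#' @param events data frame with columns `cell_id`, `amplitude` (pA)
#'   and `k_peak` (mM, evoked \[K+\]e paired with each event).
#' @param cells data frame with columns `cell_id`, `rm` (MOhm) and
#'   optionally `g_in` (nS).
#' @return Data frame, one row per regression: `response`, `predictor`,
#'   `slope`, `r_squared`, `p_value`, `n`, `direction`.
#' @export
amplitude_regressions <- function(events, cells) {
  stopifnot(all(c("cell_id", "amplitude", "k_peak") %in% names(events)),
            all(c("cell_id", "rm") %in% names(cells)))
  if (nrow(cells) < 3) stop("need at least 3 cells")
  row_for <- function(fit, response, predictor) {
    s <- summary(fit)
    if (nrow(s$coefficients) < 2 || !is.finite(s$coefficients[2, 1]))
      stop("degenerate covariate (zero variance): ", predictor)
    sl <- s$coefficients[2, 1]
    data.frame(response = response, predictor = predictor, slope = sl,
               r_squared = s$r.squared,
               p_value = s$coefficients[2, 4],
               n = length(fit$residuals),
               direction = ifelse(sl > 0, "positive", "negative"),
               stringsAsFactors = FALSE)
  }
  per_cell <- aggregate(amplitude ~ cell_id, events, mean)
  per_cell <- merge(per_cell, cells, by = "cell_id")
  out <- list(row_for(lm(amplitude ~ k_peak, events),
                      "event amplitude", "k_peak"),
              row_for(lm(amplitude ~ rm, per_cell),
                      "mean cell amplitude", "rm"))
  if ("g_in" %in% names(cells))
    out <- c(out, list(row_for(lm(amplitude ~ g_in, per_cell),
                               "mean cell amplitude", "g_in")))
  do.call(rbind, out)
}

#' Pair OPC events with preceding partner events
#'
#' Nearest-neighbour matching of each OPC event peak to the closest
#' partner (field-potential or neuronal) event within `max_lag_s`;
#' latency is OPC peak minus partner peak (positive when the partner
#' precedes).
#'
#' @param opc_times,partner_times sorted event-peak times, s.
#' @param max_lag_s maximum |latency| for a match, s.
#' @return List with `latencies` (s, one per matched OPC event),
#'   `matched`, `unmatched_opc`, `unmatched_partner`.
#' @export
pair_event_latencies <- function(opc_times, partner_times,
                                 max_lag_s = 0.5) {
  if (length(partner_times) == 0)
    return(list(latencies = numeric(0), matched = 0L,
                unmatched_opc = length(opc_times),
                unmatched_partner = 0L))
  lat <- vapply(opc_times, function(t0) {
    d <- t0 - partner_times
    d[which.min(abs(d))]
  }, numeric(1))
  ok <- abs(lat) <= max_lag_s
  used <- unique(vapply(opc_times[ok], function(t0)
    which.min(abs(t0 - partner_times)), integer(1)))
  list(latencies = lat[ok], matched = sum(ok),
       unmatched_opc = sum(!ok),
       unmatched_partner = length(partner_times) - length(used))
}

#' Percentage of events blocked between two epochs
#'
#' `100 (1 - post-rate / pre-rate)` with rates over the full epoch
#' durations; the raw (unclipped) value is kept as an attribute.
#'
#' @param pre_events,post_events event counts, `event_series` objects or
#'   event-time vectors for the two epochs.
#' @param pre_duration_s,post_duration_s epoch durations, s.
#' @return Percent blocked, clipped to \[0, 100\]; `NA` with attribute
#'   `qc_fail` if the pre-epoch rate is zero.
#' @export
percent_block <- function(pre_events, post_events, pre_duration_s,
                          post_duration_s) {
  stopifnot(pre_duration_s > 0, post_duration_s > 0)
  count <- function(x) if (is.data.frame(x)) nrow(x) else
    if (length(x) == 1 && is.numeric(x)) x else length(x)
  r_pre <- count(pre_events) / pre_duration_s
  r_post <- count(post_events) / post_duration_s
  if (r_pre == 0)
    return(structure(NA_real_, qc_fail = "no events in pre epoch"))
  raw <- 100 * (1 - r_post / r_pre)
  structure(min(100, max(0, raw)), raw = raw)
}

#' Percent block of the inward conductance between two I/V curves
#'
#' @param iv_pre,iv_post `iv_curve` objects at matching potentials.
#' @param e_k K+ equilibrium potential, mV.
#' @param v_min lower end of the slope window, mV.
#' @return `100 (1 - g_in(post) / g_in(pre))`.
#' @export
block_of_inward_current <- function(iv_pre, iv_post, e_k,
                                    v_min = min(iv_pre$v)) {
  if (!isTRUE(all.equal(iv_pre$v, iv_post$v)))
    stop("I/V curves must share potentials")
  g_pre <- inward_conductance(iv_pre, e_k, v_min)
  if (g_pre <= 0) stop("pre-block inward conductance is not positive")
  g_post <- inward_conductance(iv_post, e_k, v_min)
  100 * (1 - as.numeric(g_post) / as.numeric(g_pre))
}
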