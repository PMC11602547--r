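#' Activity scenario for a simulated co-recording session
#'
#' Describes the extracellular K+ transients produced by synchronized
#' neuronal activity, the accompanying field-potential (FP) deflections,
#' and fast synaptic-like currents.  The `"cortical"` pattern uses fast
#' transients (50 ms rise / 500 ms decay), `"hippocampal"` sustained ones
#' (500 ms rise / 5 s decay); transient peak amplitudes span the
#' 0.14-1.32 mM range that evokes detectable SLICs.  FP deflections
#' precede the K+-driven OPC currents by the latency offset (neuronal
#' firing causes the K+ rise).
#'
#' @param pattern `"cortical"` or `"hippocampal"`.
#' @param baseline_k baseline \[K+\]e, mM (aCSF: 2.5).
#' @param rate SLIC-generating event rate, Hz (default 0.09); used when
#'   `event_times_s` is `NULL`.
#' @param dk_range range of per-event peak delta \[K+\]e, mM.
#' @param event_times_s optional explicit K+ transient onset times, s;
#'   `NULL` draws a Poisson train at `rate`.
#' @param dk_mM optional explicit per-event peak delta \[K+\]e, mM
#'   (recycled to the number of events); `NULL` draws uniformly from
#'   `dk_range`.
#' @param rise_s,decay_s K+ transient kinetics, s (pattern defaults).
#' @param syn_rate,syn_amp_pA,syn_rise_s,syn_decay_s fast synaptic-like
#'   event rate (Hz), mean amplitude (pA, inward) and kinetics (s).
#' @param fp_amp_mV FP deflection amplitude, mV (negative).
#' @param fp_width_s FP deflection Gaussian SD, s.
#' @param latency_s OPC-event latency after the FP peak, s (> 0).
#' @return An `activity_scenario`.
#' @export
activity_scenario <- function(pattern = c("cortical", "hippocampal"),
                              baseline_k = 2.5, rate = 0.09,
                              dk_range = c(0.14, 1.32),
                              event_times_s = NULL, dk_mM = NULL,
                              rise_s = NULL, decay_s = NULL,
                              syn_rate = 0.2, syn_amp_pA = 15,
                              syn_rise_s = 0.001, syn_decay_s = 0.008,
                              fp_amp_mV = -0.4, fp_width_s = 0.03,
                              latency_s = 0.02) {
  pattern <- match.arg(pattern)
  if (is.null(rise_s)) rise_s <- if (pattern == "cortical") 0.05 else 0.5
  if (is.null(decay_s)) decay_s <- if (pattern == "cortical") 0.5 else 5
  stopifnot(baseline_k > 0, all(dk_range >= 0), latency_s > 0,
            rise_s > 0, decay_s > rise_s, rate >= 0)
  structure(list(pattern = pattern, baseline_k = baseline_k, rate = rate,
                 dk_range = dk_range, event_times_s = event_times_s,
                 dk_mM = dk_mM, rise_s = rise_s, decay_s = decay_s,
                 syn_rate = syn_rate, syn_amp_pA = syn_amp_pA,
                 syn_rise_s = syn_rise_s, syn_decay_s = syn_decay_s,
                 fp_amp_mV = fp_amp_mV, fp_width_s = fp_width_s,
                 latency_s = latency_s),
            class = "activity_scenario")
}

# Difference-of-exponentials waveform normalized to unit peak, and the
# time (s) of that peak.
doe_shape <- function(t, rise, decay) {
  tp <- rise * decay / (decay - rise) * log(decay / rise)
  peak <- exp(-tp / decay) - exp(-tp / rise)
  out <- (exp(-pmax(t, 0) / decay) - exp(-pmax(t, 0) / rise)) / peak
  out[t < 0] <- 0
  out
}
doe_peak_time <- function(rise, decay) {
  rise * decay / (decay - rise) * log(decay / rise)
}

#' Simulate a SLIC co-recording session
#'
#' Generates the three aligned channels of a voltage-clamp / field
#' potential / K+-ISM co-recording: extracellular K+ transients move the
#' K+ equilibrium potential according to the Nernst equation, the
#' resulting holding-current deflections (SLICs) are obtained by
#' integrating the full membrane model at the clamp potential, fast
#' synaptic-like currents and Gaussian noise are superimposed, FP
#' deflections precede the K+ events by the configured latency, and the
#' ISM channel is the calibration-forward transform of \[K+\]e(t) plus
#' the FP signal as common mode (so reference subtraction is required
#' downstream).
#'
#' @param params a [membrane_params()] object (the recorded cell); the
#'   default emulates a high-conductance OPC (input resistance approx
#'   150 MOhm).
#' @param scenario an [activity_scenario()].
#' @param duration_s session length, s.
#' @param fs sampling rate, Hz (all three channels share it).
#' @param v_hold clamp potential, mV.
#' @param noise_rms current-channel noise RMS, pA.
#' @param fp_noise_mV,ism_noise_mV voltage-channel noise SD, mV.
#' @param cal_slope,cal_intercept forward ISM calibration (mV/decade, mV).
#' @param k_in pipette K+, mM.
#' @param temperature_K temperature, K.
#' @param seed integer seed.
#' @return A `slic_session`: data frame `time` (s), `current` (pA), `fp`
#'   (mV), `ism` (mV) with attributes `truth` (event times, peak times,
#'   delta-K, predicted amplitudes, FP peak times, \[K+\]e series),
#'   `fs`, `cal`, `scenario`, `params`, `v_hold`.
#' @export
simulate_slic_session <- function(params = membrane_params(g_kir = 6.1,
                                                           cm = 42),
                                  scenario = activity_scenario(),
                                  duration_s = 120, fs = 2000,
                                  v_hold = -74, noise_rms = 2,
                                  fp_noise_mV = 0.02, ism_noise_mV = 0,
                                  cal_slope = theoretical_nernst_slope(295),
                                  cal_intercept = 0,
                                  k_in = 132, temperature_K = 295,
                                  seed = NULL) {
  stopifnot(duration_s > 0, fs > 0, noise_rms >= 0)
  with_seed(seed, {
    n <- round(duration_s * fs)
    t <- seq_len(n) / fs
    if (is.null(scenario$event_times_s)) {
      n_ev <- rpois(1, scenario$rate * duration_s)
      # keep events away from the edges so peaks fall inside the record
      t_ev <- sort(runif(n_ev, 2, max(2, duration_s - 4 * scenario$decay_s)))
    } else {
      t_ev <- sort(scenario$event_times_s)
      n_ev <- length(t_ev)
    }
    dk <- if (is.null(scenario$dk_mM))
      runif(n_ev, scenario$dk_range[1], scenario$dk_range[2])
    else rep_len(scenario$dk_mM, n_ev)
    k_t <- rep(scenario$baseline_k, n)
    for (j in seq_len(n_ev))
      k_t <- k_t + dk[j] * doe_shape(t - t_ev[j], scenario$rise_s,
                                     scenario$decay_s)
    if (any(k_t <= 0)) stop("[K+]e must stay positive")
    e_k_t <- nernst_potential(k_t, k_in, temperature_K)
    dt_ms <- 1000 / fs
    v0 <- clamp_steady_state(v_hold, params,
                             e_k = nernst_potential(scenario$baseline_k,
                                                    k_in, temperature_K))
    out <- integrate_clamp(rep(v_hold, n), e_k_t, dt_ms, v0,
                           params$cm, 1000 / params$rs,
                           params$g_leak, params$e_leak,
                           params$g_kir, params$v_half_kir, params$k_kir,
                           params$g_out, params$v_half_out, params$k_out)
    current <- out$current
    # fast synaptic-like inward currents (phenomenological)
    n_syn <- rpois(1, scenario$syn_rate * duration_s)
    t_syn <- sort(runif(n_syn, 0.5, duration_s - 0.5))
    for (j in seq_len(n_syn)) {
      amp <- scenario$syn_amp_pA * exp(rnorm(1, 0, 0.3))
      win <- which(t >= t_syn[j] & t <= t_syn[j] + 8 * scenario$syn_decay_s)
      current[win] <- current[win] -
        amp * doe_shape(t[win] - t_syn[j], scenario$syn_rise_s,
                        scenario$syn_decay_s)
    }
    if (noise_rms > 0) current <- current + rnorm(n, 0, noise_rms)
    # FP: deflections peaking latency_s before each K+-event peak
    tp <- doe_peak_time(scenario$rise_s, scenario$decay_s)
    t_peak <- t_ev + tp
    fp_peak <- t_peak - scenario$latency_s
    fp <- rep(0, n)
    for (j in seq_len(n_ev))
      fp <- fp + scenario$fp_amp_mV *
        exp(-0.5 * ((t - fp_peak[j]) / scenario$fp_width_s)^2)
    if (fp_noise_mV > 0) fp <- fp + rnorm(n, 0, fp_noise_mV)
    ism <- cal_slope * log10(k_t) + cal_intercept + fp
    if (ism_noise_mV > 0) ism <- ism + rnorm(n, 0, ism_noise_mV)
    rm_eff <- 1000 / (params$g_leak + params$g_kir *
                        f_kir(v_hold, params) +
                        params$g_out * f_out(v_hold, params))
    truth <- list(
      event_times = t_ev, peak_times = t_peak, dk = dk,
      k_peak = scenario$baseline_k + dk,
      fp_peak_times = fp_peak,
      predicted_amp = predicted_delta_I(rm_eff, scenario$baseline_k,
                                        scenario$baseline_k + dk,
                                        temperature_K = temperature_K),
      syn_times = t_syn, k_series = k_t, rm_eff = rm_eff)
    structure(data.frame(time = t, current = current, fp = fp, ism = ism),
              truth = truth, fs = fs,
              cal = list(slope = cal_slope, intercept = cal_intercept),
              scenario = scenario, params = params, v_hold = v_hold,
              class = c("slic_session", "data.frame"))
  })
}

#' Simulate a per-cell SLIC amplitude cohort for regression analysis
#'
#' Generates the data structure behind amplitude-vs-covariate
#' regressions: one recorded cell per session with membrane resistance
#' spanning the physiological range, each contributing SLIC amplitudes
#' given by the Nernst deflection of its local K+ transient, paired
#' with the delta-\[K+\]e measured by an ion-selective microelectrode
#' placed 30-180 um away.  Because transient amplitudes decorrelate
#' over that distance, the measured delta-K is only loosely coupled to
#' the transient at the cell; `spatial_coherence` sets that coupling
#' (0 = independent, the default, reproducing the observed absence of
#' amplitude-\[K+\]e correlation; 1 = identical).
#'
#' @param n_cells number of recorded cells (sessions).
#' @param events_per_cell SLIC count per cell.
#' @param rm_range membrane-resistance range, MOhm (log-uniform draw).
#' @param dk_range peak delta-\[K+\]e range, mM.
#' @param baseline_k baseline \[K+\]e, mM.
#' @param spatial_coherence coupling in \[0, 1\] between the cell-local
#'   and ISM-measured transient amplitudes.
#' @param lognoise_sd lognormal amplitude variability (biological).
#' @param noise_pA additive measurement noise on amplitudes, pA.
#' @param temperature_K temperature, K.
#' @param seed integer seed.
#' @return List with `events` (cell_id, amplitude, k_peak) and `cells`
#'   (cell_id, rm, g_in), ready for [amplitude_regressions()].
#' @export
simulate_regression_cohort <- function(n_cells = 15, events_per_cell = 3,
                                       rm_range = c(50, 1000),
                                       dk_range = c(0.14, 1.32),
                                       baseline_k = 2.5,
                                       spatial_coherence = 0,
                                       lognoise_sd = 0.15, noise_pA = 3,
                                       temperature_K = 295, seed = NULL) {
  stopifnot(n_cells >= 3, events_per_cell >= 1,
            spatial_coherence >= 0, spatial_coherence <= 1)
  with_seed(seed, {
    rm <- exp(runif(n_cells, log(rm_range[1]), log(rm_range[2])))
    events <- do.call(rbind, lapply(seq_len(n_cells), function(i) {
      dk_local <- runif(events_per_cell, dk_range[1], dk_range[2])
      dk_ism <- spatial_coherence * dk_local +
        (1 - spatial_coherence) * runif(events_per_cell, dk_range[1],
                                        dk_range[2])
      amp <- predicted_delta_I(rm[i], baseline_k, baseline_k + dk_local,
                               temperature_K) *
        exp(rnorm(events_per_cell, 0, lognoise_sd)) +
        rnorm(events_per_cell, 0, noise_pA)
      data.frame(cell_id = sprintf("cell_%02d", i),
                 amplitude = pmax(amp, 1), k_peak = baseline_k + dk_ism,
                 dk_local = dk_local, stringsAsFactors = FALSE)
    }))
    cells <- data.frame(cell_id = sprintf("cell_%02d", seq_len(n_cells)),
                        rm = rm, g_in = 1000 / rm,
                        stringsAsFactors = FALSE)
    list(events = events, cells = cells)
  })
}
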