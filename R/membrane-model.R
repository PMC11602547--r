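#' Single-compartment membrane model parameters
#'
#' Defines the biophysical stand-in used by all simulators: an RC cell
#' (access resistance `Rs`, capacitance `Cm`, ohmic leak) carrying an
#' inward-rectifier K+ conductance and, optionally, an outward
#' delayed-rectifier conductance.  The Kir gate is a falling Boltzmann of
#' the driving potential `V - E_K`,
#' `f_kir(V) = 1 / (1 + exp((V - E_K - v_half_kir) / k_kir))`,
#' so hyperpolarization opens it.  The default gate (`v_half_kir = 250`,
#' `k_kir = 50`) is open (> 0.99) across the whole step protocol, which
#' reproduces the near-ohmic ("passive") K+ current phenotype of cells
#' dominated by Kir4.1/Kir2.1; steep rectification is obtained with a
#' smaller half-activation offset and slope (e.g. `v_half_kir = 15`,
#' `k_kir = 8`).  With `g_kir = g_out = 0` the model reduces to a
#' single-exponential RC cell.
#'
#' @param rs access (series) resistance, MOhm.
#' @param cm membrane capacitance, pF.
#' @param g_leak ohmic leak conductance, nS.
#' @param e_leak leak reversal potential, mV.
#' @param g_kir inward-rectifier K+ conductance, nS.
#' @param v_half_kir Kir half-activation relative to `E_K`, mV.
#' @param k_kir Kir Boltzmann slope, mV (> 0; large + large `v_half_kir`
#'   gives a near-ohmic K+ conductance).
#' @param g_out outward delayed-rectifier conductance, nS.
#' @param v_half_out,k_out rising-Boltzmann parameters of the outward
#'   conductance (absolute mV).
#' @param e_k K+ equilibrium potential, mV; by default computed from 2.5
#'   mM bath / 132 mM pipette K+ at 295 K via [nernst_potential()].
#' @return An object of class `membrane_params`.
#' @export
membrane_params <- function(rs = 32, cm = 30, g_leak = 0.5, e_leak = -40,
                            g_kir = 4, v_half_kir = 250, k_kir = 50,
                            g_out = 0, v_half_out = -20, k_out = 12,
                            e_k = nernst_potential(2.5, 132, 295)) {
  stopifnot(rs > 0, cm > 0, g_leak >= 0, g_kir >= 0, g_out >= 0,
            k_kir > 0, k_out > 0)
  structure(list(rs = rs, cm = cm, g_leak = g_leak, e_leak = e_leak,
                 g_kir = g_kir, v_half_kir = v_half_kir, k_kir = k_kir,
                 g_out = g_out, v_half_out = v_half_out, k_out = k_out,
                 e_k = e_k),
            class = "membrane_params")
}

#' @export
print.membrane_params <- function(x, ...) {
  cat("Membrane model: Rs", x$rs, "MOhm, Cm", x$cm, "pF, g_leak",
      x$g_leak, "nS (E_leak", x$e_leak, "mV), g_kir", x$g_kir,
      "nS, g_out", x$g_out, "nS, E_K", round(x$e_k, 1), "mV\n")
  invisible(x)
}

# Kir and outward gating factors.
f_kir <- function(v, p, e_k = p$e_k) 1 / (1 + exp((v - e_k - p$v_half_kir) / p$k_kir))
f_out <- function(v, p) 1 / (1 + exp(-(v - p$v_half_out) / p$k_out))

#' Steady-state membrane current of the model
#'
#' Total ionic current (pA, positive outward) at membrane potential `v`
#' (mV), excluding the access-resistance pathway.
#'
#' @param v membrane potential(s), mV.
#' @param params a [membrane_params()] object.
#' @param e_k optional K+ reversal override, mV.
#' @export
membrane_current <- function(v, params, e_k = params$e_k) {
  params$g_leak * (v - params$e_leak) +
    params$g_kir * f_kir(v, params, e_k) * (v - e_k) +
    params$g_out * f_out(v, params) * (v - e_k)
}

# Steady-state membrane potential under clamp at v_cmd: solves
# g_s (v_cmd - v) = I_m(v).  g_s in nS.
clamp_steady_state <- function(v_cmd, params, e_k = params$e_k) {
  g_s <- 1000 / params$rs
  f <- function(v) g_s * (v_cmd - v) - membrane_current(v, params, e_k)
  uniroot(f, interval = c(-400, 400), tol = 1e-10)$root
}

# Zero-current membrane potential (the model's resting potential).
model_resting_potential <- function(params, e_k = params$e_k) {
  uniroot(function(v) membrane_current(v, params, e_k),
          interval = c(-400, 400), tol = 1e-10)$root
}

#' Voltage-step protocol
#'
#' @param v_hold holding potential, mV.
#' @param t_start,t_end step start and end, ms from sweep start.
#' @param potentials step command potentials, mV, strictly increasing.
#'   Default: 20 mV steps from -134 to +26 mV.
#' @param duration sweep duration, ms.
#' @param fs sampling rate, Hz (default 50 kHz).
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(v_hold = -74, t_start = 50, t_end = 250,
                          potentials = seq(-134, 26, by = 20),
                          duration = 300, fs = 50000) {
  stopifnot(fs > 0, all(diff(potentials) > 0),
            t_start >= 0, t_end > t_start, duration >= t_end)
  structure(list(v_hold = v_hold, t_start = t_start, t_end = t_end,
                 potentials = potentials, duration = duration, fs = fs),
            class = "step_protocol")
}

# Sample times (s) of a sweep; sample i covers ((i-1)dt, i dt].
protocol_times <- function(protocol) {
  n <- round(protocol$duration * protocol$fs / 1000)
  seq_len(n) / protocol$fs
}

# Command waveform (mV) for one step potential.
command_waveform <- function(protocol, v_step) {
  n <- round(protocol$duration * protocol$fs / 1000)
  i_on <- floor(protocol$t_start * protocol$fs / 1000) + 1
  i_off <- floor(protocol$t_end * protocol$fs / 1000)
  v <- rep(protocol$v_hold, n)
  v[i_on:i_off] <- v_step
  v
}

#' Simulate a voltage-clamp sweep bundle
#'
#' Integrates the membrane model under the step protocol with
#' exponential-Euler updates at the sampling interval and returns the
#' recorded (pipette) current for every step, with optional Gaussian
#' current noise and the generating parameters attached as ground truth.
#'
#' @param params a [membrane_params()] object.
#' @param protocol a [step_protocol()] object.
#' @param noise_rms RMS of added Gaussian current noise, pA.
#' @param seed optional integer seed for the noise.
#' @param metadata optional named list (cell id, region, age, ...).
#' @return A `sweep_bundle`: list with `time` (s), `sweeps` (samples x
#'   steps matrix of current, pA), `protocol`, `metadata` and
#'   `ground_truth`.
#' @export
simulate_voltage_clamp <- function(params, protocol = step_protocol(),
                                   noise_rms = 0, seed = NULL,
                                   metadata = list()) {
  stopifnot(inherits(params, "membrane_params"),
            inherits(protocol, "step_protocol"), noise_rms >= 0)
  dt <- 1000 / protocol$fs
  v0 <- clamp_steady_state(protocol$v_hold, params)
  g_s <- 1000 / params$rs
  sweeps <- vapply(protocol$potentials, function(vs) {
    out <- integrate_clamp(command_waveform(protocol, vs), params$e_k, dt,
                           v0, params$cm, g_s,
                           params$g_leak, params$e_leak,
                           params$g_kir, params$v_half_kir, params$k_kir,
                           params$g_out, params$v_half_out, params$k_out)
    out$current
  }, numeric(round(protocol$duration * protocol$fs / 1000)))
  if (noise_rms > 0)
    sweeps <- sweeps + with_seed(seed, matrix(
      rnorm(length(sweeps), 0, noise_rms), nrow(sweeps)))
  colnames(sweeps) <- sprintf("sweep_%02d", seq_along(protocol$potentials))
  structure(list(time = protocol_times(protocol), sweeps = sweeps,
                 protocol = protocol, metadata = metadata,
                 ground_truth = list(params = params, noise_rms = noise_rms)),
            class = "sweep_bundle")
}

#' @export
print.sweep_bundle <- function(x, ...) {
  cat("Voltage-clamp sweep bundle:", ncol(x$sweeps), "sweeps of",
      nrow(x$sweeps), "samples at", x$protocol$fs / 1000, "kHz;",
      "steps", min(x$protocol$potentials), "to", max(x$protocol$potentials),
      "mV from", x$protocol$v_hold, "mV\n")
  invisible(x)
}
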