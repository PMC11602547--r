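#' Fit the capacitive transient of a voltage step
#'
#' Estimates series resistance, input resistance and membrane capacitance
#' from the current transient evoked by one voltage step.  A single
#' exponential `I(t) = I_ss + A exp(-t/tau)` is fitted to the post-step
#' decay (log-linear initialisation refined by Levenberg-Marquardt least
#' squares); the peak current is the fit back-extrapolated to step onset,
#' so the estimate does not depend on the first sample catching the peak.
#' Then `Rs = dV / (I_peak - I_base)`, `R_input = dV / (I_ss - I_base) - Rs`
#' and `Cm = tau (Rs + R_input) / (Rs R_input)`.
#'
#' @param sweep numeric vector of recorded current, pA.
#' @param protocol the [step_protocol()] describing the sweep.
#' @param v_step the command potential of this sweep, mV.
#' @return List with `rs` (MOhm), `r_input` (MOhm), `cm` (pF), `tau` (ms),
#'   `i_baseline`, `i_peak`, `i_ss` (pA) and `qc_fail` (character, empty
#'   when the fit is usable).
#' @export
fit_capacitive_transient <- function(sweep, protocol, v_step) {
  fs <- protocol$fs
  dt_ms <- 1000 / fs
  i_on <- floor(protocol$t_start * fs / 1000) + 1
  i_off <- floor(protocol$t_end * fs / 1000)
  if (i_on < 10 || i_off - i_on < 10)
    stop("step too short to resolve a transient")
  dv <- v_step - protocol$v_hold
  if (dv == 0) stop("zero-amplitude step has no transient")
  i_base <- mean(sweep[seq_len(i_on - 2)])
  # steady state from the last 20% of the step
  ss_idx <- seq(floor(i_on + 0.8 * (i_off - i_on)), i_off)
  i_ss <- mean(sweep[ss_idx])
  noise_sd <- sd(sweep[seq_len(i_on - 2)])

  fail <- function(msg) list(rs = NA_real_, r_input = NA_real_,
                             cm = NA_real_, tau = NA_real_,
                             i_baseline = i_base, i_peak = NA_real_,
                             i_ss = i_ss, qc_fail = msg)

  # decay samples, time measured from the command transition boundary
  dec_idx <- i_on:i_off
  t_rel <- (dec_idx - i_on + 1) * dt_ms
  y <- sweep[dec_idx] - i_ss
  a0 <- y[1]
  if (!is.finite(a0) || abs(a0) <= 3 * max(noise_sd, 1e-12))
    return(fail("no resolvable transient"))
  # log-linear start on the initial run of samples clearly above the noise
  ok <- sign(y) == sign(a0) & abs(y) > max(3 * noise_sd, 0.02 * abs(a0))
  first_bad <- which(!ok)[1]
  usable <- if (is.na(first_bad)) seq_along(y) else seq_len(first_bad - 1)
  if (length(usable) < 5) return(fail("no resolvable transient"))
  lf <- lm(log(abs(y[usable])) ~ t_rel[usable])
  tau0 <- -1 / coef(lf)[[2]]
  if (!is.finite(tau0) || tau0 <= 0) return(fail("non-decaying transient"))
  a_start <- sign(a0) * exp(coef(lf)[[1]])
  # refine on a window of ~8 tau by Levenberg-Marquardt
  win <- seq_len(min(length(y), max(20, ceiling(8 * tau0 / dt_ms))))
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ A * exp(-tt / tau),
                      data = list(yy = y[win], tt = t_rel[win]),
                      start = list(A = a_start, tau = tau0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("transient fit did not converge"))
  cf <- coef(fit)
  tau <- cf[["tau"]]
  i_peak <- i_ss + cf[["A"]]
  rs <- 1000 * dv / (i_peak - i_base)          # mV/pA -> GOhm -> MOhm
  r_input <- 1000 * dv / (i_ss - i_base) - rs
  if (!is.finite(rs) || rs <= 0 || !is.finite(r_input) || r_input <= 0)
    return(fail("negative derived resistance"))
  cm <- 1000 * tau * (rs + r_input) / (rs * r_input)  # ms/MOhm -> pF
  list(rs = rs, r_input = r_input, cm = cm, tau = tau,
       i_baseline = i_base, i_peak = i_peak, i_ss = i_ss,
       qc_fail = character(0))
}

#' Steady-state current/voltage curve of a sweep bundle
#'
#' Averages the recorded current of every sweep over the final part of
#' the voltage step (default: last 50 ms, far beyond the membrane time
#' constant of any plausible cell) and pairs it with the junction-
#' corrected step potential.
#'
#' @param bundle a `sweep_bundle`.
#' @param window averaging window before step end, ms.
#' @param junction_offset_mV offset subtracted from command potentials
#'   when `bundle$metadata$junction_corrected` is `FALSE`; recordings
#'   corrected at acquisition (the default assumption) are left as is.
#' @return An `iv_curve`: data frame with `v` (mV) and `i` (pA), with the
#'   window stored as an attribute.
#' @export
steady_state_iv <- function(bundle, window = 50, junction_offset_mV = -14) {
  p <- bundle$protocol
  if (window <= 0 || window > p$t_end - p$t_start)
    stop("averaging window must lie within the step")
  fs <- p$fs
  i_off <- floor(p$t_end * fs / 1000)
  idx <- seq(i_off - round(window * fs / 1000) + 1, i_off)
  i_ss <- colMeans(bundle$sweeps[idx, , drop = FALSE])
  v <- p$potentials
  corrected <- isTRUE(bundle$metadata$junction_corrected) ||
    is.null(bundle$metadata$junction_corrected)
  if (!corrected) v <- v + junction_offset_mV
  structure(data.frame(v = v, i = unname(i_ss)),
            window_ms = window, class = c("iv_curve", "data.frame"))
}

#' Resting membrane potential from an I/V curve
#'
#' Zero-current potential by linear interpolation between the two points
#' bracketing the sign change of the steady-state current.
#'
#' @param iv an `iv_curve` (data frame with `v`, `i`).
#' @return RMP in mV, or `NA` with a `"no zero crossing"` QC attribute
#'   when the curve does not cross zero.
#' @export
resting_potential <- function(iv) {
  s <- sign(iv$i)
  k <- which(s[-1] * s[-length(s)] <= 0 & s[-length(s)] != 0)
  if (any(iv$i == 0)) return(iv$v[which(iv$i == 0)[1]])
  if (length(k) == 0)
    return(structure(NA_real_, qc_fail = "no zero crossing"))
  k <- k[1]
  iv$v[k] - iv$i[k] * (iv$v[k + 1] - iv$v[k]) / (iv$i[k + 1] - iv$i[k])
}

#' Inward conductance from an I/V curve
#'
#' Slope (nS) of the least-squares line through the steady-state I/V
#' points between the most hyperpolarized tested potential and the K+
#' equilibrium potential -- the operational definition of the inward
#' (Kir-dominated) conductance.  With 20 mV steps and physiological
#' solutions fewer than three sampled potentials lie at or below `E_K`,
#' so the window is extended upward to the next sampled potential(s)
#' until three points are available; the window actually used is
#' reported.
#'
#' @param iv an `iv_curve`.
#' @param e_k K+ equilibrium potential, mV (see [nernst_potential()]).
#' @param v_min lower end of the slope window, mV; defaults to the most
#'   hyperpolarized tested potential.
#' @return `g_in` in nS with attributes `window` (mV range used) and
#'   `n_points`.
#' @export
inward_conductance <- function(iv, e_k, v_min = min(iv$v)) {
  sel <- which(iv$v >= v_min & iv$v <= e_k)
  if (length(sel) < 3) {
    above <- which(iv$v > e_k & iv$v >= v_min)
    need <- 3 - length(sel)
    if (length(above) < need)
      stop(sprintf("fewer than 3 I/V points available in [%g, %g] mV",
                   v_min, e_k))
    sel <- sort(c(sel, above[seq_len(need)]))
  }
  fit <- lm(i ~ v, data = iv[sel, ])
  structure(unname(coef(fit)[2]),
            window = range(iv$v[sel]), n_points = length(sel))
}

#' Quality-control criteria for whole-cell recordings
#'
#' @param max_leak_pA maximum absolute leak (holding) current, pA.
#' @param rs_bounds_MOhm admissible series-resistance range, MOhm.
#' @param max_drift_pA_per_min maximum baseline drift, pA/min.
#' @export
qc_criteria <- function(max_leak_pA = 500, rs_bounds_MOhm = c(2, 60),
                        max_drift_pA_per_min = 50) {
  stopifnot(max_leak_pA > 0, all(rs_bounds_MOhm > 0),
            max_drift_pA_per_min > 0)
  structure(list(max_leak_pA = max_leak_pA, rs_bounds_MOhm = rs_bounds_MOhm,
                 max_drift_pA_per_min = max_drift_pA_per_min),
            class = "qc_criteria")
}

#' Apply inclusion criteria to extracted passive properties
#'
#' @param props a one-row data frame or list of passive properties (as
#'   returned by [passive_properties()]).
#' @param criteria a [qc_criteria()] object.
#' @param drift_pA_per_min optional measured baseline drift.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   violated criteria, empty on pass).
#' @export
apply_qc <- function(props, criteria = qc_criteria(),
                     drift_pA_per_min = NULL) {
  reasons <- character(0)
  if (length(props$qc_flags) && any(nzchar(props$qc_flags)))
    reasons <- c(reasons, props$qc_flags[nzchar(props$qc_flags)])
  if (is.finite(props$leak_pA) &&
      abs(props$leak_pA) >= criteria$max_leak_pA)
    reasons <- c(reasons, sprintf("leak current %.0f pA >= %.0f pA",
                                  abs(props$leak_pA),
                                  criteria$max_leak_pA))
  if (is.finite(props$rs)) {
    if (props$rs < criteria$rs_bounds_MOhm[1] ||
        props$rs > criteria$rs_bounds_MOhm[2])
      reasons <- c(reasons, sprintf("Rs %.1f MOhm outside [%g, %g]",
                                    props$rs, criteria$rs_bounds_MOhm[1],
                                    criteria$rs_bounds_MOhm[2]))
  } else reasons <- c(reasons, "Rs not measurable")
  if (!is.null(drift_pA_per_min) &&
      abs(drift_pA_per_min) > criteria$max_drift_pA_per_min)
    reasons <- c(reasons, "unstable baseline")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Extract passive properties from a sweep bundle
#'
#' Full per-cell pipeline: capacitive-transient fit on the test sweep
#' (the step closest to 20 mV hyperpolarizing, where the response is
#' most nearly linear), steady-state I/V, resting potential by zero-
#' crossing interpolation, inward conductance below `E_K`, and leak
#' (holding) current.
#'
#' @param bundle a `sweep_bundle`.
#' @param e_k K+ equilibrium potential used for the inward-conductance
#'   window, mV.
#' @param window steady-state averaging window, ms.
#' @return One-row data frame: `rmp` (mV), `rm` (MOhm), `cm` (pF),
#'   `rs` (MOhm), `leak_pA`, `g_in` (nS), `e_k`, `qc_flags`.
#' @export
passive_properties <- function(bundle, e_k = nernst_potential(2.5, 132, 295),
                               window = 50) {
  p <- bundle$protocol
  test_idx <- which.min(abs(p$potentials - (p$v_hold - 20)))
  tf <- fit_capacitive_transient(bundle$sweeps[, test_idx], p,
                                 p$potentials[test_idx])
  iv <- steady_state_iv(bundle, window = window)
  rmp <- resting_potential(iv)
  g_in <- tryCatch(inward_conductance(iv, e_k = e_k), error = function(e) NA_real_)
  flags <- c(tf$qc_fail,
             if (is.na(rmp)) attr(rmp, "qc_fail"),
             if (is.na(g_in)) "inward-conductance window unusable")
  i_on <- floor(p$t_start * p$fs / 1000) + 1
  leak <- mean(bundle$sweeps[seq_len(i_on - 2), test_idx])
  out <- data.frame(rmp = as.numeric(rmp), rm = tf$r_input, cm = tf$cm,
                    rs = tf$rs, leak_pA = leak,
                    g_in = as.numeric(g_in), e_k = e_k,
                    qc_flags = paste(flags, collapse = "; "),
                    stringsAsFactors = FALSE)
  attr(out, "iv") <- iv
  out
}
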