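#include <Rcpp.h>
using namespace Rcpp;

// Exponential-Euler integration of a voltage-clamped single-compartment cell.
//
// Circuit: command potential v_cmd through access resistance (conductance
// g_s) onto a membrane with capacitance cm, ohmic leak (g_leak, e_leak),
// an inward-rectifier K+ conductance gated by a falling Boltzmann of
// (V - E_K) and an outward delayed-rectifier gated by a rising Boltzmann
// of V.  E_K may vary sample-by-sample (extracellular K+ transients).
//
// Units: mV, ms, pF, nS, pA; tau = cm/g_tot is in ms since pF/nS = ms.
// Gating is frozen over each sampling interval, which makes the update
// exact for the linear sub-problem and unconditionally stable.
//
// [[Rcpp::export]]
List integrate_clamp(NumericVector v_cmd, NumericVector e_k, double dt,
                     double v0, double cm, double g_s,
                     double g_leak, double e_leak,
                     double g_kir, double v_half_kir, double k_kir,
                     double g_out, double v_half_out, double k_out) {
  const int n = v_cmd.size();
  if (e_k.size() != n && e_k.size() != 1)
    stop("e_k must have length 1 or length(v_cmd)");
  const bool ek_scalar = (e_k.size() == 1);
  NumericVector i_rec(n), vm(n);
  double v = v0;
  for (int i = 0; i < n; ++i) {
    const double ek = ek_scalar ? e_k[0] : e_k[i];
    const double fk = 1.0 / (1.0 + std::exp((v - ek - v_half_kir) / k_kir));
    const double fo = 1.0 / (1.0 + std::exp(-(v - v_half_out) / k_out));
    const double gk = g_kir * fk + g_out * fo;
    const double g_tot = g_s + g_leak + gk;
    const double v_inf = (g_s * v_cmd[i] + g_leak * e_leak + gk * ek) / g_tot;
    v = v_inf + (v - v_inf) * std::exp(-dt * g_tot / cm);
    if (!R_finite(v))
      stop("membrane integration diverged at sample %d", i + 1);
    vm[i] = v;
    i_rec[i] = g_s * (v_cmd[i] - v);
  }
  return List::create(_["current"] = i_rec, _["vm"] = vm);
}
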