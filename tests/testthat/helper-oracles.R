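# Independent oracles used across tests; kept free of package internals.

# Closed-form current of a two-resistor RC cell under a voltage step:
# I(t) = dV/(Rs+Rm) + (dV/Rs - dV/(Rs+Rm)) exp(-t/tau),
# tau = Cm Rs Rm / (Rs + Rm).  Units: mV, MOhm, pF, ms -> pA.
rc_step_current <- function(t_ms, dv_mV, rs_MOhm, rm_MOhm, cm_pF) {
  i_ss <- 1000 * dv_mV / (rs_MOhm + rm_MOhm)
  i_0 <- 1000 * dv_mV / rs_MOhm
  tau_ms <- cm_pF * rs_MOhm * rm_MOhm / (rs_MOhm + rm_MOhm) / 1000
  i_ss + (i_0 - i_ss) * exp(-t_ms / tau_ms)
}

# Lewis-Sargent junction potential for a binary junction of two
# uni-univalent salts at equal concentration, side 1 relative to side 2:
# E = (RT/F) ln(Lambda_1 / Lambda_2).
lewis_sargent_mV <- function(lambda_cat1, lambda_cat2, lambda_an,
                             temperature_K) {
  rt_f <- 1000 * 8.31446261815324 * temperature_K / 96485.33212331
  -rt_f * log((lambda_cat1 + lambda_an) / (lambda_cat2 + lambda_an))
}

# Ideal Nernst potential, mV (duplicated on purpose as a test oracle).
nernst_oracle <- function(ko, ki, temp_K) {
  1000 * 8.31446261815324 * temp_K / 96485.33212331 * log(ko / ki)
}

# Build an iv_curve object directly from numbers.
make_iv <- function(v, i) {
  structure(data.frame(v = v, i = i), window_ms = 50,
            class = c("iv_curve", "data.frame"))
}
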