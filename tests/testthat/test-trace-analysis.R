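test_that("capacitive-transient fit inverts the RC generator exactly at zero noise", {
  p <- membrane_params(rs = 10, cm = 30, g_leak = 5, e_leak = -74,
                       g_kir = 0, g_out = 0, e_k = -74)  # Rm = 200 MOhm
  b <- simulate_voltage_clamp(p, noise_rms = 0)
  prot <- b$protocol
  j <- which(prot$potentials == -94)
  fit <- fit_capacitive_transient(b$sweeps[, j], prot, -94)
  expect_length(fit$qc_fail, 0)
  expect_lt(abs(fit$rs - 10) / 10, 0.01)
  expect_lt(abs(fit$r_input - 200) / 200, 0.01)
  expect_lt(abs(fit$cm - 30) / 30, 0.01)
})

test_that("steady-state I/V uses the default protocol's nine step potentials", {
  b <- simulate_voltage_clamp(membrane_params(), noise_rms = 0)
  iv <- steady_state_iv(b)
  expect_equal(nrow(iv), 9)
  expect_equal(iv$v, seq(-134, 26, by = 20))
  expect_error(steady_state_iv(b, window = 500))
})

test_that("junction offset is applied only to uncorrected recordings", {
  b <- simulate_voltage_clamp(membrane_params(), noise_rms = 0,
                              metadata = list(junction_corrected = FALSE))
  iv <- steady_state_iv(b)
  expect_equal(iv$v, seq(-134, 26, by = 20) - 14)
})

test_that("resting potential and inward conductance on an ideal ohmic I/V", {
  v <- seq(-134, 26, by = 20)
  iv <- make_iv(v, 1 * (v - -74))       # 1 nS line through -74 mV
  expect_equal(resting_potential(iv), -74)
  expect_equal(as.numeric(inward_conductance(iv, e_k = -100.8)), 1,
               tolerance = 1e-12)
  # invariance to a current offset, linearity under current scaling
  expect_equal(as.numeric(inward_conductance(make_iv(v, iv$i + 50), -100.8)),
               1, tolerance = 1e-12)
  expect_equal(as.numeric(inward_conductance(make_iv(v, 3 * iv$i), -100.8)),
               3, tolerance = 1e-12)
})

test_that("RMP from the I/V matches the model's zero-current root within 1 mV", {
  p <- membrane_params(rs = 5, g_leak = 1, e_leak = -40, g_kir = 5)
  b <- simulate_voltage_clamp(p, noise_rms = 0)
  iv <- steady_state_iv(b)
  root <- uniroot(function(v) membrane_current(v, p), c(-200, 100))$root
  expect_lt(abs(resting_potential(iv) - root), 1)
})

test_that("an I/V without a zero crossing yields a flagged, undefined RMP", {
  v <- seq(-134, 26, by = 20)
  rmp <- resting_potential(make_iv(v, v + 200))   # all positive
  expect_true(is.na(rmp))
  expect_match(attr(rmp, "qc_fail"), "zero crossing")
})

test_that("inward conductance errors when too few points are available", {
  iv <- make_iv(c(-134, -114), c(-50, -30))
  expect_error(inward_conductance(iv, e_k = -100.8), "3 I/V points")
})

test_that("QC applies the 500 pA leak criterion and Rs bounds", {
  props <- data.frame(rmp = -90, rm = 200, cm = 30, rs = 20,
                      leak_pA = 499, g_in = 3, qc_flags = "")
  expect_true(apply_qc(props)$pass)
  expect_length(apply_qc(props)$reasons, 0)
  props$leak_pA <- 501
  r <- apply_qc(props)
  expect_false(r$pass)
  expect_match(r$reasons, "leak current")
  props$leak_pA <- 100; props$rs <- 80
  expect_false(apply_qc(props)$pass)
})

test_that("QC excludes exactly the injected high-leak fraction of a cohort", {
  set.seed(2)
  n <- 30; bad <- rep(c(TRUE, FALSE), c(9, 21))
  props <- data.frame(rmp = -90, rm = 200, cm = 30, rs = 20,
                      leak_pA = ifelse(bad, runif(n, 600, 900),
                                       runif(n, 0, 300)),
                      g_in = 3, qc_flags = "")
  pass <- vapply(seq_len(n), function(i) apply_qc(props[i, ])$pass, TRUE)
  expect_equal(sum(!pass), sum(bad))
})

test_that("Nernst potential: identity, printed solutions, ten-fold shift", {
  expect_equal(nernst_potential(2.5, 2.5), 0)
  expect_equal(nernst_potential(2.5, 132, 295),
               nernst_oracle(2.5, 132, 295))
  expect_equal(nernst_potential(2.5, 132, 295), -100.8, tolerance = 1e-3)
  shift <- nernst_potential(25, 132, 295) - nernst_potential(2.5, 132, 295)
  expect_equal(shift, theoretical_nernst_slope(295), tolerance = 1e-10)
  expect_error(nernst_potential(-1, 132))
})

test_that("estimated inward conductance is monotone in the generator's g_kir", {
  g <- vapply(c(1, 3, 6, 10), function(gk) {
    b <- simulate_voltage_clamp(membrane_params(rs = 2, g_kir = gk),
                                noise_rms = 0)
    as.numeric(inward_conductance(steady_state_iv(b),
                                  e_k = nernst_potential(2.5)))
  }, 0)
  expect_true(all(diff(g) > 0))
})

test_that("passive properties are recovered from noisy sweeps", {
  pop <- simulate_population(population_spec(n = 20), seed = 31)
  props <- do.call(rbind, lapply(pop$bundles, passive_properties))
  expect_lt(median(abs(props$rs - pop$truth$rs) / pop$truth$rs), 0.05)
  expect_lt(median(abs(props$rm - pop$truth$rm_true) /
                     pop$truth$rm_true), 0.05)
  expect_lt(median(abs(props$cm - pop$truth$cm) / pop$truth$cm), 0.10)
  expect_lt(median(abs(props$g_in - pop$truth$g_in_true) /
                     pop$truth$g_in_true), 0.05)
})
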