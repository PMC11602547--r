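test_that("calibration fit recovers a perfect Nernstian electrode exactly", {
  pts <- simulate_kism_calibration(true_slope = 59.2, intercept = 3,
                                   noise_sd = 0)
  cal <- fit_calibration(pts$conc_mM, pts$voltage_mV)
  expect_equal(cal$slope, 59.2, tolerance = 1e-10)
  expect_equal(cal$intercept, 3, tolerance = 1e-10)
  expect_equal(cal$residual_sd, 0, tolerance = 1e-10)
  expect_true(cal$is_nernstian)
})

test_that("a sub-Nernstian electrode (<= 50 mV/decade) is flagged", {
  pts <- simulate_kism_calibration(true_slope = 45, noise_sd = 0)
  expect_false(fit_calibration(pts$conc_mM, pts$voltage_mV)$is_nernstian)
  expect_error(fit_calibration(c(10, 10), c(1, 2)), "distinct")
})

test_that("noisy calibration slope estimates are unbiased", {
  set.seed(4)
  slopes <- replicate(200, {
    pts <- simulate_kism_calibration(true_slope = 58.54, noise_sd = 1)
    fit_calibration(pts$conc_mM, pts$voltage_mV)$slope
  })
  # MC standard error of the mean slope
  expect_lt(abs(mean(slopes) - 58.54), 4 * sd(slopes) / sqrt(200))
})

test_that("theoretical Nernstian slope matches the closed form and is linear in T", {
  expect_equal(theoretical_nernst_slope(298.15), 59.16, tolerance = 1e-2)
  expect_equal(theoretical_nernst_slope(295), 58.54, tolerance = 1e-2)
  s1 <- theoretical_nernst_slope(280); s2 <- theoretical_nernst_slope(560)
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  expect_lt(theoretical_nernst_slope(1e-6), 1e-3)
})

test_that("voltage-to-concentration inverts the forward calibration", {
  cal <- fit_calibration(c(1, 2, 10, 20),
                         58.54 * log10(c(1, 2, 10, 20)) + 5)
  # constant at the intercept -> 1 mM
  expect_equal(voltage_to_concentration(rep(5, 10), NULL, cal),
               rep(1, 10))
  k <- c(2.5, 2.8, 3.4, 2.6)
  v <- 58.54 * log10(k) + 5
  expect_equal(voltage_to_concentration(v, NULL, cal), k,
               tolerance = 1e-10)
})

test_that("reference subtraction removes a common-mode field-potential signal", {
  cal <- fit_calibration(c(1, 2, 10, 20), 58.54 * log10(c(1, 2, 10, 20)))
  k <- seq(2.5, 3.5, length.out = 50)
  fp <- 0.5 * sin(seq(0, 6, length.out = 50))
  ism <- 58.54 * log10(k) + fp
  expect_equal(voltage_to_concentration(ism, fp, cal), k,
               tolerance = 1e-12)
})

test_that("session round trip recovers [K+]e within 1e-6 at zero noise", {
  ses <- simulate_slic_session(duration_s = 30, noise_rms = 0,
                               fp_noise_mV = 0, ism_noise_mV = 0,
                               seed = 12)
  cal <- attr(ses, "cal")
  fit <- fit_calibration(c(1, 2, 10, 20),
                         cal$slope * log10(c(1, 2, 10, 20)) + cal$intercept)
  k_rec <- voltage_to_concentration(ses$ism, ses$fp, fit)
  k_true <- attr(ses, "truth")$k_series
  expect_lt(max(abs(k_rec - k_true) / k_true), 1e-6)
})

test_that("junction potential is zero for identical solutions and antisymmetric", {
  int <- internal_kgluconate(); ext <- hepes_acsf()
  expect_equal(junction_potential(int, int), 0, tolerance = 1e-9)
  expect_equal(junction_potential(int, ext),
               -junction_potential(ext, int), tolerance = 1e-9)
})

test_that("binary junction matches the Lewis-Sargent closed form", {
  kcl <- solution_composition(c("K", "Cl"), c(100, 100), c(1, -1))
  nacl <- solution_composition(c("Na", "Cl"), c(100, 100), c(1, -1))
  lam <- ionic_mobilities()
  expect_equal(junction_potential(kcl, nacl, 298.15),
               lewis_sargent_mV(lam[["K"]], lam[["Na"]], lam[["Cl"]],
                                298.15),
               tolerance = 1e-9)
})

test_that("printed pipette solution against HEPES-aCSF gives about -14 mV", {
  ljp <- junction_potential(internal_kgluconate(), hepes_acsf(), 295)
  expect_lt(abs(ljp - (-14)), 2)
})

test_that("missing ionic mobilities are reported by species name", {
  expect_error(solution_composition("unobtainium", 10, 1), "unobtainium")
})
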