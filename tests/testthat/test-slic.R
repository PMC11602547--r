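rt_f_295 <- 1000 * 8.31446261815324 * 295 / 96485.33212331

test_that("Nernst delta-I evaluates its closed form", {
  expect_equal(predicted_delta_I(100, 2.5, 2.5), 0)
  expect_equal(predicted_delta_I(100, 2.5, 5.0),
               1000 * rt_f_295 * log(2) / 100, tolerance = 1e-12)
  expect_equal(predicted_delta_I(100, 2.5, 5.0), 176.2, tolerance = 1e-3)
  expect_equal(predicted_delta_I(400, 2.5, 3.0), 11.59, tolerance = 1e-3)
  expect_error(predicted_delta_I(100, -1, 2))
})

test_that("delta-I is algebraically the E_K shift divided by Rm", {
  for (rm in c(50, 178, 960)) for (kp in c(2.6, 3.1, 3.82)) {
    expect_equal(
      predicted_delta_I(rm, 2.5, kp),
      1000 * (nernst_potential(kp, 132, 295) -
                nernst_potential(2.5, 132, 295)) / rm,
      tolerance = 1e-12)
  }
})

test_that("a noise-only trace yields essentially no SLIC detections", {
  set.seed(6)
  fp_rate <- mean(replicate(10, {
    tr <- rnorm(120 * 2000, 0, 5)
    ev <- detect_events(tr, 2000)
    sum(ev$class == "SLIC") / 2          # events per minute
  }))
  expect_lt(fp_rate, 0.01)
  expect_error(detect_events(c(1, NA, 3), 2000), "non-finite")
})

test_that("SLICs well above the noise are detected with accurate onsets", {
  sc <- activity_scenario(event_times_s = seq(8, 98, by = 10), dk_mM = 0.8,
                          syn_rate = 0)
  ses <- simulate_slic_session(scenario = sc, duration_s = 110,
                               noise_rms = 5, seed = 21)
  ev <- detect_events(ses$current, attr(ses, "fs"))
  slics <- ev[ev$class == "SLIC", ]
  truth <- attr(ses, "truth")
  expect_gte(nrow(slics), 9)
  matched <- vapply(truth$event_times, function(t0)
    min(abs(slics$onset - t0)), 0)
  expect_lt(max(matched), 0.05)
  # no SLIC-classed detection away from any true event
  far <- vapply(slics$peak_time, function(t0)
    min(abs(truth$peak_times - t0)), 0)
  expect_true(all(far < 1))
})

test_that("detector sensitivity is monotone non-decreasing in amplitude", {
  sens <- vapply(c(0.15, 0.45, 1.2), function(dk) {
    sc <- activity_scenario(event_times_s = seq(8, 98, by = 10),
                            dk_mM = dk, syn_rate = 0)
    ses <- simulate_slic_session(scenario = sc, duration_s = 110,
                                 noise_rms = 5, seed = 33)
    ev <- detect_events(ses$current, attr(ses, "fs"))
    truth <- attr(ses, "truth")
    mean(vapply(truth$peak_times, function(t0)
      any(abs(ev$peak_time[ev$class == "SLIC"] - t0) < 0.5), TRUE))
  }, 0)
  expect_true(all(diff(sens) >= 0))
})

test_that("fast synaptic-like currents are separated from SLICs by duration", {
  sc <- activity_scenario(event_times_s = c(20, 50), dk_mM = 0.8,
                          syn_rate = 0.5)
  ses <- simulate_slic_session(scenario = sc, duration_s = 70,
                               noise_rms = 2, seed = 14)
  ev <- detect_events(ses$current, attr(ses, "fs"))
  expect_equal(sum(ev$class == "SLIC"), 2)
  expect_gt(sum(ev$class == "synaptic"), 5)
  expect_true(all(ev$halfwidth[ev$class == "synaptic"] < 0.2))
})

test_that("event pairing recovers the configured neuronal latency", {
  expect_equal(pair_event_latencies(c(1, 2, 3), c(1, 2, 3))$latencies,
               c(0, 0, 0))
  p <- pair_event_latencies(c(5, 9), numeric(0))
  expect_equal(p$unmatched_opc, 2)
  ses <- simulate_slic_session(
    scenario = activity_scenario(event_times_s = seq(10, 100, by = 10),
                                 syn_rate = 0),
    duration_s = 110, noise_rms = 0, fp_noise_mV = 0, seed = 2)
  truth <- attr(ses, "truth")
  lat <- pair_event_latencies(truth$peak_times, truth$fp_peak_times)
  expect_equal(median(lat$latencies), 0.02, tolerance = 1e-9)
  expect_true(all(lat$latencies > 0))   # FP strictly precedes
})

test_that("percent block follows event-rate arithmetic", {
  expect_equal(as.numeric(percent_block(12, 0, 300, 300)), 100)
  expect_equal(as.numeric(percent_block(8, 8, 300, 300)), 0)
  # invariance to uniform time rescaling of both epochs
  expect_equal(as.numeric(percent_block(10, 4, 300, 300)),
               as.numeric(percent_block(10, 4, 600, 600)))
  flagged <- percent_block(0, 3, 300, 300)
  expect_true(is.na(flagged))
  expect_match(attr(flagged, "qc_fail"), "pre epoch")
})

test_that("thinning events by 0.7 yields about 70% block", {
  set.seed(8)
  blocks <- replicate(200, {
    n_pre <- rpois(1, 30) + 1
    n_post <- rbinom(1, n_pre, 0.3)
    as.numeric(percent_block(n_pre, n_post, 300, 300))
  })
  expect_lt(abs(mean(blocks) - 70), 2)
})

test_that("conductance block matches the simulated Kir fraction", {
  p <- membrane_params(rs = 0.5, g_leak = 1, g_kir = 6)
  pre <- steady_state_iv(simulate_voltage_clamp(p, noise_rms = 0))
  p_blk <- p; p_blk$g_kir <- 0
  post <- steady_state_iv(simulate_voltage_clamp(p_blk, noise_rms = 0))
  blk <- block_of_inward_current(pre, post, e_k = p$e_k)
  expect_equal(blk, 100 * 6 / 7, tolerance = 0.02)
  expect_equal(block_of_inward_current(pre, pre, e_k = p$e_k), 0,
               tolerance = 1e-9)
  p_res <- p; p_res$g_kir <- 0.05 * 6; p_res$g_leak <- 0.05 * 1
  post2 <- steady_state_iv(simulate_voltage_clamp(p_res, noise_rms = 0))
  expect_equal(block_of_inward_current(pre, post2, e_k = p$e_k), 95,
               tolerance = 0.01)
})

test_that("amplitudes generated exactly from Rm give a near-perfect Rm fit", {
  # narrow Rm span so the 1/Rm dependence is close to linear
  rm <- seq(140, 260, length.out = 12)
  ev <- data.frame(cell_id = seq_along(rm),
                   amplitude = predicted_delta_I(rm, 2.5, 3.2),
                   k_peak = 3.2)
  cells <- data.frame(cell_id = seq_along(rm), rm = rm)
  expect_error(amplitude_regressions(ev, cells), "degenerate")
  ev$k_peak <- runif(12, 2.6, 3.8)      # decoupled from amplitude
  r <- amplitude_regressions(ev, cells)
  expect_gt(r$r_squared[r$predictor == "rm"], 0.9)
  expect_equal(r$direction[r$predictor == "rm"], "negative")
})

test_that("shuffled covariates are significant only at the nominal rate", {
  set.seed(19)
  hits <- replicate(100, {
    d <- simulate_regression_cohort(seed = sample.int(1e6, 1))
    d$cells$rm <- sample(d$cells$rm)    # break the Rm link
    r <- amplitude_regressions(d$events, d$cells)
    r$p_value[r$predictor == "rm"] < 0.05
  })
  expect_lt(mean(hits), 0.12)
})
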