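test_that("a clearly bimodal cohort prefers the two-Gaussian model", {
  set.seed(3)
  spec <- population_spec()
  g <- draw_inward_conductances(spec, seed = 3)
  fit <- fit_conductance_mixture(g)
  expect_equal(fit$preferred, "two")
  expect_lt(fit$p_value, 0.05)
  expect_gt(fit$r_squared[["two"]], 0.8)
  expect_lt(fit$two$mu1, fit$two$mu2)
  expect_equal(fit$two$mu1, spec$mu[1], tolerance = 0.25)
  expect_equal(fit$two$mu2, spec$mu[2], tolerance = 0.15)
})

test_that("non-positive conductances are excluded with a count", {
  set.seed(5)
  g <- c(10^rnorm(100, 0.3, 0.2), -1, 0, NA)
  fit <- fit_conductance_mixture(g)
  expect_equal(fit$n_excluded, 3)
  expect_equal(fit$n, 100)
})

test_that("AIC and the F-test agree on clearly separated mixtures", {
  set.seed(17)
  spec <- population_spec()
  agree <- replicate(20, {
    fit <- fit_conductance_mixture(draw_inward_conductances(spec))
    (fit$p_value < 0.05) == (fit$aic[["two"]] < fit$aic[["one"]])
  })
  expect_gte(mean(agree), 0.9)
})

test_that("state threshold is the low component's percentile, with the
           symmetric reading reported", {
  fit <- structure(list(two = list(mu1 = 0, sigma1 = 1e-9, a1 = 50,
                                   mu2 = 1, sigma2 = 0.2, a2 = 40),
                        preferred = "two"),
                   class = "mixture_fit")
  thr <- state_threshold(fit)
  expect_equal(as.numeric(thr), 1, tolerance = 1e-6)     # 10^0
  expect_equal(as.numeric(state_threshold(fit, percentile = 0.5)), 1)
  expect_equal(attr(thr, "alternative"),
               10^(1 - qnorm(0.9) * 0.2), tolerance = 1e-9)
  fit$preferred <- "one"
  expect_error(state_threshold(fit), "not preferred")
})

test_that("EM cross-check agrees with the histogram fit on component means", {
  skip_if_not_installed("mclust")
  spec <- population_spec()
  g <- draw_inward_conductances(spec, seed = 8)
  ls_fit <- fit_conductance_mixture(g)
  em <- fit_conductance_mixture_em(g)
  expect_equal(sort(unname(em$mu)), c(ls_fit$two$mu1, ls_fit$two$mu2),
               tolerance = 0.15)
  expect_equal(em$bic_preferred, 2)
})

test_that("cell classification at the boundary is correct, idempotent and
           order-stable", {
  cohort <- data.frame(cell_id = 1:4, g_in = c(1, 3, 2.35, 0.4),
                       region = "ctx", age_days = 30)
  c1 <- classify_cells(cohort, 2.35)
  expect_equal(c1$state, c("low", "high", "low", "low"))
  expect_equal(classify_cells(c1, 2.35)$state, c1$state)
  shuf <- classify_cells(cohort[c(3, 1, 4, 2), ], 2.35)
  expect_equal(shuf$state[match(cohort$cell_id, shuf$cell_id)], c1$state)
  expect_equal(attr(classify_cells(data.frame(g_in = c(1, 2)), 10),
                    "proportions"), NULL)
  expect_equal(mean(classify_cells(data.frame(g_in = c(1, 2)),
                                   10)$state == "high"), 0)
})

test_that("territory density class uses the more-than-5-NeuN rule", {
  expect_equal(territory_density(0)$class, "low")
  expect_equal(territory_density(5)$class, "low")
  expect_equal(territory_density(6)$class, "high")
  # boundary-inclusive counting from raw coordinates
  pts <- rbind(c(40, 0), c(0, -40), c(41, 0), c(10, 10))
  td <- territory_density(points = pts, diameter_um = 80)
  expect_equal(td$count, 3L)
})

test_that("Poisson soma fields have the expected territory counts", {
  set.seed(23)
  lambda_per_um2 <- 9 / (pi * 40^2)     # 9 expected somata per territory
  counts <- replicate(300, {
    n <- rpois(1, lambda_per_um2 * 120^2)
    pts <- cbind(runif(n, -60, 60), runif(n, -60, 60))
    territory_density(points = pts, diameter_um = 80)$count
  })
  expect_equal(mean(counts), 9, tolerance = 0.1)
})

test_that("group summaries reproduce overall means for a single group", {
  cohort <- data.frame(g = "a", rmp = c(-90, -80, -85), rm = c(100, 200, 150),
                       g_in = c(2, 4, 3))
  s <- group_summaries(cohort, "g", measures = c("rmp", "rm", "g_in"))
  expect_equal(s$summary$rmp_mean, -85)
  expect_equal(s$summary$g_in_mean, 3)
  expect_equal(s$summary$n, 3)
})

test_that("G1/G0 cells have higher conductance and proliferate less in the
           generated cohort", {
  pop <- simulate_population(population_spec(n = 120), seed = 77,
                             sweeps = FALSE)
  tr <- pop$truth
  tr$g_in <- tr$g_in_true
  s <- group_summaries(tr, "cycle_label", measures = "g_in",
                       marker = "edu_pos")
  g1 <- s$summary[s$summary$group == "G1/G0", ]
  g2 <- s$summary[s$summary$group == "G2/M", ]
  expect_gt(g1$g_in_mean, g2$g_in_mean)
  expect_lt(s$tests$p_value[1], 0.05)
  # proliferation fraction lower in the high-conductance arm
  s2 <- group_summaries(tr, "state_true", measures = "g_in",
                        marker = "edu_pos")
  hi <- s2$summary[s2$summary$group == "high", ]
  lo <- s2$summary[s2$summary$group == "low", ]
  expect_lt(hi$prolif_fraction, lo$prolif_fraction)
  expect_error(group_summaries(tr, "nonexistent"))
})

test_that("the population generator is anchored, reproducible and honest
           about its boundary", {
  spec <- population_spec()
  expect_equal(spec$boundary, 2.35, tolerance = 1e-3)
  # degenerate single-component population collapses to the component mean
  one <- population_spec(n = 1, weights = c(1, 0), sigma = c(1e-9, 0.18))
  pop1 <- simulate_population(one, seed = 4, sweeps = FALSE)
  expect_equal(pop1$truth$g_in_true, 10^one$mu[1], tolerance = 1e-6)
  p_a <- simulate_population(population_spec(n = 25), seed = 9,
                             sweeps = FALSE)
  p_b <- simulate_population(population_spec(n = 25), seed = 9,
                             sweeps = FALSE)
  expect_identical(p_a$truth, p_b$truth)
  # neuronal density tracks the conductance component
  pop <- simulate_population(population_spec(n = 150), seed = 5,
                             sweeps = FALSE)
  hi <- pop$truth$component == 2
  expect_gt(mean(pop$truth$neun_count[hi]),
            mean(pop$truth$neun_count[!hi]))
})
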