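#' Specification of a simulated OPC population
#'
#' Defines the two-component log-normal mixture of inward conductance and
#' the conditional models that link conductance to capacitance, cell-cycle
#' phase, proliferation and local neuronal density.  The defaults emulate
#' a cortical cohort: the low-conductance component is anchored so that
#' its 90th percentile equals the 2.35 nS state boundary, the high
#' component sits 3 SD higher on the log10 scale, and capacitance means
#' follow the low/high neuronal-density phenotypes (26 vs 42.1 pF).
#'
#' @param n number of cells.
#' @param weights mixture weights (sum to 1).
#' @param mu,sigma per-component mean and SD of log10 inward conductance
#'   (log10 nS).
#' @param cm_mean,cm_sd per-component membrane capacitance mean/SD (pF).
#' @param rs_meanlog,rs_sdlog log-normal access resistance parameters
#'   (MOhm; default centred on 32 MOhm).
#' @param g_leak_frac fraction of the drawn conductance assigned to the
#'   ohmic leak (the rest is Kir).
#' @param e_leak leak reversal, mV.
#' @param noise_rms current noise RMS for simulated sweeps, pA.
#' @param cycle_beta slope of the G1/G0 probability on
#'   `log10(g_in) - log10(boundary)` (positive: high-conductance cells
#'   are more likely non-cycling G1/G0).
#' @param prolif_intercept,prolif_beta logistic model of the probability
#'   that a cell is proliferation-marker positive (EdU/Ki67), declining
#'   with conductance.
#' @param density_lambda per-component Poisson mean of the NeuN+ count in
#'   the cell's territory.
#' @param territory_diam_mean,territory_diam_sd territory circle diameter
#'   (um; default 80 um, the mean measured OPC territory).
#' @param region,age_days metadata tags.
#' @param percentile percentile of the low component defining the state
#'   boundary.
#' @return A `population_spec` with the analytic state boundary (nS)
#'   stored in `$boundary`.
#' @export
population_spec <- function(n = 264, weights = c(0.5, 0.5),
                            mu = c(0.1404, 0.6804), sigma = c(0.18, 0.18),
                            cm_mean = c(26, 42.1), cm_sd = c(5, 5),
                            rs_meanlog = log(32), rs_sdlog = 0.2,
                            g_leak_frac = 0.2, e_leak = -40,
                            noise_rms = 5,
                            cycle_beta = 3,
                            prolif_intercept = -0.8, prolif_beta = 2,
                            density_lambda = c(3, 9),
                            territory_diam_mean = 80, territory_diam_sd = 8,
                            region = "cortex", age_days = 30,
                            percentile = 0.90) {
  stopifnot(n >= 1, abs(sum(weights) - 1) < 1e-8, all(sigma > 0),
            all(weights >= 0), g_leak_frac >= 0, g_leak_frac < 1,
            percentile > 0, percentile < 1)
  boundary <- 10^(mu[1] + qnorm(percentile) * sigma[1])
  structure(list(n = n, weights = weights, mu = mu, sigma = sigma,
                 cm_mean = cm_mean, cm_sd = cm_sd,
                 rs_meanlog = rs_meanlog, rs_sdlog = rs_sdlog,
                 g_leak_frac = g_leak_frac, e_leak = e_leak,
                 noise_rms = noise_rms, cycle_beta = cycle_beta,
                 prolif_intercept = prolif_intercept,
                 prolif_beta = prolif_beta,
                 density_lambda = density_lambda,
                 territory_diam_mean = territory_diam_mean,
                 territory_diam_sd = territory_diam_sd,
                 region = region, age_days = age_days,
                 percentile = percentile, boundary = boundary),
            class = "population_spec")
}

# Draw inward conductances (nS) from the mixture.
draw_g_in <- function(spec, n = spec$n) {
  comp <- sample.int(length(spec$weights), n, replace = TRUE,
                     prob = spec$weights)
  g <- 10^rnorm(n, spec$mu[comp], spec$sigma[comp])
  list(g_in = g, component = comp)
}

# Least-squares slope of the Kir gating current factor f(V)(V - E_K)
# over the potentials used for the inward-conductance window.
kir_slope_factor <- function(params, potentials, e_k = params$e_k) {
  w <- sort(potentials)[1:3]
  y <- f_kir(w, params, e_k) * (w - e_k)
  unname(coef(lm(y ~ w))[2])
}

#' Simulate a cohort of cells with known ground truth
#'
#' Draws per-cell inward conductance from the mixture, derives membrane
#' parameters so that the measurable inward-limb slope (including the
#' series-resistance attenuation of the voltage clamp) equals the drawn
#' conductance, draws cell-cycle / proliferation / neuronal-density
#' labels from the conditional models, and (optionally) simulates the
#' full voltage-clamp sweeps for every cell.  Draws whose conductance is
#' too large to be clamped through the drawn access resistance are
#' rejected and redrawn, with the count reported.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed; the simulation is fully reproducible.
#' @param sweeps simulate raw sweeps (`TRUE`) or ground truth only.
#' @param protocol a [step_protocol()].
#' @return An `opc_population`: list with `truth` (per-cell data frame),
#'   `bundles` (list of `sweep_bundle` or `NULL`), `spec`, `boundary`
#'   (nS, analytic state boundary recorded by the generator) and
#'   `n_redraws`.
#' @export
simulate_population <- function(spec = population_spec(), seed = 1,
                                sweeps = TRUE, protocol = step_protocol()) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(seed, {
    e_k <- nernst_potential(2.5, 132, 295)
    base <- membrane_params(e_k = e_k)
    n_redraws <- 0L
    cells <- vector("list", spec$n)
    for (i in seq_len(spec$n)) {
      repeat {
        d <- draw_g_in(spec, 1)
        rs <- rlnorm(1, spec$rs_meanlog, spec$rs_sdlog)
        # invert the series-resistance attenuation g_meas = g/(1 + g Rs/1000)
        denom <- 1 - d$g_in * rs / 1000
        if (d$g_in > 0 && denom > 0.05 && rs > 2) break
        n_redraws <- n_redraws + 1L
      }
      g_cell <- d$g_in / denom
      g_leak <- spec$g_leak_frac * g_cell
      cm <- max(8, rnorm(1, spec$cm_mean[d$component],
                         spec$cm_sd[d$component]))
      p <- membrane_params(rs = rs, cm = cm, g_leak = g_leak,
                           e_leak = spec$e_leak, g_kir = 0,
                           e_k = e_k)
      sf <- kir_slope_factor(base, protocol$potentials, e_k)
      p$g_kir <- (g_cell - g_leak) / sf
      lg <- log10(d$g_in) - log10(spec$boundary)
      cycle <- if (runif(1) < stats::plogis(spec$cycle_beta * lg))
        "G1/G0" else "G2/M"
      edu <- runif(1) < stats::plogis(spec$prolif_intercept -
                                        spec$prolif_beta * lg)
      neun <- rpois(1, spec$density_lambda[d$component])
      diam <- max(20, rnorm(1, spec$territory_diam_mean,
                            spec$territory_diam_sd))
      cells[[i]] <- list(params = p, g_in = d$g_in, component = d$component,
                         cycle = cycle, edu = edu, neun = neun, diam = diam)
    }
    truth <- data.frame(
      cell_id = sprintf("cell_%03d", seq_len(spec$n)),
      g_in_true = vapply(cells, `[[`, 0, "g_in"),
      component = vapply(cells, `[[`, 0L, "component"),
      rs = vapply(cells, function(c) c$params$rs, 0),
      cm = vapply(cells, function(c) c$params$cm, 0),
      g_leak = vapply(cells, function(c) c$params$g_leak, 0),
      g_kir = vapply(cells, function(c) c$params$g_kir, 0),
      rm_true = 1000 / vapply(cells, `[[`, 0, "g_in") *
        (1 - vapply(cells, function(c) c$params$rs, 0) *
           vapply(cells, `[[`, 0, "g_in") / 1000),
      cycle_label = vapply(cells, `[[`, "", "cycle"),
      edu_pos = vapply(cells, `[[`, TRUE, "edu"),
      neun_count = vapply(cells, `[[`, 0L, "neun"),
      territory_diam = vapply(cells, `[[`, 0, "diam"),
      region = spec$region, age_days = spec$age_days,
      stringsAsFactors = FALSE)
    truth$state_true <- ifelse(truth$g_in_true > spec$boundary,
                               "high", "low")
    bundles <- NULL
    if (sweeps) {
      bundles <- lapply(seq_len(spec$n), function(i) {
        simulate_voltage_clamp(cells[[i]]$params, protocol,
                               noise_rms = spec$noise_rms,
                               metadata = list(cell_id = truth$cell_id[i],
                                               region = spec$region,
                                               age_days = spec$age_days,
                                               junction_corrected = TRUE))
      })
      names(bundles) <- truth$cell_id
    }
    structure(list(truth = truth, bundles = bundles, spec = spec,
                   boundary = spec$boundary, n_redraws = n_redraws),
              class = "opc_population")
  })
}

#' @export
print.opc_population <- function(x, ...) {
  cat("Simulated OPC population:", nrow(x$truth), "cells;",
      "state boundary", round(x$boundary, 3), "nS;",
      sum(x$truth$state_true == "high"), "high-state cells;",
      x$n_redraws, "redraws\n")
  invisible(x)
}

#' Draw inward conductances from a population mixture
#'
#' Samples conductances (nS) from the two-component log-normal mixture
#' of a [population_spec()] without simulating traces; the sampling
#' model is identical to the one used by [simulate_population()].
#'
#' @param spec a [population_spec()].
#' @param n number of draws (default `spec$n`).
#' @param seed optional integer seed.
#' @return Numeric vector of conductances, nS, with the component index
#'   as attribute `component`.
#' @export
draw_inward_conductances <- function(spec = population_spec(), n = spec$n,
                                     seed = NULL) {
  with_seed(seed, {
    d <- draw_g_in(spec, n)
    structure(d$g_in, component = d$component)
  })
}
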