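#' Limiting equivalent ionic conductivities
#'
#' Built-in table of limiting equivalent conductivities (S cm^2 / eq,
#' 25 degC, water) used by [junction_potential()].  Large organic anions
#' without tabulated values (BAPTA, nucleotides, Lucifer yellow) are
#' assigned gluconate-like mobilities, the convention of standard
#' junction-potential calculators.  Override any entry through the
#' `lambda` column of [solution_composition()].
#'
#' @return Named numeric vector.
#' @export
ionic_mobilities <- function() {
  c(H = 349.8, K = 73.5, Na = 50.1, Li = 38.7, Cs = 77.3, NH4 = 73.7,
    Ca = 59.5, Mg = 53.1, Ba = 63.6,
    Cl = 76.4, Br = 78.1, F = 55.4, NO3 = 71.5, OH = 198,
    HCO3 = 44.5, H2PO4 = 36, SO4 = 80, acetate = 40.9,
    gluconate = 24.3, HEPES = 22.1, MES = 26.8, glutamate = 26,
    BAPTA = 24.3, MgATP = 24.3, ATP = 24.3, GTP = 24.3,
    luciferyellow = 24.3)
}

#' Ionic composition of a solution
#'
#' @param species character vector of ion names (see [ionic_mobilities()]
#'   for the built-in mobility table).
#' @param conc_mM ionic concentrations, mM (of the ion, not the salt).
#' @param charge signed ionic charges (nonzero integers).
#' @param lambda optional limiting equivalent conductivities overriding
#'   the built-in table (NA entries fall back to the table).
#' @return A `solution_composition` data frame.
#' @export
solution_composition <- function(species, conc_mM, charge, lambda = NULL) {
  stopifnot(length(species) == length(conc_mM),
            length(species) == length(charge),
            all(conc_mM >= 0), all(charge != 0))
  if (is.null(lambda)) lambda <- rep(NA_real_, length(species))
  tab <- ionic_mobilities()
  miss <- is.na(lambda)
  lambda[miss] <- tab[species[miss]]
  if (any(is.na(lambda) & conc_mM > 0))
    stop("no mobility for species: ",
         paste(species[is.na(lambda) & conc_mM > 0], collapse = ", "))
  structure(data.frame(species = species, conc_mM = conc_mM,
                       charge = as.integer(charge), lambda = lambda,
                       stringsAsFactors = FALSE),
            class = c("solution_composition", "data.frame"))
}

#' Printed K-gluconate intracellular solution, as ions
#'
#' The standard K-gluconate pipette solution (mM: 130 K-gluconate, 4
#' NaCl, 0.5 CaCl2, 10 HEPES, 10 BAPTA, 4 MgATP, 0.5 Na2GTP, 2 K-Lucifer
#' yellow, pH 7.3 with KOH) decomposed into ions.  HEPES is treated as
#' 50% anionic at pH 7.3, BAPTA as tetra-anionic, MgATP as a divalent
#' anionic complex and GTP as divalent.
#'
#' By default the recipe is entered exactly as printed (K+ = 132 mM,
#' from 130 mM K-gluconate plus 2 mM K-Lucifer yellow), the convention
#' of standard junction-potential calculators, which ignore the
#' unreported ions introduced by pH titration.  `balance =
#' "electroneutral"` instead adds the K+ implied by KOH titration of the
#' weak acids so that the composition is charge-balanced.
#'
#' @param balance `"printed"` (default) or `"electroneutral"`.
#' @return A [solution_composition()].
#' @export
internal_kgluconate <- function(balance = c("printed", "electroneutral")) {
  balance <- match.arg(balance)
  anions <- solution_composition(
    species = c("gluconate", "Cl", "HEPES", "BAPTA", "MgATP", "GTP",
                "luciferyellow"),
    conc_mM = c(130, 4 + 2 * 0.5, 0.5 * 10, 10, 4, 0.5, 2),
    charge = c(-1, -1, -1, -4, -2, -2, -1))
  fixed_cat <- solution_composition(
    species = c("Na", "Ca"), conc_mM = c(4 + 2 * 0.5, 0.5),
    charge = c(1, 2))
  k_total <- if (balance == "printed") 130 + 2 else {
    sum(abs(anions$charge) * anions$conc_mM) -
      sum(abs(fixed_cat$charge) * fixed_cat$conc_mM)
  }
  rbind(solution_composition("K", k_total, 1), fixed_cat, anions)
}

#' Printed HEPES-buffered aCSF bath solution, as ions
#'
#' mM: 144 NaCl, 2.5 KCl, 10 HEPES, 1 NaH2PO4, 2.5 CaCl2, 10 glucose,
#' pH 7.35 with NaOH.  HEPES 50% anionic; glucose is neutral and
#' omitted; Na+ from NaOH titration closes the charge balance.
#'
#' @param mg_mM optional added MgCl2, mM (some recordings use 2 mM).
#' @return A [solution_composition()].
#' @export
hepes_acsf <- function(mg_mM = 0) {
  hepes_an <- 0.5 * 10
  cl <- 144 + 2.5 + 2 * 2.5 + 2 * mg_mM
  na <- 144 + 1 + hepes_an
  sp <- c("Na", "K", "Ca", "Cl", "H2PO4", "HEPES")
  conc <- c(na, 2.5, 2.5, cl, 1, hepes_an)
  chg <- c(1, 1, 2, -1, -1, -1)
  if (mg_mM > 0) { sp <- c(sp, "Mg"); conc <- c(conc, mg_mM); chg <- c(chg, 2) }
  solution_composition(sp, conc, chg)
}

#' Henderson liquid junction potential
#'
#' Potential of the pipette solution relative to the bath, from the
#' Henderson equation with tabulated limiting equivalent conductivities:
#' `LJP = (RT/F) * (sum_i s_i L_i d_i / sum_i |z_i| L_i d_i) *
#' ln(S_bath / S_pip)` with `d_i = c_i(bath) - c_i(pip)`,
#' `S = sum_i |z_i| L_i c_i`, `s_i = sign(z_i)` and `L_i` the equivalent
#' conductivity.  For a K-gluconate pipette in NaCl-rich aCSF the result
#' is negative (pipette negative): K+ leaves the tip faster than
#' gluconate follows.
#'
#' @param internal pipette [solution_composition()].
#' @param external bath [solution_composition()].
#' @param temperature_K absolute temperature, K.
#' @return Junction potential in mV (pipette minus bath).
#' @examples
#' junction_potential(internal_kgluconate(), hepes_acsf())  # approx -14 mV
#' @export
junction_potential <- function(internal, external, temperature_K = 295) {
  stopifnot(inherits(internal, "solution_composition"),
            inherits(external, "solution_composition"),
            nrow(internal) > 0, nrow(external) > 0)
  sp <- union(internal$species, external$species)
  get <- function(sol, what) {
    v <- setNames(rep(0, length(sp)), sp)
    v[sol$species] <- sol[[what]]
    v
  }
  cp <- get(internal, "conc_mM"); cb <- get(external, "conc_mM")
  zp <- get(internal, "charge"); zb <- get(external, "charge")
  z <- ifelse(zp != 0, zp, zb)
  if (any(zp != 0 & zb != 0 & zp != zb))
    stop("inconsistent charges for shared species")
  lam <- pmax(get(internal, "lambda"), get(external, "lambda"))
  d <- cb - cp
  num <- sum(sign(z) * lam * d)
  den <- sum(abs(z) * lam * d)
  s_p <- sum(abs(z) * lam * cp)
  s_b <- sum(abs(z) * lam * cb)
  if (s_p <= 0 || s_b <= 0) stop("solutions must contain ions")
  if (abs(den) < 1e-12) return(0)
  rt_over_f_mV(temperature_K) * (num / den) * log(s_b / s_p)
}

#' Theoretical Nernstian electrode slope
#'
#' Voltage change of an ideal monovalent-cation electrode per 10-fold
#' concentration increase: `ln(10) RT/F`.
#'
#' @param temperature_K absolute temperature, K.
#' @return Slope in mV per decade (59.16 at 298.15 K, 58.54 at 295 K).
#' @export
theoretical_nernst_slope <- function(temperature_K = 295) {
  log(10) * rt_over_f_mV(temperature_K)
}

#' Fit a K+-selective microelectrode calibration
#'
#' Unweighted least-squares log-linear fit `V = slope log10(c) +
#' intercept` to calibration points (typically 1, 2, 10 and 20 mM KCl).
#' The electrode is flagged Nernstian when the fitted slope exceeds
#' 50 mV per decade.
#'
#' @param conc_mM calibration concentrations, mM.
#' @param voltage_mV measured electrode voltages, mV.
#' @return A `kism_calibration`: slope (mV/decade), intercept (mV, the
#'   voltage at 1 mM), residual SD, `is_nernstian`, and the points.
#' @export
fit_calibration <- function(conc_mM, voltage_mV) {
  stopifnot(length(conc_mM) == length(voltage_mV), all(conc_mM > 0))
  if (length(unique(conc_mM)) < 2)
    stop("calibration needs at least 2 distinct concentrations")
  fit <- lm(voltage_mV ~ log10(conc_mM))
  res_sd <- if (length(conc_mM) > 2) sqrt(sum(fit$residuals^2) /
                                            (length(conc_mM) - 2)) else 0
  slope <- unname(coef(fit)[2])
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 residual_sd = res_sd, is_nernstian = slope > 50,
                 points = data.frame(conc_mM = conc_mM,
                                     voltage_mV = voltage_mV)),
            class = "kism_calibration")
}

#' @export
print.kism_calibration <- function(x, ...) {
  cat(sprintf(
    "K+-ISM calibration: %.2f mV/decade (intercept %.2f mV, resid SD %.2f mV) - %s\n",
    x$slope, x$intercept, x$residual_sd,
    if (x$is_nernstian) "Nernstian (> 50 mV/decade)" else
      "NOT Nernstian (<= 50 mV/decade)"))
  invisible(x)
}

#' Convert an ISM voltage trace to extracellular K+ concentration
#'
#' Subtracts the co-localized reference (field-potential) electrode trace
#' to remove the common-mode signal, then inverts the log-linear
#' calibration: `c(t) = 10^((V_ism - V_ref - intercept) / slope)`.
#'
#' @param ism_mV ISM voltage trace, mV.
#' @param reference_mV reference electrode trace, mV (same length), or
#'   `NULL` if already subtracted.
#' @param cal a [fit_calibration()] object.
#' @return \[K+\]e trace in mM (strictly positive).
#' @export
voltage_to_concentration <- function(ism_mV, reference_mV = NULL, cal) {
  stopifnot(inherits(cal, "kism_calibration"))
  if (abs(cal$slope) < 1) stop("calibration slope too close to zero")
  if (!cal$is_nernstian)
    warning("electrode is not Nernstian (slope <= 50 mV/decade)")
  v <- if (is.null(reference_mV)) ism_mV else {
    stopifnot(length(ism_mV) == length(reference_mV))
    ism_mV - reference_mV
  }
  10^((v - cal$intercept) / cal$slope)
}

#' Simulate ISM calibration points
#'
#' @param true_slope electrode slope, mV/decade.
#' @param intercept electrode offset at 1 mM, mV.
#' @param concentrations calibration concentrations, mM (default the
#'   standard 1, 2, 10, 20 mM KCl series).
#' @param noise_sd voltage noise SD, mV.
#' @param seed optional RNG seed.
#' @return Data frame `conc_mM`, `voltage_mV`.
#' @export
simulate_kism_calibration <- function(true_slope = theoretical_nernst_slope(295),
                                      intercept = 0,
                                      concentrations = c(1, 2, 10, 20),
                                      noise_sd = 0, seed = NULL) {
  stopifnot(length(concentrations) > 0, all(concentrations > 0),
            noise_sd >= 0)
  v <- true_slope * log10(concentrations) + intercept
  if (noise_sd > 0)
    v <- v + with_seed(seed, rnorm(length(v), 0, noise_sd))
  data.frame(conc_mM = concentrations, voltage_mV = v)
}
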