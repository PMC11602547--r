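#' Fit one- and two-Gaussian models to the conductance distribution
#'
#' Histograms the log10-transformed inward conductances on a fixed
#' log10 grid, fits one- and two-Gaussian curves to the bin counts by
#' Levenberg-Marquardt least squares, and compares the nested models
#' with the extra-sum-of-squares F-test and AIC.  This reproduces the
#' curve-fitting workflow used to establish the bimodality of the
#' conductance population; a likelihood-based EM fit is available as a
#' cross-check via [fit_conductance_mixture_em()].
#'
#' Three numerical safeguards keep the nested F-test calibrated (its
#' type-I error near the nominal level) on histogram counts: bins are
#' weighted by inverse counts (Poisson variance), component SDs are
#' bounded below by one bin width (a narrower component cannot be
#' resolved and would only absorb single-bin noise), and the two
#' component means must differ by at least two bin widths (the
#' two-Gaussian model is otherwise unidentifiable as it degenerates
#' into the single-Gaussian null).  See the package vignette.
#'
#' @param g_values inward conductances, nS; non-positive values are
#'   excluded (count reported).
#' @param binwidth histogram bin width on the log10 scale (default
#'   0.085, about 20 bins for a typical cortical cohort).
#' @param alpha significance level of the F-test used to prefer the
#'   two-Gaussian model.
#' @param weighted weight bins by inverse counts (default) or fit
#'   unweighted.
#' @return A `mixture_fit`: bin `mids`/`counts`, per-model parameters
#'   (`one`: mu, sigma, a; `two`: mu1, sigma1, a1, mu2, sigma2, a2 with
#'   mu1 < mu2), `r_squared` (unweighted, comparable to published
#'   curve-fit R2), `f_statistic`, `df`, `p_value`, `aic` (per model),
#'   `preferred` (`"one"`/`"two"`), `n`, `n_excluded`.
#' @export
fit_conductance_mixture <- function(g_values, binwidth = 0.085,
                                    alpha = 0.05, weighted = TRUE) {
  n_excluded <- sum(!(g_values > 0) | !is.finite(g_values))
  g <- g_values[g_values > 0 & is.finite(g_values)]
  if (length(g) < 30)
    warning("fewer than 30 cells; mixture comparison will be unstable")
  x <- log10(g)
  br <- seq(floor(min(x) / binwidth) * binwidth, max(x) + binwidth,
            by = binwidth)
  h <- graphics::hist(x, breaks = br, plot = FALSE)
  mids <- h$mids; counts <- h$counts
  nb <- length(mids)
  bw <- binwidth
  w <- if (weighted) 1 / pmax(counts, 1) else rep(1, nb)
  ctl <- minpack.lm::nls.lm.control(maxiter = 300)
  rng <- diff(range(mids))
  ss_tot <- sum((counts - mean(counts))^2)
  wrss <- function(fit) sum((counts - predict(fit))^2 * w)

  fit1 <- tryCatch(minpack.lm::nlsLM(
    counts ~ a * exp(-(mids - mu)^2 / (2 * s^2)),
    weights = w,
    start = list(mu = mean(x), s = sd(x), a = max(counts)),
    lower = c(min(mids), bw, 0), upper = c(max(mids), rng, Inf),
    control = ctl),
    error = function(e) NULL)

  # two Gaussians, parameterized as mu2 = mu1 + d with d >= 2 bins
  fit2_try <- function(split_q) {
    cut <- quantile(x, split_q)
    lo <- x[x <= cut]; hi <- x[x > cut]
    if (length(lo) < 3 || length(hi) < 3) return(NULL)
    tryCatch(minpack.lm::nlsLM(
      counts ~ a1 * exp(-(mids - mu1)^2 / (2 * s1^2)) +
        a2 * exp(-(mids - (mu1 + d))^2 / (2 * s2^2)),
      weights = w,
      start = list(mu1 = mean(lo), s1 = max(sd(lo), bw),
                   a1 = max(counts),
                   d = max(mean(hi) - mean(lo), 2.4 * bw),
                   s2 = max(sd(hi), bw), a2 = max(counts) / 2),
      lower = c(min(mids), bw, 0, 2 * bw, bw, 0),
      upper = c(max(mids), rng, Inf, rng, rng, Inf),
      control = ctl),
      error = function(e) NULL)
  }
  fits2 <- Filter(Negate(is.null), lapply(c(0.5, 0.35, 0.65), fit2_try))
  fit2 <- if (length(fits2))
    fits2[[which.min(vapply(fits2, wrss, 0))]] else NULL

  ls_aic <- function(rss, k) nb * log(rss / nb) + 2 * (k + 1)
  out <- list(data = x, mids = mids, counts = counts, n = length(g),
              n_excluded = n_excluded, alpha = alpha, binwidth = binwidth)
  if (is.null(fit1)) stop("single-Gaussian fit failed")
  p1 <- as.list(coef(fit1)); names(p1) <- c("mu", "sigma", "a")
  rss1 <- sum((counts - predict(fit1))^2)
  rss1w <- wrss(fit1)
  out$one <- p1
  out$r_squared <- c(one = 1 - rss1 / ss_tot)
  out$aic <- c(one = ls_aic(rss1w, 3))

  if (!is.null(fit2) && nb > 6) {
    cf <- coef(fit2)
    p2 <- list(mu1 = cf[["mu1"]], sigma1 = cf[["s1"]], a1 = cf[["a1"]],
               mu2 = cf[["mu1"]] + cf[["d"]], sigma2 = cf[["s2"]],
               a2 = cf[["a2"]])
    rss2 <- sum((counts - predict(fit2))^2)
    rss2w <- wrss(fit2)
    df2 <- nb - 6
    f_stat <- max(0, ((rss1w - rss2w) / 3) / (rss2w / df2))
    out$two <- p2
    out$r_squared <- c(out$r_squared, two = 1 - rss2 / ss_tot)
    out$aic <- c(out$aic, two = ls_aic(rss2w, 6))
    out$f_statistic <- f_stat
    out$df <- c(3, df2)
    out$p_value <- pf(f_stat, 3, df2, lower.tail = FALSE)
    out$preferred <- if (out$p_value < alpha) "two" else "one"
  } else {
    out$f_statistic <- NA_real_
    out$p_value <- NA_real_
    out$preferred <- "one"
  }
  structure(out, class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("Conductance mixture fit on", x$n, "cells (",
      length(x$mids), "bins )\n")
  cat(sprintf("  one Gaussian: mu=%.3f sigma=%.3f R2=%.3f AIC=%.1f\n",
              x$one$mu, x$one$sigma, x$r_squared[["one"]],
              x$aic[["one"]]))
  if (!is.null(x$two))
    cat(sprintf(
      "  two Gaussians: mu1=%.3f s1=%.3f mu2=%.3f s2=%.3f R2=%.3f AIC=%.1f\n",
      x$two$mu1, x$two$sigma1, x$two$mu2, x$two$sigma2,
      x$r_squared[["two"]], x$aic[["two"]]))
  cat(sprintf("  extra-sum-of-squares F=%.2f, p=%.3g -> preferred: %s\n",
              x$f_statistic, x$p_value, x$preferred))
  invisible(x)
}

#' State boundary from a two-Gaussian mixture fit
#'
#' The conductance dividing the low- and high-state populations: the
#' configured percentile (default 90th) of the low component,
#' `10^(mu1 + z_p sigma1)`.  The symmetric value from the high
#' component, `10^(mu2 - z_p sigma2)`, is computed alongside and the
#' discrepancy reported, since the two readings coincide only when the
#' components are symmetric about the boundary.
#'
#' @param fit a [fit_conductance_mixture()] result with the two-Gaussian
#'   model preferred.
#' @param percentile percentile of the low component (default 0.90).
#' @return Threshold in nS, with attributes `alternative` (high
#'   component reading, nS) and `discrepancy` (nS).
#' @export
state_threshold <- function(fit, percentile = 0.90) {
  stopifnot(inherits(fit, "mixture_fit"))
  if (is.null(fit$two) || fit$preferred != "two")
    stop("two-Gaussian model not preferred; no state boundary defined")
  z <- qnorm(percentile)
  thr <- 10^(fit$two$mu1 + z * fit$two$sigma1)
  alt <- 10^(fit$two$mu2 - z * fit$two$sigma2)
  structure(thr, alternative = alt, discrepancy = alt - thr)
}

#' EM cross-check of the conductance mixture
#'
#' Gaussian-mixture fit of the log10 conductances by maximum likelihood
#' (EM, via \pkg{mclust}), used as an independent cross-check of the
#' histogram least-squares procedure, not as the primary analysis.
#'
#' @param g_values inward conductances, nS.
#' @return List with `mu`, `sigma`, `weights`, `bic_preferred`
#'   (components selected by BIC among 1-2).
#' @export
fit_conductance_mixture_em <- function(g_values) {
  if (!requireNamespace("mclust", quietly = TRUE))
    stop("the EM cross-check needs the mclust package")
  mclustBIC <- mclust::mclustBIC   # Mclust() resolves this in the caller
  x <- log10(g_values[g_values > 0])
  m <- mclust::Mclust(x, G = 1:2, modelNames = "V", verbose = FALSE)
  list(mu = m$parameters$mean,
       sigma = sqrt(m$parameters$variance$sigmasq),
       weights = m$parameters$pro, bic_preferred = m$G)
}

#' Classify cells into conductance states
#'
#' @param cohort data frame with a `g_in` column (nS).
#' @param threshold state boundary, nS.
#' @return The cohort with a `state` column (`"high"` iff
#'   `g_in > threshold`) and, as attribute `proportions`, the share of
#'   high-state cells by `region` and `age_days` when present.
#' @export
classify_cells <- function(cohort, threshold) {
  stopifnot(threshold > 0, "g_in" %in% names(cohort))
  cohort$state <- ifelse(cohort$g_in > threshold, "high", "low")
  keys <- intersect(c("region", "age_days"), names(cohort))
  if (length(keys)) {
    prop <- aggregate(cohort$state == "high", cohort[keys], mean)
    names(prop)[ncol(prop)] <- "prop_high"
    attr(cohort, "proportions") <- prop
  }
  cohort
}

#' Neuronal-density class of an OPC territory
#'
#' A territory is high-density when more than 5 NeuN+ somata lie within
#' the territory circle.  Either a pre-counted `neun_count` or raw
#' soma coordinates plus the circle geometry may be supplied; counting
#' is boundary-inclusive, with coordinates in um relative to the soma.
#'
#' @param neun_count NeuN+ count within the territory.
#' @param points optional 2-column matrix of soma coordinates (um).
#' @param center circle centre (um), default the origin (the soma).
#' @param diameter_um circle diameter, um (default 80, the measured mean
#'   OPC territory).
#' @return List with `count` and `class` (`"high"`/`"low"`).
#' @export
territory_density <- function(neun_count = NULL, points = NULL,
                              center = c(0, 0), diameter_um = 80) {
  stopifnot(diameter_um > 0)
  if (is.null(neun_count)) {
    stopifnot(!is.null(points))
    points <- as.matrix(points)
    d2 <- (points[, 1] - center[1])^2 + (points[, 2] - center[2])^2
    neun_count <- sum(d2 <= (diameter_um / 2)^2)
  }
  stopifnot(neun_count >= 0)
  list(count = as.integer(neun_count),
       class = if (neun_count > 5) "high" else "low")
}

#' Per-group summaries and comparisons of a cohort table
#'
#' Mean +/- SEM of the passive properties per group, proliferation
#' fraction where a marker column exists, and standard two-group
#' (Welch t-test) or multi-group (one-way ANOVA with Holm-corrected
#' pairwise t-tests) comparisons of each measure.
#'
#' @param cohort cohort data frame.
#' @param by name of the grouping column.
#' @param measures numeric columns to summarise (defaults to the
#'   intersection with `rmp`, `rm`, `g_in`).
#' @param marker optional logical column of proliferation-marker
#'   positivity (EdU/Ki67).
#' @return List with `summary` (data frame) and `tests` (data frame of
#'   p-values per measure).
#' @export
group_summaries <- function(cohort, by,
                            measures = intersect(c("rmp", "rm", "g_in"),
                                                 names(cohort)),
                            marker = NULL) {
  stopifnot(by %in% names(cohort), length(measures) > 0)
  g <- factor(cohort[[by]])
  if (any(table(g) == 0) || nlevels(g) == 0) stop("empty group")
  sem <- function(v) sd(v, na.rm = TRUE) / sqrt(sum(is.finite(v)))
  rows <- lapply(levels(g), function(lev) {
    sub <- cohort[g == lev, , drop = FALSE]
    r <- data.frame(group = lev, n = nrow(sub), stringsAsFactors = FALSE)
    for (m in measures) {
      r[[paste0(m, "_mean")]] <- mean(sub[[m]], na.rm = TRUE)
      r[[paste0(m, "_sem")]] <- sem(sub[[m]])
    }
    if (!is.null(marker))
      r$prolif_fraction <- mean(sub[[marker]], na.rm = TRUE)
    r
  })
  tests <- if (nlevels(g) < 2) list() else lapply(measures, function(m) {
    p <- if (nlevels(g) == 2) {
      t.test(cohort[[m]] ~ g)$p.value          # Welch by default
    } else {
      summary(aov(cohort[[m]] ~ g))[[1]][["Pr(>F)"]][1]
    }
    data.frame(measure = m,
               test = if (nlevels(g) == 2) "Welch t" else "one-way ANOVA",
               p_value = p, stringsAsFactors = FALSE)
  })
  posthoc <- NULL
  if (nlevels(g) > 2)
    posthoc <- lapply(setNames(measures, measures), function(m)
      pairwise.t.test(cohort[[m]], g, p.adjust.method = "holm")$p.value)
  list(summary = do.call(rbind, rows), tests = do.call(rbind, tests),
       posthoc = posthoc)
}
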