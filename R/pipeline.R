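#' Write a sweep bundle to a directory
#'
#' One directory per cell: a `manifest.yaml` holding the protocol,
#' metadata and (for simulated data) ground truth, plus one two-column
#' tab-separated table per sweep (`time_s`, `current_pA`).
#'
#' @param bundle a `sweep_bundle`.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_sweep_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  p <- bundle$protocol
  truth <- bundle$ground_truth
  man <- list(format = "opcephys-sweep-bundle-v1",
              protocol = list(v_hold = p$v_hold, t_start = p$t_start,
                              t_end = p$t_end, potentials = p$potentials,
                              duration = p$duration, fs = p$fs),
              metadata = bundle$metadata,
              n_sweeps = ncol(bundle$sweeps))
  if (!is.null(truth))
    man$ground_truth <- list(params = unclass(truth$params),
                             noise_rms = truth$noise_rms)
  yaml::write_yaml(man, file.path(path, "manifest.yaml"))
  for (j in seq_len(ncol(bundle$sweeps)))
    write.table(data.frame(time_s = bundle$time,
                           current_pA = bundle$sweeps[, j]),
                file.path(path, sprintf("sweep_%02d.tsv", j)),
                sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sweep bundle from a directory
#'
#' @param path directory written by [write_sweep_bundle()].
#' @return A `sweep_bundle`.
#' @export
read_sweep_bundle <- function(path) {
  man <- yaml::read_yaml(file.path(path, "manifest.yaml"))
  pr <- man$protocol
  protocol <- step_protocol(v_hold = pr$v_hold, t_start = pr$t_start,
                            t_end = pr$t_end,
                            potentials = unlist(pr$potentials),
                            duration = pr$duration, fs = pr$fs)
  files <- sprintf("sweep_%02d.tsv", seq_len(man$n_sweeps))
  sweeps <- vapply(files, function(f)
    read.delim(file.path(path, f))$current_pA,
    numeric(round(pr$duration * pr$fs / 1000)))
  colnames(sweeps) <- sub(".tsv", "", files, fixed = TRUE)
  truth <- NULL
  if (!is.null(man$ground_truth)) {
    gp <- man$ground_truth$params
    truth <- list(params = do.call(membrane_params, c(
      list(rs = gp$rs, cm = gp$cm, g_leak = gp$g_leak,
           e_leak = gp$e_leak, g_kir = gp$g_kir,
           v_half_kir = gp$v_half_kir, k_kir = gp$k_kir,
           g_out = gp$g_out, v_half_out = gp$v_half_out,
           k_out = gp$k_out, e_k = gp$e_k))),
      noise_rms = man$ground_truth$noise_rms)
  }
  structure(list(time = protocol_times(protocol), sweeps = sweeps,
                 protocol = protocol, metadata = man$metadata,
                 ground_truth = truth),
            class = "sweep_bundle")
}

#' Validate a sweep-bundle directory
#'
#' Checks the manifest, sweep files, lengths and sampling consistency
#' without mutating anything.
#'
#' @param path bundle directory.
#' @return List with `valid` (logical) and `issues` (character vector,
#'   each naming the offending file or field).
#' @export
validate_bundle <- function(path) {
  issues <- character(0)
  note <- function(...) issues <<- c(issues, sprintf(...))
  if (!dir.exists(path)) {
    return(list(valid = FALSE, issues = sprintf("missing directory %s", path)))
  }
  mf <- file.path(path, "manifest.yaml")
  if (!file.exists(mf)) {
    return(list(valid = FALSE, issues = sprintf("missing manifest %s", mf)))
  }
  man <- tryCatch(yaml::read_yaml(mf), error = function(e) NULL)
  if (is.null(man)) return(list(valid = FALSE,
                                issues = sprintf("unreadable manifest %s", mf)))
  pr <- man$protocol
  for (f in c("v_hold", "t_start", "t_end", "potentials", "duration", "fs"))
    if (is.null(pr[[f]])) note("manifest missing protocol field %s", f)
  if (!is.null(pr$fs) && pr$fs <= 0) note("non-positive sampling rate")
  if (!is.null(pr$potentials) && any(diff(unlist(pr$potentials)) <= 0))
    note("step potentials not strictly increasing")
  n_expect <- if (!is.null(pr$duration) && !is.null(pr$fs))
    round(pr$duration * pr$fs / 1000) else NA
  for (j in seq_len(man$n_sweeps %||% 0)) {
    f <- file.path(path, sprintf("sweep_%02d.tsv", j))
    if (!file.exists(f)) { note("missing sweep file %s (sweep %d)", f, j); next }
    d <- tryCatch(read.delim(f), error = function(e) NULL)
    if (is.null(d) || !all(c("time_s", "current_pA") %in% names(d))) {
      note("unreadable or malformed sweep file %s (sweep %d)", f, j); next
    }
    if (!is.na(n_expect) && nrow(d) != n_expect)
      note("truncated sweep file %s (sweep %d): %d of %d samples",
           f, j, nrow(d), n_expect)
    if (nrow(d) > 1) {
      dt <- diff(d$time_s[1:2])
      if (!is.null(pr$fs) && abs(dt - 1 / pr$fs) > 1e-9)
        note("sampling rate mismatch in %s (sweep %d)", f, j)
    }
  }
  list(valid = length(issues) == 0, issues = issues)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configuration of a full pipeline run
#'
#' @param seed master seed; every stochastic stage derives its stream
#'   from it.
#' @param out_dir output directory.
#' @param population a [population_spec()].
#' @param protocol a [step_protocol()].
#' @param n_sessions number of SLIC co-recording sessions to simulate.
#' @param session_duration_s session length, s.
#' @param scenario an [activity_scenario()].
#' @param detector [detector_params()].
#' @param qc [qc_criteria()].
#' @param percentile mixture state-boundary percentile.
#' @param temperature_K,k_in,bath_k temperature (K) and pipette/bath K+
#'   (mM) for Nernst calculations.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("opcephys_run_"),
                       population = population_spec(),
                       protocol = step_protocol(),
                       n_sessions = 5, session_duration_s = 120,
                       scenario = activity_scenario(),
                       detector = detector_params(),
                       qc = qc_criteria(), percentile = 0.90,
                       temperature_K = 295, k_in = 132, bath_k = 2.5) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the simulate - analyze - classify - report pipeline
#'
#' Executes the stages in order on a simulated cohort: sweep simulation,
#' per-cell passive-property extraction, QC, mixture fit and state
#' classification, SLIC-session simulation and event detection with
#' ISM conversion and amplitude regressions, and per-state summaries.
#' All tables are written as tab-separated text under the configured
#' output directory and a manifest records the config, versions, output
#' checksums and timing.  Deterministic under the config seed.
#'
#' @param config a [run_config()].
#' @return A `run_manifest` (list), invisibly also written as
#'   `manifest.yaml`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stages <- character(0)
  manifest <- list(software = paste("opcephys",
                                    as.character(packageVersion("opcephys"))),
                   seed = config$seed, outputs = list(),
                   warnings = character(0))
  tsv <- function(df, name) {
    f <- file.path(config$out_dir, name)
    write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
    manifest$outputs[[name]] <<- unname(tools::md5sum(f))
    f
  }
  e_k <- nernst_potential(config$bath_k, config$k_in, config$temperature_K)
  result <- tryCatch({
    # stage 1: simulate cohort
    pop <- simulate_population(config$population, seed = config$seed,
                               sweeps = TRUE, protocol = config$protocol)
    stages <- c(stages, "simulate")
    # stage 2: trace analysis
    props <- do.call(rbind, lapply(pop$bundles, passive_properties,
                                   e_k = e_k))
    props <- cbind(cell_id = pop$truth$cell_id, props)
    qc <- lapply(seq_len(nrow(props)),
                 function(i) apply_qc(props[i, ], config$qc))
    props$qc_pass <- vapply(qc, `[[`, TRUE, "pass")
    props$qc_reasons <- vapply(qc, function(x)
      paste(x$reasons, collapse = "; "), "")
    tsv(props, "passive_properties.tsv")
    if (any(!props$qc_pass))
      manifest$warnings <- c(manifest$warnings,
                             sprintf("%d cells excluded by QC",
                                     sum(!props$qc_pass)))
    stages <- c(stages, "analyze-traces")
    # stage 3: mixture + classification
    ok <- props$qc_pass & is.finite(props$g_in) & props$g_in > 0
    cohort <- props[ok, c("cell_id", "rmp", "rm", "cm", "rs", "g_in")]
    cohort$region <- pop$truth$region[ok]
    cohort$age_days <- pop$truth$age_days[ok]
    mix <- NULL; thr <- NA_real_
    if (sum(ok) >= 30) {
      mix <- fit_conductance_mixture(cohort$g_in)
      if (mix$preferred == "two")
        thr <- as.numeric(state_threshold(mix, config$percentile))
    }
    if (is.finite(thr)) {
      cohort <- classify_cells(cohort, thr)
    } else cohort$state <- rep(NA_character_, nrow(cohort))
    tsv(cohort, "cohort.tsv")
    manifest$mixture <- if (!is.null(mix))
      list(preferred = mix$preferred, p_value = mix$p_value,
           threshold_nS = thr) else list(preferred = NA)
    stages <- c(stages, "classify-population")
    # stage 4: SLIC sessions
    events_all <- list()
    session_cells <- list()
    for (s in seq_len(config$n_sessions)) {
      ses <- simulate_slic_session(scenario = config$scenario,
                                   duration_s = config$session_duration_s,
                                   seed = config$seed * 1000 + s)
      ev <- detect_events(ses$current, attr(ses, "fs"), config$detector)
      ev <- ev[ev$class == "SLIC", , drop = FALSE]
      cal <- attr(ses, "cal")
      calib <- fit_calibration(c(1, 2, 10, 20),
                               cal$slope * log10(c(1, 2, 10, 20)) +
                                 cal$intercept)
      k_e <- voltage_to_concentration(ses$ism, ses$fp, calib)
      ev$k_peak <- vapply(ev$peak_time, function(tt) {
        win <- which(abs(ses$time - tt) <= 0.5)
        max(k_e[win])
      }, 0)
      ev$cell_id <- rep(sprintf("session_%02d", s), nrow(ev))
      events_all[[s]] <- ev
      session_cells[[s]] <- data.frame(
        cell_id = sprintf("session_%02d", s),
        rm = attr(ses, "truth")$rm_eff,
        g_in = 1000 / attr(ses, "truth")$rm_eff)
    }
    events <- do.call(rbind, events_all)
    tsv(events, "slic_events.tsv")
    cells_df <- do.call(rbind, session_cells)
    regressions <- NULL
    if (!is.null(events) && nrow(events) >= 3 &&
        length(unique(events$cell_id)) >= 3) {
      regressions <- tryCatch(
        amplitude_regressions(events, cells_df), error = function(e) NULL)
      if (!is.null(regressions)) tsv(regressions, "amplitude_regressions.tsv")
    }
    stages <- c(stages, "detect-slics")
    # stage 5: summaries
    if (is.finite(thr) && any(!is.na(cohort$state))) {
      summ <- group_summaries(cohort, "state")
      tsv(summ$summary, "state_summaries.tsv")
    }
    stages <- c(stages, "report")
    list(population = pop, properties = props, cohort = cohort,
         mixture = mix, threshold = thr, events = events,
         session_cells = cells_df, regressions = regressions)
  }, error = function(e) {
    manifest$failed_stage <<- setdiff(
      c("simulate", "analyze-traces", "classify-population",
        "detect-slics", "report"), stages)[1]
    manifest$error <<- conditionMessage(e)
    NULL
  })
  manifest$stages_completed <- stages
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$config <- list(seed = config$seed,
                          n_cells = config$population$n,
                          n_sessions = config$n_sessions,
                          percentile = config$percentile,
                          temperature_K = config$temperature_K)
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  out <- structure(list(manifest = manifest, result = result,
                        out_dir = config$out_dir),
                   class = "run_manifest")
  invisible(out)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("Pipeline run:", x$out_dir, "\n  stages:",
      paste(x$manifest$stages_completed, collapse = ", "), "\n")
  if (!is.null(x$manifest$error))
    cat("  FAILED at", x$manifest$failed_stage, ":", x$manifest$error, "\n")
  invisible(x)
}
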