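# opcephys

Passive membrane properties and potassium-driven currents in glial
voltage-clamp recordings.

Oligodendrocyte precursor cells (OPCs) — the main proliferative cells of
the adult brain — change their passive bioelectrical phenotype as they
mature: an inwardly rectifying K⁺ conductance (Kir4.1/Kir2.1) grows,
membrane resistance falls, and the resting potential approaches the K⁺
equilibrium potential.  The population splits into low- and
high-conductance states, and high-conductance cells respond to
synchronized neuronal activity with spontaneous long inward currents
(SLICs) driven by transient rises in extracellular K⁺.  `opcephys`
implements the quantitative pipeline for this kind of data:

* **Trace analysis** — series resistance, capacitance and input
  resistance from the capacitive transient; steady-state I/V curves;
  resting potential; the inward conductance *g*ᵢₙ as the slope of the
  I/V between the most hyperpolarized potential and *E*ₖ; inclusion
  criteria (|leak| < 500 pA, Rs bounds).
* **State classification** — one- vs two-Gaussian least-squares fits to
  the histogram of log₁₀ *g*ᵢₙ, compared by extra-sum-of-squares F-test
  and AIC; the state boundary is the low component's 90th percentile
  (≈ 2.35 nS in the emulated cortical cohort).
* **SLIC analysis** — detection (20 Hz low-pass, rolling-median
  baseline, 4×MAD threshold, duration-based classification), pairing
  with field-potential events, pharmacological block quantification,
  and the Nernst prediction ΔI = (1/Rm)·(RT/F)·ln([K⁺]′ₑ/[K⁺]ₑ).
* **K⁺-selective microelectrodes** — log-linear calibration (Nernstian
  if > 50 mV/decade; ideal slope ln(10)·RT/F = 59.16 mV/decade at
  298.15 K), reference subtraction, voltage→[K⁺]ₑ conversion, and
  Henderson liquid junction potentials from solution compositions.
* **A biophysical simulator** — RC + Kir membrane model integrated by
  exponential Euler at 20 µs, cohort and co-recording-session
  generators with known ground truth, used throughout the test suite.

## Worked example

```r
library(opcephys)

# a cortical-like cohort of 264 cells with known ground truth
pop   <- simulate_population(population_spec(n = 264), seed = 42)
props <- do.call(rbind, lapply(pop$bundles, passive_properties))
ok    <- vapply(seq_len(nrow(props)),
                function(i) apply_qc(props[i, ])$pass, TRUE)

fit <- fit_conductance_mixture(props$g_in[ok])
fit
#> Conductance mixture fit on 264 cells ( 20 bins )
#>   one Gaussian: mu=0.421 sigma=0.322 R2=0.747 AIC=13.1
#>   two Gaussians: mu1=0.151 s1=0.213 mu2=0.647 s2=0.196 R2=0.878 AIC=6.5
#>   extra-sum-of-squares F=4.10, p=0.0278 -> preferred: two

thr <- state_threshold(fit)
sprintf("boundary %.2f nS (symmetric reading %.2f nS)",
        thr, attr(thr, "alternative"))
#> "boundary 2.65 nS (symmetric reading 2.49 nS)"

ses <- simulate_slic_session(seed = 42)
ev  <- detect_events(ses$current, attr(ses, "fs"))
subset(ev, class == "SLIC")   # 12 events: rate 0.100 Hz, mean 39.3 pA
predicted_delta_I(178, 2.5, 3.0)
#> [1] 25.96  # pA for a 2.5 -> 3.0 mM K+ rise at Rm = 178 MOhm
```

The fitted two-Gaussian mixture recovers the generator's components
(true μ₁ = 0.140, μ₂ = 0.680 log₁₀ nS), the boundary estimate scatters
around the generator's analytic 2.35 nS anchor with ~10% per-cohort
spread, and the detected SLIC rate and amplitude sit at the simulated
0.09 Hz / ≈ 35 pA operating point.

A pipeline front end (`run_pipeline()`, plus the thin CLI at
`inst/cli/opcephys.R` with `simulate / analyze-traces / calibrate-kism /
detect-slics / classify-population / report / validate` subcommands)
chains the stages, writes tab-separated tables and records a manifest;
runs are byte-reproducible under a seed.

See `vignettes/opcephys-methods.Rmd` for the membrane model, the
detector design, the mixture-test calibration and every default worth
questioning.

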