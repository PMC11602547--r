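---
title: "Models and methods behind opcephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind opcephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opcephys)
```

`opcephys` analyses whole-cell voltage-clamp recordings of
oligodendrocyte precursor cells (OPCs) and similar glia, whose
electrophysiological signature is a passive, inwardly-rectifying K⁺
conductance (Kir4.1/Kir2.1 family).  This vignette explains the models
the package implements, the parameters that matter, and the design
choices made where the underlying experimental literature leaves the
procedure open.  Nothing here states an empirical result that the test
suite does not itself compute.

## The membrane model

All simulated data come from a single-compartment cell seen through a
patch pipette:

$$C_m \frac{dV_m}{dt} = \frac{V_{cmd} - V_m}{R_s} - I_m(V_m), \qquad
I_{rec} = \frac{V_{cmd} - V_m}{R_s},$$

with membrane current

$$I_m(V) = g_{leak}(V - E_{leak})
  + g_{kir}\, f_{kir}(V)\,(V - E_K)
  + g_{out}\, f_{out}(V)\,(V - E_K),$$

where $f_{kir}(V) = 1/(1 + \exp((V - E_K - V_{1/2}) / k))$ is a falling
Boltzmann of the driving potential (hyperpolarization opens the
channel) and $f_{out}$ a rising Boltzmann for the delayed-rectifier
component present in immature cells.  Units are mV, ms, pF, nS and pA
throughout, which makes $C_m/g$ a time constant in ms directly.

**Rectification defaults.**  Mature OPC-like cells pass nearly ohmic K⁺
currents over the tested voltage range, so the default gate
($V_{1/2} = +250$ mV relative to $E_K$, $k = 50$ mV) is open (> 0.99)
across the whole protocol.  This choice makes the identity "inward-limb
slope = $g_{leak} + g_{kir}$" hold to better than 2%, which the test
suite verifies; a gate centred at $E_K$ would scale the slope by about
0.85 and break that identity.  Steep rectification, used to test that
the inward limb can exceed the outward limb, is obtained with e.g.
$V_{1/2} = 15$ mV, $k = 8$ mV.

**Integration.**  The integrator (compiled code) uses exponential-Euler
updates at the 20 µs sampling interval with gating frozen per step.
For the linear sub-problem this update is *exact*, so a pure RC cell
reproduces the closed-form step response
$I(t) = \Delta V/(R_s + R_m) + (\Delta V/R_s - \Delta V/(R_s+R_m))
e^{-t/\tau}$ to better than $10^{-6}$ relative error, and the scheme is
unconditionally stable for this stiff, linear-dominated system.
Non-finite membrane potentials abort with an error rather than
producing silent NaNs.

## Passive-property extraction

The per-cell pipeline mirrors standard practice:

1. **Capacitive transient.**  A single exponential is fitted to the
   decay after the test step (log-linear initialisation, then
   Levenberg–Marquardt).  Back-extrapolation of the fit to step onset
   gives the peak current, hence $R_s = \Delta V / (I_{peak} -
   I_{base})$, $R_{input} = \Delta V/(I_{ss} - I_{base}) - R_s$ and
   $C_m = \tau (R_s + R_{input})/(R_s R_{input})$.  Back-extrapolation
   makes the estimate independent of whether the first sample catches
   the true peak.  The fit is performed on the step closest to 20 mV
   hyperpolarizing, where the response is most nearly linear.
2. **Steady-state I/V.**  Mean current over the last 50 ms of each step
   (the step is 200 ms; 50 ms is far beyond the time constant of any
   plausible cell, which is below 2 ms for these parameters).
3. **Resting potential** by linear interpolation of the zero-current
   crossing of the I/V; an I/V without a sign change yields `NA` plus a
   QC flag.  When a current-clamp baseline exists it should take
   precedence; the I/V route is used because step protocols are always
   available.
4. **Inward conductance** $g_{in}$: least-squares slope of the I/V
   between the most hyperpolarized tested potential and $E_K$.  With
   2.5 mM bath and 132 mM pipette K⁺ at 295 K, $E_K \approx -100.8$ mV,
   so a 20 mV protocol samples only two potentials below $E_K$; the
   window is therefore extended upward to the next sampled potential
   until three points are available, and the window used is recorded.
   This matches the practice of fitting "the linear part" of the inward
   limb.  $E_K$ is always computed from solution composition via the
   Nernst equation, never hard-coded.
5. **Quality control**: cells fail on |leak| ≥ 500 pA, series
   resistance outside 2–60 MΩ, or an unstable baseline; failure reasons
   are enumerated rather than collapsed into a boolean.

Junction potential: simulated recordings are generated in corrected
coordinates; the `junction_corrected` metadata flag triggers a −14 mV
correction for recordings that were not compensated at acquisition.

## Liquid junction potentials and K⁺-selective microelectrodes

`junction_potential()` implements the Henderson equation with a shipped
table of limiting equivalent conductivities.  Conventions follow
standard junction-potential calculators: HEPES is 50% anionic at
pH 7.3, BAPTA tetra-anionic, MgATP a divalent anionic complex, and
large organic anions without tabulated mobilities (BAPTA, nucleotides,
Lucifer yellow) take gluconate-like values.  The builder for the
printed pipette solution enters the recipe *as printed* (K⁺ = 132 mM);
ions introduced by pH titration are not reconstructed, because
published junction values are invariably computed that way.  An
electroneutral variant (adding the KOH-derived K⁺) is available and
shifts the result by about −3.6 mV — that sensitivity, not a hidden
constant, is why the builder exposes the choice.  The implementation is
checked against the Lewis–Sargent closed form on binary junctions and
for antisymmetry under solution exchange.

Electrode calibration is an unweighted least-squares fit of
$V = s \log_{10} c + b$ on the standard 1/2/10/20 mM KCl series; an
electrode is *Nernstian* when $s > 50$ mV/decade (the ideal slope is
$\ln(10) RT/F$: 59.16 mV/decade at 298.15 K).  Conversion of a
recorded ISM trace to \[K⁺\]ₑ subtracts the co-localized reference
(field-potential) electrode first — the simulator deliberately injects
the FP signal into the ISM channel as common mode so that this
subtraction is exercised — then inverts the calibration.  The round
trip is exact to $10^{-6}$ at zero noise.

## SLIC detection and the Nernst ΔI model

Spontaneous long inward currents (SLICs) are slow (hundreds of ms),
small (tens of pA) inward deflections of the holding current driven by
activity-evoked rises in extracellular K⁺.  No published detection
algorithm exists for them, so the detector is designed from their
time scale: zero-phase low-pass at 20 Hz, rolling-median baseline
(10 s window), threshold at 4 robust (MAD-scaled) SDs below baseline,
merging of sub-threshold gaps shorter than 200 ms, and classification
by duration at half amplitude — ≥ 200 ms is a SLIC, shorter events are
synaptic-like.  Onsets are found by walking back from the peak to 10%
of the deflection, so they do not inherit the latency of a threshold
crossing.  Amplitudes are baseline-to-peak on the filtered trace
(primary) with the raw-trace value reported alongside, since published
amplitudes do not state which convention was used.

The predicted deflection for a K⁺ step $[K^+]_e \to [K^+]_e'$ at fixed
holding potential is

$$\Delta I = \frac{1}{R_m}\frac{RT}{F}\ln\frac{[K^+]_e'}{[K^+]_e},$$

i.e. the shift of $E_K$ divided by the membrane resistance; the holding
potential cancels.  Two properties of this formula are tested: it is
algebraically identical to $(E_K' - E_K)/R_m$, and full-model simulated
amplitudes converge to it within 1% for cells whose membrane
conductance is entirely K⁺-selective and whose series resistance is
negligible.  Both qualifications are physical, not numerical: a non-K⁺
leak does not respond to $E_K$ shifts, and series resistance attenuates
measured deflections by $1/(1 + g R_s/1000)$ — about 17% for a 6 nS
cell at 32 MΩ.  The package treats these as facts about the
measurement, not errors to be calibrated away.

## The synthetic-data generator

The generator produces what the analysis consumes, with ground truth:

* **Step-protocol sweeps** under the default protocol (−134 to +26 mV
  in 20 mV steps from −74 mV, 50 kHz, 200 ms steps) with Gaussian
  current noise (default 5 pA RMS).
* **Populations**: per-cell $g_{in}$ from a two-component log-normal
  mixture.  The low component is anchored so that its 90th percentile
  is 2.35 nS — the published boundary between low- and high-conductance
  states — with $\sigma_1 = 0.18$ log₁₀ nS, giving $\mu_1 = 0.140$
  (median 1.38 nS); the high component sits 3 SD higher
  ($\mu_2 = 0.680$, median 4.79 nS, $\sigma_2 = 0.18$), equal weights.
  Membrane parameters are derived so that the *measured* inward-limb
  slope — including series-resistance attenuation — equals the drawn
  conductance; draws too large to clamp through the drawn $R_s$ are
  rejected and redrawn with the count reported.  Capacitance follows
  the density phenotypes (means 26 vs 42.1 pF), access resistance is
  log-normal around 32 MΩ.  Cell-cycle labels (G1/G0 more likely at
  high conductance), proliferation markers (less likely at high
  conductance) and territory NeuN counts (Poisson, means 3 vs 9 within
  the 80 µm mean territory) are drawn from logistic/Poisson conditional
  models.
* **Co-recording sessions**: K⁺ transients as difference-of-exponential
  waveforms (cortical 50 ms/500 ms, hippocampal 500 ms/5 s — chosen to
  reproduce the fast-vs-sustained contrast; the literature reports no
  numerical kinetics, so these are tunable assumptions), Poisson event
  times at 0.09 Hz, peak amplitudes spanning 0.14–1.32 mM on a 2.5 mM
  baseline.  The default session cell (≈ 6.6 nS, 42 pF) makes the mean
  detected amplitude land near 35 pA.  FP deflections precede the
  K⁺-event peaks by 20 ms (the observed ordering is "slightly
  preceded", unquantified).  The ISM channel is the forward calibration
  of \[K⁺\]ₑ(t) plus the FP common mode.
* **Regression cohorts** (`simulate_regression_cohort()`): one cell per
  session with $R_m$ log-uniform over 50–1000 MΩ, three SLICs each.
  The ISM sits 30–180 µm from the recorded cell, so the *measured*
  Δ\[K⁺\] is decoupled from the transient at the cell
  (`spatial_coherence = 0` by default; fully coupled at 1).  This is
  the feature of real co-recordings that produces a strong
  amplitude–$R_m$ relation and no amplitude–\[K⁺\]ₑ relation; with
  coherence 1 the amplitude–\[K⁺\]ₑ regression becomes significant,
  which is worth knowing when interpreting the corresponding test.

What the generator does *not* emulate: spatial K⁺ diffusion,
conductance-based network activity (FP and synaptic events are
phenomenological), electrode drift, and cell-to-cell variation in
rectification shape.  Tests passing on this generator therefore
validate the estimators against the stated model class, not against
every property of real recordings.

## The conductance-state mixture

The state classification fits one and two Gaussians to the histogram of
log₁₀ conductance by least squares and compares them with the
extra-sum-of-squares F-test and AIC — the workflow of standard
curve-fitting software, kept as the primary procedure deliberately; a
maximum-likelihood EM fit (`fit_conductance_mixture_em()`, via mclust)
serves as an independent cross-check.  Three numerical choices keep the
F-test honest, all verified by simulation in the test suite:

* **Bin width 0.085 log₁₀ nS** (≈ 20 bins at n = 264).  Automatic rules
  (Freedman–Diaconis) give ~9 bins here, leaving the six-parameter
  model only 3 residual degrees of freedom and destroying power.
* **Poisson bin weights** $1/\max(c_i, 1)$.  Unweighted fits let the
  flexible two-Gaussian model chase tall-bin noise; the observed type-I
  error of the F-test then exceeds 15%.  Whether the original analyses
  weighted bins is unknowable; weighting is the choice that makes the
  published test calibrated.
* **Identifiability bounds**: component SDs at least one bin width and
  means separated by at least two bin widths, since the two-Gaussian
  model otherwise degenerates into the null (one component collapsing
  onto a single bin, or the two components coinciding), which is what
  inflates naive nested tests.

With these settings the measured type-I error at n = 264 is ≈ 0.05 and
the power at the default component separation ≈ 0.96 (both recomputed
by the acceptance tests at 500 and 200 replicates).

The state boundary is the low component's 90th percentile,
$10^{\mu_1 + z_{0.9}\sigma_1}$, with the high component's symmetric
10th-percentile reading computed alongside and the discrepancy
reported: the published description ("the 90th percentile of both
curves merge at an equal conductance") does not disambiguate the two,
and they coincide only for symmetric components.  Across 100 simulated
cohorts the median recovered boundary sits within a few percent of the
2.35 nS anchor; the per-cohort spread (median |error| ≈ 10%) is at the
information limit of the problem — an exact-likelihood EM fit achieves
≈ 8.6% under the same conditions — so the boundary should be reported
with that uncertainty in mind.

Age-group comparisons default to the conventional developmental bins
(P6–9, P10–22, P25–34, P100–120, P180–210), configurable.  Two-group
comparisons use Welch t-tests; multi-group, one-way ANOVA with
Holm-corrected pairwise tests.  Territory density classes use the
more-than-5-NeuN⁺-somata rule with boundary-inclusive point-in-circle
counting, coordinates in µm relative to the soma.

## Degenerate inputs and tie-breaks

Non-positive conductances are excluded from the mixture with a reported
count; an I/V without a zero crossing flags rather than extrapolates;
`percent_block()` with a silent pre-epoch returns `NA` with a flag and
clips to [0, 100] while keeping the raw value; empty partner series
leave all events unmatched; two-Gaussian fits that fail to converge
from all three split starts fall back to the single-Gaussian
preference (a conservative tie-break).  Event merging bridges
sub-threshold gaps below 200 ms; the first threshold crossing wins when
events overlap, so coincident transients are reported as one event.

## Problem sizes

The shipped tests and the acceptance script use the cohort sizes of the
emulated study where they matter statistically: n = 264 cells for the
mixture (500 null replicates for type-I, 200 for power, 100 cohorts for
boundary recovery), 100 noisy plus 20 noise-free cells for parameter
recovery, ten 110 s sessions for detector sensitivity, and 100
regression cohorts of 15 cells.  Sessions are synthesized at 2 kHz —
ample for events band-limited below ~5 Hz — rather than the 20–50 kHz
of acquisition hardware, and session durations of 1–2 minutes keep
expected event counts near ten.

## Known limitations

* The transient-fit algorithm reconstructs an unpublished analysis
  script; it is validated only against the simulator's model class.
* The Henderson calculation ignores activity coefficients and assumes
  the printed-recipe ion entry convention; its ±2 mV agreement with the
  published −14 mV value absorbs the unstated temperature.
* The detector's parameters are tuned to the SLIC time scale; very slow
  baseline drift (> tens of seconds) is absorbed by the rolling median,
  but drift on the event time scale would bias amplitudes.
* The mixture procedure inherits the arbitrariness of histogram
  binning; the EM cross-check should accompany any borderline model
  preference.
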