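Package: opcephys
Title: Passive Membrane Properties and Potassium-Driven Currents in
    Glial Voltage-Clamp Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-cell voltage-clamp recordings of
    oligodendrocyte precursor cells (OPCs) and other glia: extraction of
    passive bioelectrical properties (series resistance, membrane
    capacitance and resistance, resting potential, inward potassium
    conductance) from voltage-step sweeps; two-Gaussian classification of
    conductance states on the log-transformed inward conductance;
    detection of spontaneous long inward currents (SLICs) in holding
    current traces and their pairing with field-potential and
    potassium-selective microelectrode recordings; Nernst-based prediction
    of potassium-evoked current deflections; log-linear calibration of
    potassium-selective microelectrodes and Henderson liquid junction
    potentials. A single-compartment biophysical simulator generates
    voltage-clamp sweeps, co-recorded SLIC sessions and cell populations
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    minpack.lm,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
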