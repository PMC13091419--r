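Package: spikefield
Title: Spike-Train and Local-Field-Potential Analysis for Neonatal
    Hypoxic-Ischemic Injury Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies long-term electrophysiological consequences of
    neonatal hypoxic-ischemic (HI) brain injury from single-unit spike
    trains and local field potentials (LFP) recorded in retrosplenial
    cortex and hippocampal CA1.  Provides Poisson-surprise burst
    detection, correlograms and pairwise firing-rate correlation
    matrices, Welch spectral estimates with band areas, spike-field
    coherence, theta-alpha spike-phase statistics (phase-locking value,
    Rayleigh test, phase-amplitude modulation index), waveform-based
    pyramidal/interneuron classification, longitudinal unit tracking
    across a 7-day rotarod protocol, and a synthetic-cohort generator
    with the group structure (sham left/right, HI contralateral/
    ipsilateral) needed to exercise every stage without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
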