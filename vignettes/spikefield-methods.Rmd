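---
title: "Methods: spike-train and LFP analysis in spikefield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train and LFP analysis in spikefield}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spikefield` analyses single-unit spike trains and local field
potentials (LFP) from a neonatal hypoxic-ischemic (HI) injury model:
four hemisphere groups (sham left/right, HI contralateral/ipsilateral)
recorded in retrosplenial cortex (RSC) and hippocampal CA1.  This
vignette documents the models behind each stage, the tunable
parameters and their defaults, the numerical conventions, and what the
synthetic cohort generator does and does not emulate.

## Data model and conventions

A `spike_train` holds absolute spike times in seconds (double
precision, strictly increasing, within `[0, duration]`); a
`lfp_signal` holds uniformly sampled microvolt values with an explicit
sampling rate.  All bin edges throughout the package are half-open
`[start, end)`, so a spike or lag on an edge is counted exactly once
(a relative epsilon of 1e-9 bins keeps edge values in the upper bin
despite floating-point rounding).  Duplicate spike timestamps —
refractory violations — are collapsed to one spike with a warning
rather than an error: they are a data-quality signal, not a fatal
condition.  `analysis_config()` centralises every tunable parameter;
unknown keys are rejected by name so typos cannot silently fall back
to defaults.

## Burst detection

The burst statistic is the Poisson surprise: for `n` spikes spanning
`T` seconds in a train with whole-session mean rate `r`,
`S = -ln Pr[N >= n]` with `N ~ Poisson(rT)`, computed on the log scale
via the upper regularised tail (`ppois(..., log.p = TRUE)`), so values
of several hundred remain exact.  Natural logarithms are used, so the
acceptance threshold `S >= 5` corresponds to a tail probability below
`e^-5 ≈ 0.0067`.  The baseline is the whole-train mean rate: the
simplest reading of a "random spike" null, and configurable.

The search seeds candidate windows at (a) every maximal run of
interspike intervals shorter than half the mean ISI and (b) the
highest-surprise consecutive spike triplets, which catches clusters in
sparsely firing units whose ISIs are not short relative to the
train-wide mean.  Each seed is refined by coordinate ascent: the end
is re-optimised over forward extensions for the fixed start, then the
start over all admissible positions for the fixed end, iterating to a
fixed point.  The per-coordinate search is bounded to a 200-spike
horizon beyond the current window — bursts are local events — but
iterated ascent can grow past it.  Overlapping accepted windows merge
to their union only when the union scores at least as well as either
constituent; otherwise the better window is kept.  On trains of up to
30 spikes this procedure reproduces exhaustive surprise maximization
over all contiguous windows (tested on 1000 random trains), while
remaining near-linear in practice on hour-long recordings.

A minimum of three spikes per burst is enforced: the surprise of a
two-spike event is dominated by a single ISI and unstable.  Burst
duration is last-minus-first spike time; no padding is invented.

One property of surprise maximization deserves emphasis: a detector
that finds *every* window with `S >= 5` necessarily also flags chance
windows in featureless Poisson trains (the maximum over many
overlapping windows is far more liberal than any single window test).
Percent-spikes-in-bursts therefore has a nonzero floor in
Poisson-firing units, and detected counts sit above an injected burst
load.  Recovery tests consequently match detected windows to injected
events rather than comparing raw counts, and group comparisons of
burst load are interpreted as contrasts against that common floor.

## Discharge-pattern classification

Units with at least 50 spikes are classed by χ² template competition
on the ISI distribution, binned into 50 equal-width bins up to the
99th ISI percentile (fixed binning keeps results reproducible; the
upper 1% of intervals would otherwise stretch the grid arbitrarily).
Three templates are parameterised from the train itself rather than
free-fitted:

* *regular* — a Gaussian centred on the mean ISI with sd = mean/4
  (symmetric, narrow);
* *irregular* — an exponential at the mean rate (the Poisson ISI law);
* *bursting* — an early-peaked quasi-normal centred on the median ISI
  (the intra-burst interval when bursts dominate), mixed 3:1 with the
  exponential so the inter-burst gaps do not produce empty expected
  cells.

Expected counts are floored at 0.5 to guard degenerate cells; the
class with the smallest χ² wins, and "regular" splits into
regular-PN / regular-IN by the unit's waveform class.  Cell-type
classification itself is the region-specific quadrant rule (IN iff
trough-to-peak < 0.4 ms in RSC / 0.25 ms in CA1 *and* rate > 15 Hz;
PN iff wide *and* at most 15 Hz); boundary values fall PN-side or
unclassified, never IN, and off-quadrant units are excluded from
group composition statistics.

## Spectral estimation

All spectra are Welch estimates: Hann-tapered 256-sample blocks with
5 % overlap between consecutive blocks.  The 5 % overlap is
unconventional (50 % is more common) but is the acquisition protocol's stated value and is configurable.  Power densities are one-sided and
Parseval-consistent (the integral reproduces the signal variance
within a few percent).  Per-block demeaning suppresses the DC bin, so
white-noise flatness holds per Hz from theta upward; the delta band
(0–4 Hz) carries that rolloff.

The LFP analysis rate defaults to 500 Hz (`lfp_decimate()` performs
zero-phase anti-alias filtering before subsampling).  With 256-point
blocks this gives a 1.95 Hz grid.  A 0.4 Hz resolution with 256-point
blocks would imply a ~102 Hz analysis rate, whose Nyquist cannot
support a 0.5–100 Hz coherence range; since those two protocol parameters
are mutually inconsistent, the resolution here follows from
(rate, nfft), and both are configurable.

Spike-field coherence bins the train as a 0/1 indicator on the LFP
sample grid (multiple spikes in one ~2 ms sample collapse to 1, with a
message), mean-subtracts, and computes magnitude-squared coherence;
band summaries are the *mean* coherence within each band (the peak
would be an alternative; averaging is less sensitive to single-bin
noise).  Spike-spike coherence uses 1000 Hz count series by default
and summarises as the mean over 0.5–100 Hz.

## Phase statistics

The theta-alpha phase is the analytic-signal argument of the 4–12 Hz
zero-phase band-passed LFP, wrapped to `[0, 2π)` with the cosine
convention: 0 at the oscillation peak, π at the trough.  Spike phases
are read at the nearest LFP sample.  `PLV = |n⁻¹ Σ e^{iθ}|`; the
Rayleigh statistic is `Z = n·PLV²` with the standard small-sample
corrected p value.  The phase-amplitude modulation index follows the
entropy construction over 18 phase bins (the convention of the
standard entropy-based implementations; configurable):
`MI = (ln N − H(p))/ln N`, where `p` is the normalised mean envelope
per bin.  `MI` is exactly 0 for a phase-independent envelope and
exactly 1 when all envelope mass falls in one bin, is invariant to
positive rescaling, and is monotone in the depth of a
`1 + d·cos(phase)` envelope family.

Per-unit summaries (`phase_stats()`) report the same entropy
normalisation applied to the spike-phase histogram as the unit's
phase-locking-bias `MI`: unlike an LFP-only phase-amplitude index,
this quantity responds to the spike-phase concentration that the
coupling parameter κ controls, which is the contrast of interest
between hemisphere groups.  A sine-based transform of PLV to degrees
is not well defined, so PLV (in `[0,1]`) and the mean
resultant angle (degrees) are reported separately.

## Pairwise synchrony and matrix ordering

Rates are binned at 12.5 ms and convolved with a Gaussian kernel
(default sd 25 ms = 2 bins — not fixed by the acquisition protocol; chosen
to suppress bin noise while preserving burst-scale structure).  The
pairwise matrix holds squared Pearson correlations of the smoothed
series over the analysis window; zero-variance series yield 0 with a
warning.  Display order is the leaf order of average-linkage
agglomerative clustering on distance `1 − R²` (average linkage is the
least shape-biased default given no stated linkage); when every
off-diagonal distance ties, the input order is kept.  Session matrices
are compared by the correlation of their strict upper triangles.

## Longitudinal tracking

Identity across days combines four measures: maximum time-shifted
waveform correlation (Fisher-z transformed, r clipped at ±0.9999),
normalised trough-to-peak amplitude change `|A_k − A_1|/A_1`, and KL
divergences of log-scaled ISI histograms (100 log-spaced bins from
0.5 to 1e5 ms — a 0.5–105 ms reading would make a log-scaled 100-bin
histogram pointless) and ±100 ms autocorrelograms (100 bins).
Histograms are smoothed additively (ε = 1e-6) before normalising, so
KL is finite; the reported statistic is `ln(KL + ε)`, which brings the
within-day distribution toward normality.

Stability thresholds are calibrated from within-day split-half scores
of the same units, assumed stable: 99th percentiles of the two KL
measures and the amplitude change, 1st percentile of Fisher-z.  The
four criteria combine conjunctively (the strictest reading; a
composite score is the alternative), and the fraction of calibration
pairs failing their own criterion is reported as the false-negative
estimate.  With small calibration sets the percentile thresholds sit
near the sample extremes, so a matching share of genuinely persisting
units fails — the reported false-negative rate, not a bug.

Learning-response classification regresses per-session spike-field
coherence on session index over task-on sessions and classifies by
quadrant: consistent trends (high R²) are *reactive*; low R² with low
mean coherence is *non-reactive*; low R² with constant high coherence
is the pathological *HI-affected* profile.  Axis thresholds default to
a deterministic 1-D two-means split (centres initialised at the range
extremes, iterated to a fixed point; threshold = centre midpoint).
Cohort medians were considered and are available via
`thresholds = "median"`, but a median separates the classes only when
each axis splits the cohort exactly in half, which no realistic
reactive/non-reactive/affected composition satisfies; the two-means
split recovers generated labels across compositions.

## The synthetic cohort

`cohort_spec()` encodes the modelled recording conditions as generator defaults,
per hemisphere group (per region): 10/10/10/5 units (the ipsilateral
count at half the sham count), pyramidal background rates 5/5/5/2.5 Hz,
injected bursts 1/1/1/6 per minute (Poisson sizes, mean 8, fixed 5 ms
intra-burst ISI — the fixed ISI keeps the expected surprise of an
injected burst analytic), shared slow log-rate modulation 0/0/0/0.8
(a ~1 Hz-bandwidth Gaussian process common to a group's units, which
elevates pairwise R² without duplicating spike times), von Mises
phase-locking concentration κ = 0/0/0/4 to the group LFP in 4–12 Hz,
and theta LFP amplitude 10/10/10/30 µV over a 5 µV broadband floor
with 5 µV white noise.  Sessions default to 300 s at a 500 Hz LFP
rate.  Where the reported phenotype gives directions rather than
magnitudes usable for calibration, these are
order-of-magnitude choices — set once, stated here, and exercised
only as directional contrasts.

Spike generation is exact inhomogeneous-Poisson sampling by thinning
a maximum-rate process (no discretisation bias); with κ = 0 and zero
modulation it reduces to homogeneous Poisson.  Waveforms replicate a
biphasic template (Gaussian trough at the alignment sample, peak
trough-to-peak milliseconds later, trough width set from the half
width) over four channels with fixed gains.  Every generator is a
pure function of its parameters and seed.

What the generator does *not* emulate: spike-sorting errors and drift,
non-stationary rates beyond the slow modulation, 1/f LFP background
(bands are sinusoids plus white noise), volume conduction, behavioural
covariates, or cross-frequency coupling beyond the single band.
Passing recovery tests therefore demonstrates estimator correctness
under the assumed statistical structure, not robustness to every
failure mode of in-vivo data.

## Problem sizes and numerical choices

Test and acceptance runs use deliberately scaled problem sizes chosen
for tight feedback: 200–1000 random trains of ≤ 30 spikes for
exhaustive-oracle agreement, 1e5 angles for von Mises recovery,
600–1000 s null recordings for coherence calibration, one 300 s
single-region cohort per seed (10 seeds) for phenotype recovery, and
12-unit tracking sets.  Remaining conventions: peak search after the
trough breaks ties toward the earlier sample; the spike-detection
alignment sample defaults to 10 of 40 (unstated in the protocol;
configurable); correlation clipping at ±0.9999 bounds Fisher-z;
surprise of an empty window is 0; an all-zero envelope, a constant
LFP, or an empty train for phase/coherence statistics are errors, not
silent NaNs.

## Known limitations

Burst detection inherits the chance-window floor discussed above;
comparisons should always be against a matched control group or the
Poisson floor.  The discharge-pattern templates are intentionally
rigid (parameterised from the train, not fitted), so intermediate
patterns resolve by relative χ², not by absolute goodness of fit.
Spectral band summaries depend on the (rate, nfft) grid; with the
default 1.95 Hz resolution a tone near a band edge leaks into the
neighbouring band, and analyses needing sharper allocation should
raise `nfft`.  Stability calibration requires enough within-day units
(≥ 10) for its percentiles to be meaningful.  Group-level inferential
statistics (ANOVA families) are intentionally out of scope: the
pipeline emits the per-unit tables such tests would consume.
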