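---
title: "Methods: oscillation detection and spike-phase analysis"
author: "ripplephase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oscillation detection and spike-phase analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripplephase)
```

# Scope and model

`ripplephase` analyses how single interneurons time their action potentials
relative to hippocampal network oscillations. The pipeline takes a
continuous local field potential (LFP), a treadmill speed trace, and
per-cell spike timestamps, and produces per-cell and per-group statistics
for four oscillation bands: theta (5–10 Hz), gamma (25–90 Hz) and epsilon
(90–130 Hz) during running, and ripples (90–200 Hz) during rest.

Because the kinds of recordings this analysis was designed for are not
publicly deposited, the package pairs every analysis stage with a synthetic
generator whose ground truth is known exactly. All quantitative claims made
by the test suite and the acceptance script are claims about recovery of
that ground truth, under the study conditions described below.

# Behavioral segmentation

Run/rest states are thresholded from the speed trace. Episodes must be
strictly longer than 20 s (running) or 200 s (resting) to enter the
analysis; shorter episodes are discarded, never merged. The default speed
threshold of 1 (trace units) is meaningful only for the bimodal synthetic
traces; real data require a rig-specific value.

# Filtering and envelopes

Canonical band filtering uses a 4th-order Butterworth applied forward and
backward. The two pass orders are averaged, which leaves the passband
response unchanged and makes the operation exactly symmetric under time
reversal — the zero-phase property that the trough-anchored phase
convention depends on. Edges are padded by odd reflection over three filter
time constants (`3 fs / low`), and the envelope is the magnitude of the
analytic signal (FFT Hilbert transform). "Power of the envelope" means the
squared envelope before z-scoring; a config switch (`power = "envelope"`)
exposes the unsquared reading.

The time–frequency filterbank (4 Hz bands, 2 Hz steps, 10–200 Hz, 96
bands) is realized in the frequency domain: cosine-tapered band weights
applied to the analytic spectrum give each band-limited analytic signal in
one inverse FFT. A time-domain Butterworth of 4 Hz bandwidth near 10 Hz
places poles essentially on the unit circle, so the spectral implementation
was chosen for numerical robustness; per-band envelope power is z-scored
over the whole usable trace by default (normalization epochs are
switchable, since the convention — whole recording vs per state — is a
genuinely open choice).

One temporal-resolution caveat is worth stating: a band of full width B Hz
has an envelope that can only fluctuate at rates below ~B, so the default
4 Hz grid cannot follow power modulation at theta frequency (8 Hz) — a
coherently amplitude-modulated tone is exactly invisible to it, because
its ±8 Hz sidebands fall outside every 4 Hz band. Broadband fast
oscillations survive (their power is smeared but keeps its timing), and
cross-frequency timing checks in the test suite use a wider (20 Hz)
analysis bandwidth where within-cycle timing is resolvable.

# Event detection

Ripples are detected on the 90–200 Hz band envelope normalized to SD units,
z = (envelope − mean)/SD, with mean and SD computed over the supplied rest
epochs (event samples included; an iterative exclusion re-estimate was
considered and rejected as an undocumented elaboration — the resulting bias
is small and conservative, and it is stated here instead). An event is a
contiguous excursion at or above the 2 SD edge threshold that reaches 5 SD
somewhere inside; this is equivalent to extending each 5 SD crossing
outward to the 2 SD crossings, and makes the event count monotone in the
detection threshold. The thresholds are interpreted as SD above the *mean*
envelope: with an uncentered reading (5×SD of the envelope alone) the
threshold would sit at ~3.3× the raw-signal SD, which band-limited noise
crosses routinely — incompatible with the intended rarity of events.

Excursions separated by less than `mergeGap` (default 10 ms) are merged and
events shorter than `minDuration` (default 15 ms, two ripple-band cycles) are dropped; both exist
to keep envelope dips inside one ripple from splitting it, and both are
exposed as parameters because the original procedure leaves them unstated.

Boundary accuracy is assessed against the *expected* 2 SD crossing times of
the planted envelope (the solution of
`sqrt(planted² + E[noise envelope²]) = mean + 2 SD`), not against the
planted support edges: for a smooth (Hann) envelope the 2 SD crossing lies
genuinely inside the planted support (by d/6 for an 8 SD event), so support
edges are not what a correctly working detector should report.

# Phase convention and circular statistics

Phase is defined with 0° at the trough and 180° at the peak, ascending limb
0→180. The default extraction interpolates linearly between detected
troughs and peaks, so trough samples map exactly to 0° and peak samples to
180° even for asymmetric cycles; analytic-signal phase (shifted so troughs
sit at 0°) is available as an alternative, and the two differ on asymmetric
theta.

Per-cell phase locking is the mean resultant vector (length r, mean
direction), uniformity is the Rayleigh test with the standard finite-n
corrected approximation, and mean directions are compared across groups
with the Watson–Williams circular ANOVA with the (1 + 3/8κ) concentration
correction. When classes of cells are compared, the test is applied to
per-cell mean phases, each cell weighted equally; group dispersion is
reported as circular SD. With n ≈ 2–12 cells per class the Watson–Williams
group sizes fall below the usual n ≥ 5 guidance, so the implementation
warns (rather than refuses) for small or weakly concentrated groups.

# Rate modulation and randomization tests

Event-related rate changes are tested against Monte-Carlo surrogates:
either every spike is redrawn uniformly within the behavioral-state
intervals (spike shuffle, preserving spike count), or the events are
repositioned uniformly within the state (event shuffle, preserving
durations and non-overlap, via the sorted-uniform-gap construction in a
concatenated state-time coordinate). The two-sided p doubles the more
extreme tail with the (k+1)/(N+1) floor, capped at 1; N defaults to 1000
surrogates and the seed is recorded in the result. Because the in-event
spike count is integer-valued, tie inclusion makes the test mildly
conservative; calibration on 250 s rest epochs (the analysis minimum) with
~5,000-spike trains holds the empirical type-I error within a couple of
points of the nominal 5%.

Peri-event histograms use 40/20/40 normalized-time bins (before span =
twice the event duration, event span, after span). Each bin value is the
mean spike count per event in that bin, so the 20 "during" bins sum to the
mean in-event spike count — the reading of "spiking probability" that makes
the histogram exactly mass-preserving. Doublets are defined as ≥2 spikes
between consecutive ripple-band troughs inside an event; trough-to-trough
is the unique parameter-free cycle partition consistent with the phase
convention.

# Core frequency

Each event's intra-event frequency is estimated three ways on the 90–200 Hz
filtered trace *within the detected event boundaries*: (1) the inverse of
the mean inter-zero-crossing interval halved, with crossings located by
linear interpolation; (2) the inverse of the mean interval between positive
local maxima, with parabolic sub-sample refinement; (3) the frequency of
the global magnitude maximum of a complex Morlet scalogram (bandwidth
parameter 5, center-frequency parameter 1) over a 90–200 Hz grid at 1 Hz
spacing. The wavelet method is the default and the one used for reported
values. Operating inside the detected (2 SD) boundaries matters for the
time-domain estimators: outside them the envelope approaches the noise
floor and zero crossings become noise-driven.

Events are partitioned by the presence of a cell's spikes and the two
core-frequency samples compared with the unpaired rank-sum (Mann–Whitney)
test by default; the event partitions are independent sets, so the paired
signed-rank variant (also provided) is only applicable to artificially
matched partitions and refuses unequal sizes.

# The synthetic generator

The generator emulates exactly the structure the analysis assumes, and no
more:

* **Background**: spectrally shaped Gaussian noise with a 1/f^α spectrum
  (α = 1 by default), RMS 0.05 mV. Real LFPs have line noise, non-Gaussian
  transients and nonstationary spectra; none of these are modeled, so
  passing tests demonstrate correctness of the estimators, not robustness
  to every recording artifact.
* **Rhythms**: sinusoids with the trough at epoch onset; a nested fast
  rhythm's amplitude can be coupled to a carrier phase with depth m ∈ [0, 1]
  (envelope maximal at the preferred carrier phase), emulating
  theta-nested fast oscillations.
* **Events**: Hann-enveloped bursts, 40–150 ms, 90–200 Hz, placed without
  overlap. Event height is set in detector SD units via the measured
  envelope baseline, and each burst is compensated for its band-pass gain
  (`burstBandGain`) — short bursts and band-edge carriers are attenuated
  by the 90–200 Hz filter, so without compensation a nominal "8 SD" event
  can arrive at ~4 SD where the detector measures it. The source
  recordings' ripple SNR is not reported anywhere, so SNR is an explicit
  free parameter (8–12 SD in the packaged conditions).
* **Spikes**: thinning of a piecewise rate at the sampling resolution —
  base rate × von Mises phase modulation (normalized to preserve the mean
  rate) × event gain inside events — with a 2 ms absolute refractory
  period and centered sub-sample jitter (uncentered jitter would bias
  ripple-frequency phases by ~20°). Doublets add a second spike 3–5 ms
  after a cycle's first in-event spike with a per-cycle probability, and
  the generator logs every insertion so detection can be scored against
  truth. No biophysics, bursting dynamics, or spatial coding is modeled.
* **Sampling rate**: 1250 Hz by default — several times the Nyquist needs
  of the fastest band while keeping the packaged simulations light. All
  operations are rate-agnostic; recordings at 12–20 kHz are handled by the
  same code (the 20× downsampling step reproduces the original workflow's
  theta path).

Problem sizes used in the packaged validation: ripple-detection recovery
uses 20 seeds × 300 s of rest LFP with 20 planted events each; Rayleigh
calibration uses 1,000 uniform simulations of n = 100; randomization
calibration uses 200 null datasets on a 250 s rest epoch; core-frequency
agreement uses 50 events spanning 100–190 Hz; the demo cohort is 6 cells
(two per class) over 60 s running + 250 s rest.

# Degenerate inputs and numerical choices

* Mean phase is flagged undefined when r = 0 (perfectly balanced phases).
* Fewer than 2 cycle landmarks, fewer than 3 zero crossings, fewer than 2
  peaks, or single-partition spike-conditioned comparisons are flagged
  rather than guessed.
* The Rayleigh approximation refuses n < 5.
* Thinning probabilities above 0.95 per sample trigger a warning to raise
  the sampling rate.
* All randomness is seeded; identical configuration and seed give
  byte-identical pipeline outputs (output files carry the package version,
  seed and a parameter digest in their header).

# Known limitations

* The baseline SD of the detection envelope includes event samples,
  slightly inflating the baseline for event-rich epochs (conservative).
* Landmark-interpolated phase is undefined before the first and after the
  last landmark; spikes there are excluded and counted.
* The Watson–Williams test on very small groups (2–4 cells) is reported
  with a warning; its p-values should be read as descriptive at that size.
* The generator's spike trains are conditionally Poisson apart from the
  refractory period; real interneurons burst and adapt.
* The unimodality check on pooled core frequencies tests for the absence
  of a depleted 130–150 Hz trough between modes, a pragmatic surrogate for
  a formal dip test.
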