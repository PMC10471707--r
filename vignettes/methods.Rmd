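---
title: "Methods: functional characterisation of retinal ganglion cells from high-density MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional characterisation of retinal ganglion cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinafunc)
```

## Overview

`retinafunc` implements a pipeline for characterising the light responses of
retinal ganglion cells (RGCs) recorded on a high-density 64 x 64
multielectrode array (MEA) under full-field chromatic stimulation, as used in
studies of the avian retina. The pipeline covers:

* **Stimulus construction**: achromatic contrast steps ("white steps", WS,
  100% down to 10% contrast, 2 s On / 2 s Off), single-LED colour steps (CS,
  six LEDs from 630 to 360 nm), an exponentially accelerating chirp
  (1 to 30 Hz over 30 s), and a 20 Hz binary chromatic noise sequence on four
  LEDs (R, G, C, B).
* **Electrical images**: spike-triggered voltage averages across all 4,096
  channels, from which the soma, the axon trajectory and the axonal
  conduction velocity are recovered.
* **Response indices**: polarity (PI), transience (TI), spectral dominance
  (SD), spectral tuning against log-transformed visual pigment nomograms
  (ST), latency, and a high-frequency index (HFI) from the chirp spectrum.
* **Spectral kernels**: per-LED linear temporal filters by spike-triggered
  averaging, with amplitude, spectral-centroid kinetics and time-resolved
  colour opponency (COI).
* **Phase locking**: vector strength per chirp frequency bin against a
  Poisson bootstrap null.
* **Clustering**: block-wise PCA feature reduction and Gaussian-mixture
  clustering over four covariance structures selected by BIC, followed by
  similarity-based merging and a minimum-size retention filter.
* **Synthetic ground truth**: a linear-nonlinear-Poisson (LNP) simulator and
  an electrical-footprint generator, so that every stage has a
  parameter-recovery test with known answers.

Because raw MEA recordings of this kind are far too large to redistribute,
the package validates itself entirely on synthetic data with known ground
truth; the synthetic generator is first-class, tested code.

## The LNP simulator and what it does (and does not) emulate

Each ground-truth cell (`gt_cell()`) is a linear-nonlinear-Poisson cascade.
The stimulus (six LED intensity channels, centred per channel on its
temporal mean) is passed through a temporal filter — an alpha function
`t exp(-t/tau)` for sustained (monophasic) kinetics or a zero-net-integral
difference of alpha functions for transient (biphasic) kinetics — and
weighted by a signed six-vector of spectral weights. The rectified positive
part of the drive excites an On branch, the rectified negative part an Off
branch, with configurable branch weights; spikes are drawn from an
inhomogeneous Poisson process (1 ms simulation step for step/chirp stimuli,
2 ms for the long noise run) with a 2 ms absolute refractory period. A pure
delay (default 100 ms) stands in for phototransduction and inner-retinal
processing, making the chirp phase-shift correction exactly recoverable.

An optional second chromatic pathway with its own kinetics can be summed
into the drive (simple opponency), and the Off branch can be given a
separate drive (`off_pathway`). The latter matters for OnOff cells: a
balanced OnOff cell whose two branches rectify the *same* drive has a firing
rate that is an even function of that drive, so its linear spike-triggered
kernel cancels to zero. Real OnOff cells show strong, time-dependently
opponent kernels precisely because their On and Off circuits integrate
different spectra with different kinetics; the fixture's OnOff archetype
therefore couples a fast, red-dominant, near-zero-sum On pathway with a
slower, spectrally opposed Off pathway.

The generator deliberately omits spatial receptive fields (all stimuli are
full field), adaptation, spike-sorting artefacts and correlated noise.
Passing tests therefore demonstrate that the estimators recover the
parameters of this model family under Poisson variability — not that they
are robust to every failure mode of real recordings.

### Fixture archetypes

The fixture (`generate_fixture_dataset()`) mirrors the four response groups
that dominate such datasets, plus stimulus-independent noise cells:

| archetype | polarity | kinetics | spectral signature |
|---|---|---|---|
| `off_fast` | Off | transient (tau = 12 ms, biphasic) | broad, long-wavelength weighted |
| `onoff_opponent` | OnOff | mixed | fast +R/-B On pathway vs slow opposed Off pathway |
| `on_transient_narrow` | On | transient (tau = 12 ms) | narrow blue, long-wavelength opponent surround |
| `on_sustained_broad` | On | sustained (tau = 50 ms, monophasic) | broad, white-dominated |
| `noise` | none | none | gain 0, baseline only |

Gains and baselines (35-150 Hz per unit drive; 0.5-1 Hz baseline for
responsive cells, 4 Hz for noise cells) were chosen once so that evoked responses sit clearly
above the Poisson noise floor at the five-repeat protocol, as they do for
well-isolated units in practice. The expected signs of PI, TI and SD per
archetype are recorded in the fixture manifest and asserted by the recovery
tests.

## Stimuli: numerical choices

* **Steps** run at the stimulator frame rate of 60 Hz; epoch annotations
  tile the timeline exactly, and timelines round-trip through full-precision
  CSV.
* **Chirp**: the sweep is the standard exponential
  `f(t) = f0 (f1/f0)^(t/T)` with closed-form phase, the unique common
  convention for an "exponentially accelerating" sweep; the waveform is a
  sinusoid so that instantaneous phase is defined at all times (phase 0 =
  On onset, pi = Off onset).
* **Noise**: each of the four chromatic channels is a maximal-length
  linear-feedback shift-register sequence (order 15 by default, seeded), a
  true M-sequence; an i.i.d. Bernoulli(0.5) fallback is available. Frame
  count (18,000) and frame rate (20 Hz) are independent configuration
  values.

## Electrical images

The per-channel signal score is `max(STA) * |min(STA)| * diff(STA)`, with
the first difference reduced to its maximum absolute value (the steepest
slope); the literal signed product, which is negative on signal channels,
sits behind a flag. After median subtraction, a channel is retained only if
it also exceeds the array mean (z-score > 0): the score distribution is
extremely heavy-tailed, so the mean sits far above the median and isolates
the handful of signal-bearing channels. Isolated survivors (no retained
8-neighbour) are dropped, and a map with more than 400 survivors is
rejected as uninterpretable.

Axon tracing excludes retained channels within 6 channels of the
highest-scoring (soma) channel, sorts the rest by the frame of their STA
minimum, links channels closer than 2.2 pitches (which bridges the
single-channel gaps of fractionated, saltatory footprints) and takes the
shortest weighted path from the channel nearest the soma to the channel
whose minimum occurs latest. The conduction distance includes the hop from
the soma to the path start, since the transit time is measured from the
soma's temporal origin; velocity is `D_short / (Fmin_max / f_s) / 1000`
m/s with the transit time in frames relative to the soma minimum —
physically required for a transit time. A trace counts as a detected axon
when its path has at least 10 channels beyond the soma radius.

The detection-versus-spike-count curve is summarised by a least-squares fit
of `A (1 - exp(-n/k))`, with `A` bounded in [0, 1]; degenerate inputs fall
back to the observed fraction.

## Quality metrics

The signal-to-noise quality index QI = Var over time of the repeat mean,
divided by the repeat mean of the per-repeat time variance; it equals 1 for
perfectly repeatable responses and about 1/R for independent noise across R
repeats; 0.4 is the quality floor for step and chirp responses. The kernel
pre-selection quality is the largest per-LED standard deviation of the
z-normalised kernel, floored at 2.5. Cells passing *any* of the thresholds
are retained.

The step-response quality index combines the multivariate
SPIKE-synchronization and ISI-distance profiles across repeats with the
peristimulus histogram (50 ms bins by default):
`QI = max(SYNC) - mean(ISI) + (max(PSTH) - mean(PSTH)) * std(SYNC)`.
Both spike-train measures are implemented from their published definitions
(adaptive coincidence window of half the minimum surrounding interspike
interval; `|x_i - x_j| / max(x_i, x_j)` on instantaneous intervals with
max(edge, adjacent) edge correction) and are tested bin-for-bin against a
deliberately naive brute-force oracle.

Waveform unimodality uses Hartigan's dip statistic, implemented from the
original greatest-convex-minorant / least-concave-majorant algorithm with
an iterative modal-interval refinement, and a uniform-null bootstrap
p-value (1,000 draws by default). The implementation reproduces the exact
anchors `dip = 1/(2n)` for an equally spaced sample and `dip = 1/4` for two
equal point masses, and is affine invariant.

The On/Off independence check splits a unit's waveform PC1 loadings with a
two-component one-dimensional Gaussian mixture (EM, median-split
initialisation) and applies a continuity-corrected chi-square test to the
On/Off-by-subunit contingency table. The bias audit bins a response index
into 10 bins and rank-correlates bin labels with a quality metric; note
that binning ties ranks, so even a perfect monotone relation yields |rho|
slightly below 1.

## Response indices

PI, TI and SD are the symmetric contrasts `(a - b)/(a + b)` of,
respectively: On vs Off mean spike counts over the full 2 s epochs of the
100% contrast white step; peak 40 ms box-smoothed rate in the 80-160 ms
(transient) vs 240-2,000 ms (sustained) windows after a transition; and
the transient amplitude of the largest colour-step response vs the 100%
white step. The compound TI uses the On variant when PI >= 0 and the Off
variant otherwise, and SD (with its colour-step transience companion) is
computed from the dominant polarity's transitions, since Off-dominated
cells respond at light offset. All three are antisymmetric in their
arguments, invariant to rate rescaling, and flagged undefined (NaN) when
both amplitudes are zero.

Baseline is the mode of a 1,000-bin amplitude histogram of the concatenated
WS+CS trace (range = data range; ties break to the lowest bin, a
deterministic choice). Latency is the time to half the post-transition peak
on the 40 ms smoothed trace.

Spectral tuning compares a normalised 6-point tuning function against
log-transformed A1 visual-pigment nomograms (`T = max(0, 1 + log10 S)`,
mapping 100% and 10% linear sensitivity to 1 and 0 — the roughly ten-fold
operating range of cone phototransduction). Default peak wavelengths for
the four chick cone opsin classes are configuration values (LWS 571, RH2
508, SWS2 455, SWS1 419 nm); any published set can be substituted. Tuning
functions whose peak response is below 3 spikes are not scored.

## Spectral kernels and colour opponency

Kernels are the mean pre-spike stimulus segment minus the mean over all
possible segments, per LED, sampled finer than the 20 Hz stimulus — 51
points at 20 ms spacing for clustering features, and a fine grid (1-5 ms)
for the opponency analysis; both come from one estimator with a
configurable step. z-normalisation uses a kernel computed identically over
the [-2, -1] s pre-spike window (the methods literature also uses a
[-1, -0.5] s variant; the window is configurable). Kernel amplitude is the
per-LED max-minus-min in z units, with cluster means below 2.5 discarded.

The spectral centroid treats the area-normalised magnitude-squared Fourier
transform of the mean-subtracted, zero-padded (256 samples) kernel as a
probability mass function over positive frequencies and returns the
frequency-weighted mean in Hz; a literal reciprocal-frequency weighting —
whose units are 1/Hz — is available behind a flag for comparison.

A time bin is non-responsive when no kernel reaches the amplitude threshold
(3 z for cells, 1.5 for cluster means), opponent when the supra-threshold
kernels disagree in sign, else non-opponent. The colour opponency index is
the mean opponency label over responsive bins, defined only when at least
20 of 1,000 bins are opponent (rescaled proportionally on coarser grids)
and the kernel quality score — top-100 plus |bottom-100| of the pooled
z-values — reaches 1,000. The time-normalised opponency vector rescales
onset (first bin with any |z| >= 1) to -1 and the spike to 0, recoding
non-opponent bins to -1.

## Chirp analysis

Spectra are magnitude-squared Fourier transforms of mean-subtracted rate
traces, zero-padded to a power of two. The best frequency is the spectral
peak within the swept band (>= 0.5 Hz; power below that is stimulus
envelope, not flicker following). HFI contrasts mean power in 4-15 Hz
(high) against 0.9-2 Hz (low), so that positive values mean
high-frequency preference, consistent with the index's name; a flag
restores the opposite window naming. Cells with fewer than 20% more spikes
during the chirp than predicted from the preceding 5 s are unresponsive.

Phase locking shifts spikes back by 100 ms, bins the sweep into ten 3 s
bins whose centre frequencies are the time-averaged instantaneous
frequency (computed from the chirp model rather than hard-coded), and
measures the resultant vector strength per bin. Significance is assessed
against 1,000 count-matched Poisson neurons with uniform phases: a bin is
significant when its vector strength exceeds the null's 95th percentile.
Empty null draws score 1, a conservative choice that makes low-count bins
hard to call significant.

## Clustering

Per-cell features are the KDE rate traces (Gaussian kernel, bandwidth
0.05 s, 1,000 points over the first-repeat interval, area one — which
equalises scale across cells, so no further standardisation is applied
before PCA) split into 10 WS segments, 6 CS segments and the chirp trace,
plus the four z-kernels: 23 blocks. PCA runs per block and retains the
minimal number of components reaching 50% cumulative variance; the scores
concatenate into the clustering matrix.

The Gaussian mixture is fitted by EM for each of four covariance
structures — shared/unshared x diagonal/full (mclust models EEI, VVI, EEE,
VVV) — each from multiple random hard-assignment initialisations, keeping
the best log-likelihood replicate, and the structure minimising BIC wins.
Random restarts matter: single-start EM lands in poor local optima often
enough to corrupt small-sample cluster recovery. Components are then merged
by complete-linkage agglomeration on the correlation distance between
cluster-mean WS+CS traces, cut at correlation 0.9 — an automated,
deterministic surrogate for merging by visual inspection — and merged
clusters below the minimum size (20 in the full protocol) are discarded,
with a cluster of exactly 20 retained.

Response groups (Off / OnOff / On-transient / On-sustained) are assigned
per cluster from cluster-mean indices — Off when PI <= -1/3, On when
PI >= +1/3 (split by the sign of the colour-step transience), OnOff
between — and inherited by member cells; this is a documented surrogate
for assignment by inspection, with the cut configurable.

## Problem sizes and determinism

The test-suite and acceptance-script runs use fixture datasets of 4-6 cells
per archetype with a 12,000-frame noise run and a 5-component mixture with
10 replicates — sizes at which every recovery property (velocity within
5%/15%, kernel correlation > 0.9 at 5,000+ spikes, archetype sign recovery
>= 95%, end-to-end ARI >= 0.8) holds with margin while a full run completes
in minutes on one core. All randomness flows from explicit integer seeds;
repeated runs are bit-identical.

## Known limitations

* The LNP model has no spatial structure, adaptation, or nonlinear
  colour-opponent interactions beyond pathway summation; kernels capture
  only the linear response component by construction.
* Electrical-image synthesis places an identical biphasic waveform on soma
  and axon channels with Gaussian spatial decay; it does not model
  amplitude decay along the axon, electrode-specific noise, or overlapping
  cells.
* Serialisation targets plain-text CSV/JSON; very large recordings would
  need a binary container, which is out of scope here.
* Cluster merging replaces expert curation with a single correlation
  threshold; on real data the threshold deserves inspection.
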