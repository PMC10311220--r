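---
title: "Methods: spike, burst, colocalization and morphometry analysis of neural cultures"
author: "neuroculture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike, burst, colocalization and morphometry analysis of neural cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroculture)
```

# Scope

This package quantifies the three readouts by which 2D (dissociated) and
3D (aggregated) neural cultures are typically compared: spontaneous
electrical activity on multi-electrode arrays (MEAs), axon–dendrite
segregation in two-channel immunofluorescence, and astrocyte arborization
in hand-traced morphologies. It deliberately stops at tidy per-electrode,
per-cell and per-culture tables: hypothesis testing (ANOVA families,
Kolmogorov–Smirnov, multiple-comparison corrections) is standard machinery
that downstream code should apply to those tables with stock routines, and
is not reimplemented here. Spike sorting is likewise out of scope — all
electrode metrics describe population (multi-unit) activity.

# Electrophysiology

## Filtering and spike detection

Raw extracellular voltage is bandpass filtered 200–3000 Hz with a
4th-order Butterworth applied forward and backward
(`signal::filtfilt`). The zero-phase realization matters: burst metrics
depend on spike times, and a causal filter would delay every spike by a
band-dependent lag. The filter family itself is a free choice; Butterworth
is the common default on MEA platforms and its passband ripple is zero, so
the 1 kHz mid-band gain stays within a few percent of unity at order 4.

Spikes are detected where the filtered trace crosses a threshold of
6 × its noise level on the negative side (extracellular somatic spikes are
negative-going; polarity is configurable). The noise level is the RMS of
the filtered trace — for the zero-mean output of a bandpass, RMS and SD
coincide, which makes "6 SD from the RMS" a well-defined rule. Two
practical refinements, both configurable:

* **Dead time, 1 ms.** A single biphasic excursion can cross the
  threshold several times; detections within the dead time collapse to
  the largest excursion. The value is at the refractory scale and well
  below the 30 ms intra-burst ISIs the generator produces.
* **Robust noise option.** On very bursty electrodes, spikes inflate the
  RMS and raise the threshold. A median-absolute-deviation estimate is
  available behind `robustNoise = TRUE`; the default stays with the plain
  RMS rule.

The spike time is the extremum sample of the excursion, not the first
crossing: under noise the extremum is the stabler landmark, and on
noiseless templates it coincides with the rendered peak. Detection is
scale-equivariant (the threshold scales with the trace), which the test
suite checks by multiplying a trace by an arbitrary positive constant.

With i.i.d. Gaussian noise the false-positive rate of the 6-RMS rule is
analyzable: the one-sided tail probability at 6 SD is ~1e-9 per sample,
i.e. ~1e-4 expected crossings over a 10 s trace at 12.5 kHz. That is why
the benchmark (100 spikes of 12 × noise SD over 10 s) is expected to reach
recall and precision ≥ 0.99 with zero false positives, and the tests hold
it to that.

## Firing metrics

The mean ISI excludes intervals above 100 ms, so it reflects the
instantaneous (within-burst) firing tempo rather than the burst spacing;
the mean firing frequency is its inverse. When no ISI survives the
exclusion the mean ISI and rate are reported as `NA` rather than 0 — a
tonic slow electrode is not a fast one. An electrode is *active* with more
than one spike over the recording; aggregation is expected to run on
active electrodes.

## Burst detection

A burst opens at a spike whose ISI to the next spike is ≤ 100 ms, extends
while ISIs stay ≤ 250 ms, closes at the first longer gap, and is kept if
it holds ≥ 5 spikes. One reading note: "a minimum ISI of 100 ms to
initiate" is interpreted as the Max-Interval convention — the *initiation
ISI may be at most* 100 ms. The literal reading (an ISI of at least
100 ms starts a burst) would contradict the continuation rule being a
*maximum*, and would not detect bursts at all on dense trains. The
detector never reopens a burst across its closing gap; scanning resumes
at the spike to the right of that gap, so every spike belongs to at most
one burst.

The detector is verified two independent ways: against a brute-force
enumeration of maximal qualifying windows on 1,000 random short trains,
and by exact recovery of the generator's constructed bursts.

Burstiness is the within-burst spike fraction, in [0, 1] by construction.
On an empty train it is an error, not 0: a silent electrode and a tonic
(never-bursting) electrode are different findings. The interburst
interval is measured end-to-start — the silent gap between bursts — not
start-to-start; the alternative is a one-line change and was judged less
faithful to "interval between bursts".

## Spectrograms

`spectrogram()` is a short-time Fourier power map limited to ≤ 100 Hz,
aimed at burst-rhythm visualization. A note on the signal: a ~1 ms
extracellular spike waveform carries almost no spectral mass below
100 Hz, so burst rhythms are exposed on a smoothed firing-rate signal
(`rateSignal()`: spike counts binned at 200 Hz, Gaussian-smoothed with a
20 ms SD) rather than on raw voltage. On that signal, a train of short
sparse bursts (0.2 s ISIs) concentrates power in the 2–10 Hz band and a
long dense burst (0.07 s ISIs) in the 10–20 Hz band, which is the
super-burst signature the test suite asserts. The operation itself
accepts any uniformly sampled trace.

# Colocalization

Both channels first receive rolling-ball background subtraction
(25-pixel diameter by default). The implementation is a grayscale opening
with a ball-topped (spherical-cap) structuring element: the ball rolls
under the intensity surface, following broad illumination gradients while
unable to enter features narrower than itself. A flat-disc variant sits
behind `flat = TRUE`. The tests compare the estimate against a naive
per-pixel opening computed straight from the definition, and assert the
qualitative contract: a flat field maps to zero, a single bright pixel
keeps ≥ 95% of its excess, a blob much broader than the ball is flattened
below 10% of its height.

Mander's M1/M2 are **area ratios over binary masks** — the fraction of
channel-A signal pixels co-occurring with channel-B signal, and vice
versa — not the intensity-weighted textbook variant; that choice follows
the area-ratio definition used for these cultures. The signal threshold
behind the masks is not pinned down by that definition; the default is a
per-channel Otsu threshold after background subtraction, with fixed
thresholds available (and used by the exactness tests, where the
generator's two-level images make Otsu and fixed coincide). An empty mask
yields `NA`, not 0 — "no signal" is not "no overlap".

The Pearson coefficient uses all pixels. TOS selects the top 10% of
pixels per channel (ties broken by stable pixel order, so counts are
deterministic) and rescales their co-occurrence against the independence
expectation into [−1, 1]; a single threshold pair is reported rather than
a full threshold matrix. Background subtraction is applied before all
scores by default (`subtract = TRUE`), matching the order in which such
images are prepared; pre-corrected images can skip it.

# Morphometry

## Sholl profiles

Crossing counts are computed exactly: each tree edge is a segment, each
radius a circle about the soma, and intersections come from the
circle–segment quadratic. Tangencies count once; a node lying exactly on
a circle counts once across its incident edges (tolerance 1e-9 µm). The
radial step defaults to 5 µm — a common choice against typical astrocyte
territory sizes of tens to hundreds of µm — and the profile runs to the
farthest node by default. The exact counts are validated against a
dense-sampling oracle (0.01 µm arc-length steps) on 50 random arbors.

## Branch morphometrics

Main branches are the processes originating at the soma, measured from
the soma base to the farthest terminal of their subtree. Two filters
apply, deliberately kept separate:

* **Junction filter, 5 µm (stated rule):** an internal branching node
  counts as a junction only when its side path — measured to the farthest
  terminal of the side subtree — is at least 5 µm.
* **Main-branch floor, 10 µm (package choice):** the exclusion of
  "notably small, junction-free projections" from main branches comes
  with no published size; this package couples junction-free status with
  a 10 µm floor, configurable. Sub-threshold stubs still contribute to
  total process length — the 5 µm rule's stated scope is junction
  counting only.

At a node with three or more children, the node counts as one junction
(if any side path qualifies), not one per side branch. Round-trip tests
drive these rules against the generator's constructive truth on 100
arbors, including side projections placed at 4.9 and 5.1 µm to pin the
filter boundary (≥ 5 µm qualifies).

## Zone densities

Astrocyte positions are binned by distance to the perimeter of a circular
aggregate (`d = |p − c| − R`), into 50–200, 200–400 and 400–600 µm bands
by default, with analytic annulus areas and densities in cells/mm².
The circular-perimeter model is a simplification — real aggregate
outlines are irregular, but no geometry beyond a perimeter reference is
available; polygonal perimeters are a natural extension point. Points
inside the aggregate are flagged and left unassigned rather than
silently dropped.

# The synthetic-data generator

The generator's job is statistical structure plus exact truth, not
biophysics:

* **Spike trains** place bursts left-to-right with seeded jitter while
  preserving the configured inter-burst gap; noise spikes stay ≥ 0.3 s
  from every burst window and from each other — comfortably beyond the
  250 ms continuation limit — so the constructed burst set is provably
  what the detector must find.
* **Voltage traces** render each spike as a biphasic template (dominant
  lobe then an opposite lobe at half amplitude, 1.2 ms wide) over i.i.d.
  Gaussian noise. Defaults are 12.5 kHz, 10-minute duration, −60 µV peak
  on 5 µV noise. No published amplitude or noise statistics exist for
  the recordings this emulates, so these are field-plausible placeholder
  values, not calibration; the detection benchmarks state their own
  amplitude-to-noise ratios explicitly.
* **Image pairs** place foreground pixels by seeded sampling without
  replacement, making overlap counts exact integers and the M1/M2 truth
  exact ratios rather than statistical targets.
* **Arbors** are planar (z = 0) trees of fixed-length segments with
  jittered directions: rotations do not change path lengths, so the
  morphometric truth is computed constructively during generation, never
  by the analysis code.

Every generator is a pure function of its spec including the seed (the
caller's RNG stream is saved and restored). What passing round-trip tests
on this data shows: the analysis rules are implemented exactly as stated.
What it does not show: robustness to real-data nuisances — electrode
drift, overlapping units, uneven illumination, point-spread blur, tracing
errors — which the generator intentionally does not model.

# Numerical choices and degenerate inputs

* Thresholding is strict (`>`), so an all-zero trace has threshold 0 and
  zero spikes, and a fixed image threshold above the maximum yields an
  empty mask.
* Geometry comparisons in Sholl use a 1e-9 µm tolerance; rigid motions
  leave profiles and morphometrics unchanged at that tolerance.
* TOS denominators of zero (e.g. a channel's top set covering the whole
  image) return 0 when the numerator is also 0.
* Pipeline outputs are deterministic by construction — no timestamps, a
  canonical-JSON configuration hash — and the test suite asserts
  byte-identical reruns.
* Problem sizes in the test suite (10–120 s trains, 48–64 px images,
  tens-of-node arbors, 1,000-train oracle sweeps) are chosen so the full
  suite completes in well under a minute while still exercising every
  rule boundary; all scale linearly if enlarged.

# Known limitations

Single-electrode analysis only: network bursts, synchrony indices and
formal super-burst segmentation are not implemented (the last is
demonstrated descriptively via the spectrogram property). Colocalization
is two-channel and mask-based; object-based and randomization-test
variants are out of scope. Arbors must be trees (one root, no cycles);
anastomosing traces are rejected by validity checking. Vendor-proprietary
acquisition formats are not read — the package defines open CSV /
raw-float32 / TIFF / SWC contracts instead.
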