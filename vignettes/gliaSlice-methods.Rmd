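---
title: "Models and methods behind gliaSlice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gliaSlice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gliaSlice implements the quantitative analysis stack of a typical
neuroimmunology experiment in organotypic hippocampal slice cultures:
carbachol-driven gamma oscillations recorded as local field potentials
(LFP), intracellular characterization of pyramidal-cell excitability with
sharp microelectrodes, automated Iba1/DAPI microglia counting and
morphometry, and the standard-curve arithmetic of the accompanying plate
assays. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic-data validation does and does not
demonstrate.

## LFP spectral analysis

Recordings are assumed digitized at 10 kHz and analyzed in 5-min segments
(conventionally minutes 30–35 of a 40-min recording,
`extractSegment(trace, 1800, 2100)`). Segments are low-pass filtered with a
digital Butterworth at a 200 Hz corner. The filter order is not fixed by the
field's convention, so we use order 4 applied forward–backward
(`signal::filtfilt`): the effective magnitude response is the square of the
single pass and the phase is exactly zero, which keeps burst timepoints
unshifted — a prerequisite for the burst-triggered averaging below.

Power spectral density uses Welch's method with a Hamming window of
8192 samples. At 10 kHz this gives the characteristic frequency-bin spacing
of 10 000 / 8192 = 1.2207 Hz. The commonly quoted window size of 8129
points is treated as a typo for 8192, since only the power of two
reproduces that printed bin spacing; the window length remains
configurable. Overlap is 50 % (the standard Welch compromise between
variance reduction and redundancy) and detrending is per-segment mean
removal only. Scaling is Parseval-consistent: the PSD integrates to the
signal variance, so thresholds expressed in mV²/Hz are physically
interpretable.

The spectral peak is the argmax of the PSD restricted to a search band,
1–200 Hz by default: the lower edge excludes DC drift, the upper edge is
the filter corner. Ties resolve to the lowest frequency.

## Network-state classification

A segment is classified into one of four states with the precedence
NoActivity > Bursts > Gamma > LowActivity:

* **Gamma** — peak frequency above 23 Hz *and* peak power at least
  10⁻⁴ mV²/Hz (the standard rule for recordings at 34 ± 1 °C);
* **LowActivity** — lower peak frequency and/or power;
* **Bursts** — recurrent high-amplitude transients;
* **NoActivity** — absence of electrical activity.

Bursts and silence are identified visually in the original workflow, so the
package supplies automated surrogates and exposes their knobs:

* the silence criterion is an RMS below `silenceRms` (default 0.005 mV,
  read as five times a 1 µV recording-chain noise floor; an absolute
  configurable value was preferred over estimating the noise floor from the
  segment itself, which would be biased by the very activity being
  classified);
* a Bursts call needs at least `minEvents = 3` detected bursts per 5-min
  segment, and each counted burst must stand at least
  `burstAmpFactor = 2.5` times above the segment RMS. The second condition
  encodes "transients over a quiet background": a continuous sinusoid peaks
  near 1.4 × RMS, whereas sparse transients in the study conditions peak at
  3–7 × RMS, so 2.5 sits in the gap between the two regimes (measured on
  the package's own fixtures across burst rates 0.2–1 Hz).

The monotone consequence, verified by a property test, is that scaling a
gamma segment's amplitude down flips the call to LowActivity (and
eventually NoActivity), never to Bursts.

## Burst detection and burst-triggered wavelet averaging

Burst timepoints are local maxima of the rectified filtered trace whose
topographic prominence reaches 85 % of a per-segment prominence
reference. Reading the cutoff as *relative to the segment* makes detection
invariant to amplitude rescaling and to sign flips, which is consistent
with the normalization used elsewhere in the workflow; whether the
original cutoff was relative to prominence, amplitude, or an absolute
percentile is not documented. The reference itself is robust: the single
largest prominence in a segment is set by one noise excursion on top of
one event and grows with segment length, so anchoring the cutoff to it
silently discards the weaker tail of perfectly ordinary events (5–10 % of
them in validation runs). The package therefore takes the median
prominence of the peaks that clear a first, max-referenced pass as the
reference for the final cutoff. A 200 ms refractory period suppresses
double counts within one transient; prominence computation uses a
compiled scan restricted to candidates that can mathematically reach the
cutoff.

The burst-triggered spectrum is a continuous wavelet transform with
analytic Morlet wavelets (center-frequency parameter 6), evaluated on 120
log-spaced frequencies over 0.1–200 Hz; the magnitude columns at the
detected timepoints are averaged and normalized to their maximum. The grid
extends down to 0.1 Hz so that burst-recurrence rates as low as 0.2 Hz
remain resolvable as local maxima with a margin. Per frequency, events
inside the cone of influence (e-folding distance √2·s of the wavelet scale
s) of either edge are excluded from the average. L1 normalization is used,
so equal-amplitude components at different frequencies produce equal
magnitude — this is what makes the burst-rate peak and the intra-burst
peak comparable in one spectrum. The trace is decimated to ≥ 5× the highest
analysis frequency first (it is already low-pass filtered), and zero-padded
to a 2-3-5-smooth length because R's mixed-radix FFT degrades to quadratic
cost on large prime lengths.

Rhythmic bursting produces two characteristic local maxima: one at the
burst recurrence rate (the event train's fundamental; each simulated burst
carries a slow monophasic field deflection in addition to its
high-frequency packet, precisely so that this fundamental exists, as it
does in real LFP bursts) and one at the intra-burst oscillation frequency.

The burst-subtype heuristic labels a segment type 1 when the median
inter-event interval is ≤ 5 s and the mean intra-event dominant frequency
is ≥ 50 Hz, else type 2. This is an explicitly invented, documented rule:
the original taxonomy is visual and cannot be reproduced exactly.

## Intracellular metrics

Action potentials are detected where dV/dt first reaches 20 mV/ms. A
voltage-derivative criterion was chosen over an absolute voltage threshold
because the resting membrane potential shifts between experimental
conditions; 20 mV/ms is a common sharp-electrode convention. For noise
robustness the trace passes a 3-sample median filter, the derivative is
taken over a 0.2 ms span (then refined to the first single-step crossing),
the threshold voltage is read as the endpoint of a least-squares line
through the last ~1 ms of the pre-threshold trajectory (unbiased when the
approach is locally linear), and extrema (spike peak, AHP troughs) are
taken on a ~0.45 ms moving average — action-potential tops and troughs
are locally flat at that scale. Per event:
threshold = the fitted pre-threshold voltage at the crossing;
amplitude = peak − threshold;
half-width = width at threshold + amplitude/2 with sub-sample interpolated
crossings; mAHP = threshold minus the post-peak minimum before the next
AP (window capped at 50 ms and truncated at the step offset, since the
terminal spike's afterpotential merges into the post-step trajectory — for
the same reason the step-level mAHP aggregates all but the final AP).
sAHP = pre-stimulus resting potential minus the most hyperpolarized
potential within 1 s after step offset. Input resistance is Ohm's law on
the late steady-state deflection of a −0.2 nA, 200 ms pulse (mV/nA = MΩ).

The generator builds piecewise-linear spike waveforms whose threshold,
amplitude, half-width, mAHP and sAHP are exact by construction (the
downstroke slope is solved from the requested half-width), placed by a
linear frequency–current rule (100 Hz/nA above a 0.1 nA rheobase, 20 ms
first-spike latency) in regular mode, or as an adapting initial
high-frequency cluster (5 ms ISIs, geometric slowdown, terminal sAHP) in
bursting mode. Round-trip recovery therefore tests the measurement code,
not a biophysical model; conductance-based dynamics are out of scope.

## Microglia counting

The counting pipeline mirrors the standard macro sequence: maximum
z-projection; background subtraction on Iba1; DAPI binarized by the
iterative-intermeans ("default dark") threshold; the DAPI mask clears Iba1
signal without a nucleus; the remaining Iba1 is binarized the same way,
median-despeckled and outlier-cleaned; connected components of at least
400 px count as somata. The 400 px cutoff is read as a *minimum* area,
matching its stated purpose of excluding small patches where other cells'
nuclei cross microglial ramifications. Counts from the 200 × 200 µm ROI
extrapolate to density as n × 25 per mm², exactly linear in n. Background
subtraction uses a large-σ Gaussian background estimate rather than a
rolling ball (the original radius is unreported and the synthetic fixtures
have flat backgrounds); both auto-thresholds track the histogram, so the
count is invariant to affine intensity rescaling.

## Morphometry: territories, skeletons, Sholl

Soma markers come from DAPI ∩ Iba1 colocalization (pixelwise minimum)
binarized with the "minimum" algorithm; component centroids serve as the
deterministic equivalent of the find-maxima step for well-separated somata.
Somata themselves are segmented from Iba1 with a fixed high threshold
(default 0.7 of the dynamic range) standing in for the original interactive
threshold — reproducibility was preferred over fidelity to an undocumented
manual step; a triangle-method fallback is available. Binary area filtering
(> 99 px) emulates the grayscale area-attribute soma enhancement, and
components under 300 px are discarded.

Territories are assigned by marker-controlled watershed: the soma mask
dilated by a 100 px disk (computed via the Euclidean distance transform)
bounds the domain, and seeded region growing on the inverted,
σ = 1 px Gaussian-smoothed Iba1 intensity partitions it, one basin per
marker. Territories are pairwise disjoint by construction and verified to
stay within the dilated domain.

Per cell, the Iba1 signal is unsharp-masked, median-despeckled, thresholded
with the Kapur maximum-entropy rule, morphologically closed and
hole-filled (unsharp masking over-weights object rims; without filling, a
uniform soma can degenerate into a ring), reduced to the
component containing the soma (reconstruction from the nucleus seed), and
thinned to 1-px curves with the Zhang–Suen algorithm (compiled; no
installed package provides thinning). Sholl profiles sample circles at
5 µm steps from the soma radius outward; a crossing is a maximal circular
run of skeleton-occupied samples, which avoids double-counting thick
diagonal pixel steps. The area under the intersection–radius curve is the
scalar complexity summary used for phenotype comparisons.

The iterative-intermeans, minimum, Kapur and triangle thresholds are
implemented from their histogram recurrences and verified against naive
reference implementations on random histograms.

## Assays

Standard series are twofold dilutions (seven points from 8000 pg/mL for
IL-6, nine from 80 µM nitrite for the Griess reaction). Curves are linear
or quadratic least squares, with an optional automatic rule that accepts
the quadratic only when it cuts the residual sum of squares by more than
20 % — the source workflow allows both without stating a criterion.
Inversion is closed-form for lines; for parabolas the root inside the
calibrated concentration range is taken and ambiguity (both roots in
range) is an error rather than a guess. ODs outside the calibrated range
are refused as extrapolation by default. A 450 − 540 nm reference-wavelength
correction is applied before fitting when reference ODs are supplied. LDH
activity is the printed endpoint formula nmol NADH / (min × mL); a
kinetic-slope variant is deliberately not implemented.

## Synthetic data: what it does and does not show

Every generator is seeded, deterministic, and records ground truth
sufficient to score recovery without re-running it. The defaults encode the
study conditions: 300 s LFP segments at 10 kHz; gamma at 35 Hz with slow
(0.1 Hz) amplitude modulation over 1/f noise (amplitude 0.05 mV over a
2 µV noise floor — typical interface-chamber scales); bursting at 0.55 Hz
with 100 Hz intra-burst oscillations at ten times the background SD
(the amplitude calibration is a package choice; none is documented);
300 × 300 µm fields at 0.31 µm/px with 4.5 µm somata and five primary
branches of 40 µm (ramified), shortened to 35 % (de-ramified) or thickened
and shortened to 60 % (hypertrophic); microglial nuclei filling 90 % of
the soma radius, so that nucleus-masked somata remain above the 400 px
particle cutoff as they do in real tissue.

Passing the recovery suites shows that the measurement chain is correct
and internally consistent at realistic signal scales. It does not show
robustness to things the generators deliberately omit: line noise and
electrode drift, non-stationary oscillation frequency, overlapping or
intertwined microglial arbors, uneven illumination, or a realistic confocal
point-spread function. Problem sizes in the tests (segment lengths,
numbers of seeds, field sizes) were chosen as the smallest that exercise
each property convincingly.
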