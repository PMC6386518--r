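---
title: "Detecting, classifying and measuring the impact of hippocampal high-frequency oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, classifying and measuring the impact of hippocampal high-frequency oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripplesift)
```

## The scientific problem

In chronic temporal-lobe epilepsy the hippocampal CA1 network generates two
kinds of transient fast oscillation that overlap in frequency: events that
resemble the sharp-wave ripples of the healthy brain ("ripple-like",
~140-200 Hz riding on a modest sharp-wave envelope, confined to immobility),
and pathological high-frequency oscillations ("pHFOs", ~230-265 Hz riding on
large interictal spikes, indifferent to brain state). Separating the two at
the same electrode, and quantifying what pHFOs do to ongoing theta
oscillations, single-unit firing and place coding, requires a chain of signal
processing and resampling statistics. `ripplesift` implements that chain
end-to-end and ships a synthetic-session generator with ground truth, so that
every stage has a falsifiable test.

## Event detection

The pyramidal-layer LFP is band-pass filtered with a linear-phase equiripple
FIR filter (stopband 0-140 Hz, passband 150-800 Hz, stopband 810 Hz-Nyquist;
stopband ripple 5.6e-4, passband ripple 2.8e-2, error weights 51.2/1). The
filter is designed with the Parks-McClellan algorithm (`signal::remez`) at
order 0.24 x rate, which meets the ripple specification at 2 kHz (verified
against `freqz` in the test suite). Zero lag is obtained by compensating the
known group delay of the linear-phase kernel rather than by
forward-backward filtering, so the designed magnitude response applies
exactly.

A five-point (2.5 ms at 2 kHz) sliding RMS is thresholded at
mean + 3.5 SD; runs closer than 6 ms are merged (gap measured end-to-start,
boundary inclusive). Candidates must contain at least five oscillation
cycles whose peaks exceed 3 SD of the rectified band-passed signal. A peak
here is a positive local maximum of the signed band-passed trace: one peak
per cycle. Counting maxima of the rectified trace instead would yield two
per cycle and let three-cycle transients through a five-"cycle" rule, which
is the opposite of the criterion's intent. Finally each event's 100 ms
window (Hann-tapered, zero-padded to 1 s) must have its spectral peak above
150 Hz exceed the 75-125 Hz peak, which rejects fast-gamma bursts.

Threshold statistics (RMS mean/SD, rectified-signal SD) are computed per
epoch. The scope of these statistics is genuinely ambiguous in the original
description; per-epoch statistics are robust to brain-state-dependent
baseline shifts between rest and foraging, at the cost of slight
self-inflation of thresholds in event-dense epochs. The visual-inspection
step of the original workflow is replaced by the synthetic ground-truth
recovery tests.

## Classification

Two features per event: the slow-envelope amplitude (maximum absolute value
of the 500 ms peri-event segment filtered to 0.2-40 Hz) and the peak
frequency (argmax of FFT power above 150 Hz on the 2 Hz grid of the 500 ms
segment). The envelope filter is a 4th-order Butterworth applied
forward-backward; no filter family is prescribed by the method we follow, and
the zero-phase Butterworth is stable at the 0.2 Hz edge. Features are
normalised to their data-set maxima and clustered with k-means (Lloyd,
k = 2). Initial centroids default to the events with the smallest and
largest normalised envelope -- a deterministic stand-in for manually picked
density centres; we verified on synthetic sessions that the converged
partition does not depend on this choice.

Clusters are labelled against a control-ripple reference by ROC: sweeping a
criterion threshold over one scalar feature gives the usual
TPR/FPR curve whose area equals the rank-sum statistic scaled by the sample
sizes; the curve is oriented so AUC is at least 0.5. A cluster
indistinguishable from control on frequency (AUC < 0.8) is "ripple-like"; a
cluster separable on both features (AUC >= 0.8) is "pHFO". Any other
configuration is reported as an error carrying all four AUCs. The binary
neural-network classifier used in the original workflow for the same
summary is replaced by the threshold-sweep ROC it reduces to for a 1-D
feature.

## Theta dynamics around pHFOs

For pHFOs during running (>= 5 cm/s), 4 s of stratum radiatum LFP centred on
the event are analysed after clipping the central 200 ms (replaced by the
recording mean) to keep the interictal spike out of the spectrogram. Morlet
wavelets (six cycles, 4-20 Hz at 0.5 Hz steps, L1-normalised so a sinusoid
of amplitude A gives power ~A^2) provide mean 7-11 Hz power in three
windows: baseline (-2 to -1 s), before (-0.6 to -0.1 s) and after (+0.1 to
+0.6 s); running speed is averaged over the same windows.

The theta phase at pHFO onset is estimated by a two-filter extrapolation.
The 2 s before the event are truncated at the interictal-spike onset,
located automatically as the last departure from baseline exceeding 2 SD
that persists until the spike peak (a deterministic proxy for the manual
picking in the original workflow; it may shift onsets by a few
milliseconds). Events whose spike stays below 5 SD of the first second are
excluded. The truncated signal is band-passed at 4-12 Hz with a zero-phase
and a causal 4th-order Butterworth filter; instantaneous phases come from
the FFT analytic signal. The circular-mean offset between the two phase
series over the interior (250 ms clear of each end) corrects the causal
phase, which is then fitted linearly over the last six theta cycles and
extrapolated to the truncation point. Phase 0 is the theta peak, increasing
in time, reported in [-pi, pi). On noiseless 8 Hz sinusoids the estimator is
accurate to < 0.04 rad across truncation phases; at 20% additive noise the
circular-mean error stays well below 0.5 rad.

## Unit modulation and spatial coding

Spikes within +-500 ms of each event are binned at 20 ms; each event is one
observation. Baseline (mean rate 500-400 ms before) and during-event rate
(100 ms centred on the event, computed on exact window edges from the raw
offsets since the 20 ms grid does not align with +-50 ms) are compared with
a two-sided Wilcoxon signed-rank test; a unit is modulated at p < 0.05 with
at least 10 events. All-tied pairs give p = 1 (not modulated). No
multiple-testing correction is applied across units, matching the per-unit
criterion of the source analysis. The test holds its nominal level: over
1000 simulated null units (5 Hz Poisson, 50 events) the false-positive
fraction is 0.05 +- 0.02.

Rate maps use 5 x 5 cm bins anchored at the bounding-box corner of the
epoch's path, raw rate = spikes/occupancy, smoothed with the fixed 5 x 5
Gaussian kernel (SD ~ one bin, sums to exactly 1). Bins never within 2.5 cm
of the path or occupied under 150 ms are unvisited; smoothing is
renormalised over the visited support so no rate leaks into unvisited
territory (the alternative order -- smooth first, mask later -- is
defensible; ours avoids boundary bias). Derived metrics: Skaggs spatial
information per spike, spatial sparsity, split-half stability (epoch split
at its temporal midpoint, both halves binned on the full-epoch grid), and
the active-unit proportion (peak rate > 2 Hz). Speed is computed from
positions smoothed with a 250 ms moving average (window our choice).

## pHFO spatial impact

Event-position maps use the identical binning/smoothing machinery; sessions
need more than 15 pHFOs. The spatial information of the event map is
compared with a null built by redrawing the event times uniformly from the
epoch's tracked samples (occupancy-weighted; drawing uniformly in clock time
would confound the null with the occupancy distribution) 1000 times; the
5th-95th percentile band classifies the actual value as inside/above/below.
By construction a uniform event process falls inside the band ~90% of the
time, which the tests verify over 200 independent sessions.

Targeted down-sampling removes the spikes inside the 100 ms core of each
pHFO (the same "during" window as the modulation test, for consistency) from
a unit with at least 1% of spikes in pHFOs, and compares the resulting
change in spatial information against 1000 equal-count random removals; the
improvement is significant above the 95th percentile (the cutoff is our
operationalisation of "greater than expected by chance"). The
improvement-versus-fraction relationship is summarised by OLS over
significant units only.

Group-level statistics: the 2 x 2 chi-square uses the closed-form Pearson
statistic without continuity correction (required to reproduce the worked
contingency examples), and multi-group comparisons gate on the Lilliefors
normality test between parametric (t/ANOVA + Tukey HSD) and rank-based
(rank-sum/Kruskal-Wallis + Tukey-Kramer on ranks) branches.

## The synthetic-session generator

The generator is first-class, tested code; its defaults are the study
conditions every property test runs under.

* **Sessions**: rest 300 s, foraging 600 s, rest 300 s; LFP at 2 kHz
  (inferred from the five-point/2.5 ms RMS window; the original sampling
  rate is not stated); tracking at 30 Hz; circular 1 m arena (or 0.8 m
  square), 20 x 20 cm rest box beside the arena.
* **Trajectory**: Ornstein-Uhlenbeck velocity (0.7 s correlation time)
  steered toward waypoints drawn preferentially from not-yet-visited 5 cm
  bins and reflected at the walls -- emulating search for scattered food.
  The velocity scale is calibrated so the realised median speed matches the
  6.4 cm/s target; waypoint steering reproduces the near-complete (>= 95%)
  bin coverage of real 10 min foraging, which a plain reflected OU walk
  does not.
* **Events**: ripples at 0.3/s of immobile time (speed < 5 cm/s, the same
  cut used for the theta analysis), pHFOs homogeneous at 0.1/s, 500 ms
  minimum gap, 1 s margin from epoch edges. Class parameters are calibrated
  to the measured feature medians: 185.8/245.9 Hz oscillation frequency and
  244.9/520 uV envelope for ripple/pHFO. Only pooled cross-session IQRs are
  printed for these features; a single session is narrower, so the
  generator attributes 25% of the pooled variance to within-session spread
  (frequency SD 8.15/11.25 Hz, envelope sdlog 0.299/0.172). This is the
  compactness a two-population density plot of a single session displays,
  and it is required for any Euclidean k-means to meet the 95%
  class-recovery contract; the per-session amplitude CV of 0.3 is kept
  exactly as printed for control sessions. Band-passed amplitudes (median
  130/260 uV, CV 0.3, log-normal) and 12 cycles per burst give 65/49 ms
  events, in the range of observed ripple/pHFO durations.
* **Waveforms**: Hann-windowed sinusoid bursts; sharp waves are negative
  Gaussian bumps (40 ms SD), interictal spikes biphasic
  derivative-of-Gaussian transients (25 ms scale) shared across both LFP
  channels. Envelope amplitudes are defined in *measured* units: each
  transient is scaled by the reciprocal of its template's peak response
  through the 0.2-40 Hz measurement filter, so a scheduled 520 uV envelope
  is recovered as ~520 uV by the classifier.
* **Radiatum channel**: 8 Hz theta, 150 uV, amplitude gated by speed
  (s/(s+2)); theta amplitude is suppressed by 80% from 0.1 to 0.8 s after
  each pHFO. Pyramidal noise is white Gaussian at 12 uV SD -- chosen so
  ~95% of scheduled events exceed the 5 x noise floor the detection
  contract is conditioned on; at 15 uV too many legitimate events sit below
  the five-cycle criterion.
* **Spikes**: inhomogeneous Poisson by thinning; rate = baseline (0.2 Hz) +
  Gaussian place field (10 cm SD, 5 Hz peak) at the animal's position,
  multiplied by the unit's gain (5) inside the 100 ms core of events of a
  class the unit is modulated by. Unit categories default to 60%
  ripple-only / 12% pHFO-only / 28% both, the observed overlap proportions.

What the generator does **not** emulate: 1/f background structure, theta
harmonics and phase-amplitude coupling, spike waveforms and sorting errors,
place-field remapping or directionality, behavioural states beyond
immobile/mobile, and any within-event fine structure (phase-locked spiking).
Passing tests therefore demonstrate correctness of the analysis chain under
the stated statistical structure, not performance on raw animal data.

## Numerical choices and degenerate inputs

FFT-based convolution for filtering and wavelets; spectra on a 1 Hz grid
(detection validation) or 2 Hz grid (classification). k-means runs to a
1e-6 relative tolerance with at most 300 Lloyd iterations; identical
feature vectors raise a degenerate-clustering error. ROC ties are handled
by the trapezoid rule (AUC equals the tie-corrected rank-sum statistic).
Zero-rate maps make information/sparsity undefined and raise errors rather
than returning NaN; all-tied signed-rank pairs report p = 1. Sessions
without pHFOs skip the impact stage and label every event ripple-like after
confirming both clusters overlap the control reference.

## Problem sizes

The test-suite and acceptance defaults run single-CPU in a few minutes:
1200 s sessions at 2 kHz (~300 events, 30 units), 1000-shuffle nulls,
200-session coverage calibrations, 1000 null units for the signed-rank
level, and 20-session down-sampling calibrations. These sizes give the
binomial checks enough resolution for their stated tolerances (e.g.
coverage 0.90 +- 0.04 over 200 sessions) while staying desk-scale.

## Known limitations

* Detection thresholds are estimated from statistics that include the
  events themselves; in extremely event-dense epochs recall of the
  smallest events drops (the recovery contract holds at default rates).
* The automated interictal-spike onset detector replaces manual picking
  and can shift onsets by a few milliseconds, which propagates to the
  extrapolated onset phase.
* The k-means feature plane uses global max-normalisation; a single
  extreme envelope outlier compresses that axis for all events.
* The shuffle null redraws event times over tracked samples; if tracking
  has systematic gaps the occupancy weighting inherits them.
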