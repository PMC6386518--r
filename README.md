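# ripplesift

Detection, classification and impact analysis of hippocampal
high-frequency oscillations (HFOs) in chronic epilepsy.

In temporal-lobe epilepsy the CA1 network produces two co-occurring kinds
of fast oscillation: **ripple-like** events that resemble healthy
sharp-wave ripples (~140-200 Hz on a modest sharp-wave envelope, during
immobility) and **pathological HFOs (pHFOs)** (~230-265 Hz riding on large
interictal spikes, at any running speed). `ripplesift` is for
electrophysiologists who need to separate the two at a single electrode
and quantify what pHFOs do to theta oscillations, single-unit firing and
place coding. It implements:

* **Detection** — 140-800 Hz equiripple band-pass, five-point sliding RMS
  thresholded at mean + 3.5 SD, 6 ms merging, a five-cycle amplitude
  criterion, and spectral validation (peak power above 150 Hz must exceed
  the 75-125 Hz peak).
* **Classification** — per-event slow-envelope amplitude (0.2-40 Hz, 500 ms
  window) and peak frequency, k-means into two populations, and labelling
  against a control-ripple reference by ROC (acceptable discrimination at
  AUC >= 0.8).
* **Theta dynamics** — Morlet-wavelet 7-11 Hz power in baseline / before /
  after windows around pHFOs, with the interictal spike clipped out, and
  the theta phase at pHFO onset via causal/zero-phase Butterworth
  extrapolation over the last six cycles.
* **Unit modulation** — peri-event 20 ms rate vectors; Wilcoxon signed-rank
  between baseline (-500 to -400 ms) and during-event (100 ms core) rates;
  overlap categories across event types.
* **Spatial coding** — 5 cm rate maps with the fixed 5 x 5 Gaussian kernel,
  Skaggs spatial information
  `I = sum_i P_i (R_i/R) log2(R_i/R)` (bits/spike), sparsity
  `(sum P_i R_i)^2 / sum P_i R_i^2`, split-half stability, active-cell
  proportion (peak > 2 Hz).
* **pHFO spatial impact** — event-position maps with a 1000-draw
  occupancy-weighted shuffle null (5-95 percentile band), and targeted
  removal of pHFO spikes versus 1000 equal-count random removals.
* **Synthetic sessions** — a generator for complete sessions (both LFP
  layers, spikes, tracking, epochs) with ground-truth event times, classes,
  place fields and modulation flags, so the whole chain is testable
  without animal data.

## Worked example

```r
library(ripplesift)

ses <- simulate_session(session_spec(), seed = 1)
ses
#> hfo_session: 1200 s, 3 epochs, 30 units, 297 scheduled events (phfo=107, ripple=190)

rep <- run_session(session = ses, seed = 1)
#> detection: 282 events
#> control reference: 194 events
#> classification: 168 ripple-like, 114 pHFO
#> theta: 42 pHFO events analysed, 34 with onset phase
#> epoch 2: pHFO map info 0.306 bits (inside the shuffle band)

rep
#> session_report
#>        label   n freq_median_hz freq_iqr_lo freq_iqr_hi env_median_uV
#>         pHFO 114       247.7522    238.2617    253.7463      497.2723
#>  ripple-like 168       185.8142    179.8202    191.8082      249.3151
#> amplitude CV: 0.452
#> proportion modulated: pHFO 0.33, ripple-like 0.80
#> active units: 1.00; median info (active): 0.93 bits
```

Reading the output: detection recovered 282 of the 297 scheduled events;
classification split them into a ~186 Hz / ~249 uV ripple-like population
and a ~248 Hz / ~497 uV pHFO population (the generator schedules 185.8 and
245.9 Hz with 244.9 and 520 uV envelopes). The session-level amplitude CV
of 0.45 reflects the two co-occurring amplitude populations; single-class
control sessions sit near 0.3. 80% of units are modulated by ripple-like
events versus 33% by pHFOs, and the pHFO positions carry no more spatial
information than their shuffle null ("inside the shuffle band"), i.e. they
occur at random locations.

Individual stages are exported (`detect_hfo()`, `classify_events()`,
`theta_around_events()`, `unit_modulation()`, `build_rate_map()`,
`shuffle_event_info()`, `targeted_downsample()`, ...) and a thin CLI lives
at `inst/cli/ripplesift.R` (`simulate`, `detect`, `run-all`). On-disk
formats are plain: float32 LFP with JSON sidecars and headered CSV tables.

## Documentation

The methods vignette (`vignettes/ripplesift-methods.Rmd`) describes the
models and procedures, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and the
package's numerical choices and limitations.
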