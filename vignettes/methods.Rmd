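---
title: "Detecting seizure-related events in two-photon calcium imaging: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting seizure-related events in two-photon calcium imaging: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ictal2p)
```

## The problem

Chemoconvulsant (e.g. pentylenetetrazol) seizure models produce a stereotyped
sequence visible in awake two-photon calcium imaging with simultaneous EEG:
sporadic **pre-ictal spikes** (PIS) — brief synchronous population discharges
that appear as spike-wave discharges (SWDs) on EEG and as sharp population
calcium transients; a fast **ictal wavefront** that invades the imaged field
as a traveling wave and leaves cells on a sustained calcium plateau; and,
minutes later, a slow **terminal spreading wave** consistent with cortical
spreading depolarization. Epilepsy microcircuit questions (recruitment order,
inhibitory restraint, propagation geometry) need the *time each cell joins
each event* — on single trials, with no repeated-trial averaging to lean on.

`ictal2p` detects these events at the population level, uses the population
times as *seeds* to guide per-cell recruitment detection, evaluates the result
against manual labels, and fits a plane to per-cell recruitment times to
estimate traveling-wave velocity and direction. A paired synthetic-recording
generator with exported ground truth makes every stage testable offline.

## Signal substrate

**Normalization** (`preprocess_traces`). Suite2p-convention somatic and
neuropil fluorescence traces are background-subtracted using a single scalar
per recording — the global minimum over all neuropil samples, a proxy for the
non-biological offset — then neuropil-corrected (`soma - 0.7 * neuropil`,
both background-subtracted) and normalized as ΔF/F0 with F0 the mean of the
first 30 s of the corrected trace. The order (background before the 70%
subtraction) keeps corrected traces nonnegative at the global minimum; cells
whose F0 is not positive cannot be normalized and are flagged invalid rather
than silently dropped. A neuropil F0 of zero only invalidates that cell's
neuropil trace (it still participates in somatic detection).

**Zero-phase filtering** (`zero_phase_lowpass`). All detection operates on
traces low-passed at 1 Hz with a Butterworth filter applied forward and
backward, which cancels the phase response so that event times are not
displaced — essential when the deliverable *is* a time. The filter is designed
by the standard bilinear transform (coefficients agree with reference
implementations to machine precision) and applied with odd-reflection edge
padding of about three filter time constants; the level of the first padded
sample is subtracted before each pass so the zero-initial-state transient
scales with local signal variation, not absolute signal level. The order is
adaptive over 3–5: order 5 is tried first and decremented if the output is
non-finite or its energy exceeds the input's by more than 1% (instability at
low normalized cutoffs). The criterion is ours; only the order range is given
by the method.

**Slope-integral feature** (`positive_slope_segments`). Events are rises.
Each maximal run of strictly positive first differences is a candidate
segment, scored by the *slope integral* — the integral of the first
derivative over the run, which telescopes to the net rise. The feature
jointly rewards steep slope, high peak and long rise, which separates real
calcium events from brief noise fluctuations of similar instantaneous slope.
Each segment is indexed at its point of steepest slope (the convention used
for recruitment times throughout, matching how an expert labels traces).

## Population-level seeds

**Wavefronts** (`detect_wavefronts`). On the filtered population-mean
neuropil trace, the two contiguous supra-half-maximum intervals with the
largest trace integrals are the seizure (earlier) and terminal wave (later),
each indexed at the interval's first upward half-max crossing. Ties break by
temporal order; with fewer than two intervals (fatal seizure, truncated
recording) whatever exists is returned with a warning. The half-max is taken
on the filtered trace, consistent with the rest of the pipeline. Note the
detector *assumes a seizure recording*: on a recording with no seizure it
will promote the largest transient instead.

**Pre-ictal spikes** (`detect_population_spikes`, `reconcile_with_eeg`).
PIS detection runs on the population-mean *neuropil* ΔF/F0 — pre-ictal
spikes are more prominent in space and time in the neuropil than in single
somata — restricted to the pre-ictal portion (before the seizure seed), since
the ictal rhythmic discharge would otherwise be re-detected as spikes.
Candidate segments in the top 15% by slope-integral are thresholded by
comparing the *event-period integral* (trace minus its value at segment
start, integrated until it returns to that level or the next rise begins)
against the area of a Gaussian model spike with height one trace SD and
σ = 0.33 s (±1.5σ width ≈ 1 s) — a typical physiologic spike weight. Two
numerical choices here are ours and worth stating:

* the comparison integral covers the full event period, not the rising
  segment alone: the model area `h·σ·√(2π)` is a *full* Gaussian area, and a
  rising-only integral is systematically about half the event's area, which
  at realistic indicator kinetics under a 1-Hz low-pass falls below the model
  area even for unambiguous spikes;
* the rank cut keeps, in addition, any segment already meeting the model
  threshold. The 15% cut is computational triage that assumes noise dominates
  the segment population; on near-noise-free traces (synthetic validation)
  the only segments are real events and a pure rank cut would discard them.
  On noisy traces the rank cut dominates and behavior is unchanged.

On EEG, candidate SWDs are amplitude-threshold detections (4.5 robust SDs —
median absolute deviation × 1.4826 — of the full trace, indexed at the local
absolute-value peak, ≥ 0.7 s apart), then screened by a spectral ratio:
Welch band power at 3–15 Hz in a 1-s window starting 0.25 s before the peak,
divided by 20–55 Hz power in the subsequent 1-s window, must reach 20, and
survivors closer than 0.7 s to their predecessor are dropped (earlier kept).
The exact window placement and Welch parameters (0.5-s Hann segments, 50%
overlap) are our reading of "subsequent adjusted low-gamma power".

Calcium candidates and EEG spikes are then paired one-to-one (greedy by
ascending time difference) within 0.2 s; each pair contributes the *EEG*
time — the sharpest, least variable feature of the SWD. Finally, a matched
kernel (mean EEG segment ±0.5 s around the concordant spikes) is correlated
against the EEG; local maxima ≥ 5 SD above the correlation baseline, ≥ 1 s
apart and not within 0.5 s of an existing spike are appended as
`kernel_recovered` — recovering low-amplitude spikes whose waveform is
nevertheless physiological.

## Per-cell recruitment

**Pre-ictal spikes** (`detect_cell_pis`). Per cell, segments in the top 20%
by slope-integral (never fewer than the number of seeds — same degenerate-
regime floor as above) are paired one-to-one with seeds, nearest first. A
cell is recruited when its candidate lies within 1.5 s of the seed and the
segment peak exceeds the cell's center by 4 spreads. Center and spread are
the **median and scaled MAD** of the pre-ictal portion of the filtered trace
(up to the seizure seed minus 10 s; ictal plateaus would otherwise inflate
the statistics). The robust pair rather than mean/SD is a deliberate
deviation: in the near-noise-free regime the plain SD consists entirely of
the sparse events being detected, pinning the largest events at z ≈ 4
regardless of amplitude; MAD × 1.4826 equals the SD on the noise-dominated
traces where the published rule operates, and robust SD is already the
convention in the EEG threshold stage.

**Wavefronts** (`detect_cell_wavefront`). Per cell, every segment's
slope-integral is weighted by a Gaussian of its distance to the seed — σ =
1 s for the seizure (narrow, so the *sentinel spike* that often precedes
ictal invasion by a few seconds cannot capture the detection) and σ = 5 s for
the slower terminal wave. The maximum-weighted segment's steepest-slope time
is the recruitment time; recruitment additionally requires a ≥ 20% increase
in mean signal from the window before to the window after that time (10 s for
seizures, exploiting the sustained plateau; 5 s for terminal waves, where
inter-event calcium levels vary more) and a seed distance within 3 s
(seizure) or 5 s (terminal). The mean-ratio rule is evaluated exactly as
stated; near a zero baseline it can behave erratically for non-participating
cells (a known limitation of a ratio criterion on ΔF/F0 ≈ 0 signals).

## Evaluation

Manual and detected times are matched chronologically, nearest-unused within
1 s; unmatched manual events are false negatives, unmatched detections false
positives. Accuracy is TP/(TP+FP+FN) — there is no meaningful true-negative
count for sparse events, so chance level is far below 0.5. F1 is the
geometric mean of precision and recall, `sqrt(TP/(TP+FP) · TP/(TP+FN))`; the
source arithmetic is typeset ambiguously (product vs geometric mean of the
two ratios) and the geometric mean, consistent with the printed per-recording
values, is the default with the product available as an option. The greedy
matcher is the published procedure; it equals optimal bipartite matching at
realistic event spacing but can fall one short in adversarially crowded
configurations (the test suite checks it against a brute-force oracle).

The chance baseline simulates a homogeneous Poisson process at the manual
events' empirical rate and reports mean F1 over repetitions (50 by default);
at rate λ with a ±1-s window this approximates `1 − exp(−2λ)` ≈ 0.095 at
λ = 0.05 Hz, matching the published baseline of 0.098. Per-cell SNR is the
mean height of peaks with topographic prominence > 1 ΔF/F0 in the pre-ictal
window divided by the 40th-minus-10th percentile spread (outlier- and
peak-free noise estimate); note the absolute prominence cut means SNR is
scale-invariant only while the qualifying peak set is unchanged.

## Traveling-wave model

Per-cell recruitment times are regressed on cell positions, `t ≈ β0 + βx·x +
βy·y`, with an L1 penalty on the gradient (intercept unpenalized; glmnet
backend). The gradient is the slowness vector: speed = 1/‖(βx, βy)‖ (μm/s),
direction = gradient direction (times increase along propagation), reported
counter-clockwise from +x in degrees after converting image coordinates to a
right-handed frame. λ = "auto" uses 5-fold cross-validation on glmnet's
logarithmic grid, falling back to OLS below 10 cells (the source gives no λ).
Significance comes from permuting times across positions and refitting at the
observed fit's λ: `p = (1 + #{shuffled RSS ≤ observed}) / (1 + n_shuffles)`,
so 199 shuffles bound p below by 0.005. The published angle convention for
its example fits (0° and 152°) is not stated and no attempt is made to match
it numerically; rotation-equivariance and translation-invariance of our
convention are property-tested instead.

## The synthetic world

`sim_config()` / `generate_recording()` state the validation world once:

| parameter | default | basis |
|---|---|---|
| frame rate / EEG rate | 30 Hz / 2 kHz | acquisition standard for resonant scanning + EEG |
| PIS rate, participation | 3/min, 0.8 | published pre-ictal regime |
| PIS amplitude | 1.2–2 ΔF/F0 per cell | above the 1-ΔF/F0 SNR prominence cut |
| per-cell jitter | SD 0.05 s | sub-frame-scale synchrony of SWDs |
| indicator kinetics | rise 0.1 s, half-decay 1.4 s | jYCaMP1s-like (0.4 s for jRGECO1a-like) |
| sentinel spike | 2–4 s before onset | the wavefront-detection confound |
| seizure | 421 μm/s planar wave, 3 ΔF/F0 plateau, 20 s | published example regime |
| terminal wave | 68 μm/s, 2.5 ΔF/F0, rise 1 s, decay τ ≈ 8.7 s | spreading-depolarization-like slow large transient |
| EEG | AR(1) 1/f²-like background; biphasic SWD (30-ms spike + 120-ms wave) at 10 noise SD; 6-Hz ictal discharge | SWD phenomenology |

Somata receive white + shared noise and slow drift; each neuropil trace
carries 80% of the clean population-mean signal plus its own noise, so the
population-mean neuropil shows PIS more prominently than single somata — by
construction, mirroring why the detector uses it. Raw fluorescence is
reconstructed by inverting the normalization with known baselines and the
70% coupling, so preprocessing is genuinely exercised. Ground truth exports
both planted parameters and *label times* — the steepest-slope times of the
clean filtered traces, i.e. what an ideal labeler marking the point of
maximum slope would record; detections are compared against label times, as
manual scoring would be.

What the generator does **not** emulate: motion and z-drift artifacts,
F0 shifts at convulsive onset, scanning shot-noise statistics (noise is
Gaussian), variable SWD morphology, and multiple seizures per recording. A
green test therefore establishes algorithmic correctness on the stated
phenomenology, not robustness to acquisition pathology.

## Numerical and degenerate-input choices

* Frames map to seconds as `t0_offset + frame/frame_rate` (0-based), EEG
  clock canonical.
* First derivative = forward difference × frame rate; "positive slope" is a
  strictly positive difference; segment index times sit on the earlier frame
  of the steepest difference.
* Flat EEG (zero robust SD) → empty spike set with a warning; zero concordant
  spikes → kernel recovery skipped and logged; windows crossing record edges
  are truncated with a warning.
* Monotone-nonincreasing traces yield no segments, hence "not recruited"
  everywhere rather than errors.
* Collinear positions or < 3 finite recruitment times are errors in the wave
  fit; a zero gradient reports undefined velocity with p forced to 1.
* All randomness (generator, bootstrap, Poisson baseline, shuffles, CV folds)
  is seed-controlled; rerunning a pipeline on the same inputs is bitwise
  deterministic.

## Known limitations

* The per-cell mean-ratio (20% increase) rule is unstable when both window
  means are near zero; it is kept as published.
* The spectral-ratio screen depends on our window placement reading; the
  configurable `ratio_min`, window and band edges allow retuning for other
  models.
* The L1 velocity estimate inherits a small shrinkage bias (gradient shrinks,
  speed inflates) when cross-validation selects a nonzero λ; at the published
  example regime this stays within a few percent.
* Detection quality degrades with SNR (quantified by the SNR–F1 regression);
  very low-SNR cells are detectable mainly through the EEG-reconciled seeds.
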