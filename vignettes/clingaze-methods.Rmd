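---
title: "Methods: gaze-event detection, ROI attention and the synthetic experiment model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-event detection, ROI attention and the synthetic experiment model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clingaze)
```

`clingaze` analyses mobile eye-tracking experiments on clinician interaction
with AI decision support: physicians in a simulation suite prescribe fluid
and vasopressor doses for septic patients, see an AI recommendation with four
explanation (XAI) panels — safe in four of six scenarios, deliberately
extreme and unsafe in two — and then confirm or revise their doses. This
vignette documents the models and the numerical and design choices behind
each stage, and what the synthetic-data tests do and do not establish.

## Coordinate and time conventions

Gaze and ROI boxes live in normalized world-view coordinates: origin at the
top-left of the scene camera frame, x rightward, y downward, the world-view
being the unit square. Gaze may fall outside the unit square (off-world);
such samples are flagged at ingest but never clipped or dropped. Timestamps
are milliseconds from session start; inputs recorded in seconds are converted
at ingest via the reader's `time_unit` flag, which avoids float-precision
surprises at a 120 Hz sampling rate. Samples below the confidence flag
threshold are *flagged, not deleted*: blink detection is driven precisely by
those low-confidence stretches.

## Fixation detection (I-DT)

A fixation is the period when the eyes cease scanning and hold the foveal
area in one place. Commercial headset software detects these with
undocumented parameters, so the package uses the transparent standard
dispersion-threshold algorithm (I-DT): a maximal window of consecutive
samples, all at or above `min_confidence`, is a fixation iff its time span is
at least `min_duration` and its dispersion
\((\max x - \min x) + (\max y - \min y)\) stays within
`dispersion_threshold`. Windows grow greedily left to right; a sample that
could either extend the current window or begin the next one extends the
current one (deterministic, canonical I-DT behaviour), and windows never
overlap. Dispersion is non-decreasing as a window grows, which is what makes
the greedy scan equivalent to exhaustive search — the test suite checks that
equivalence against a brute-force oracle over all contiguous windows on
streams of up to 50 samples.

Defaults: `dispersion_threshold = 0.03` normalized units,
`min_duration = 80` ms, `min_confidence = 0.6`. An 80 ms floor permits the
~135 ms mean fixation durations typical of this task; 0.03 normalized units
corresponds to roughly 1.5–2° of visual angle for a scene camera with a
~60° horizontal field of view. All thresholds are exposed through
`detection_params()` and the pipeline config; none are hard-coded.

## Blink detection

Blinks are maximal runs of samples whose pupil-detection confidence falls
below `confidence_threshold` (default 0.5). Runs separated by gaps shorter
than `merge_gap` (20 ms) merge, absorbing momentary half-open-eye
recoveries. Merged runs shorter than 50 ms are discarded as noise; runs
longer than 500 ms exceed physiological blink durations and are counted
separately as tracking signal loss, never as blinks. Onset is the first
low-confidence sample; offset is the recovery time (first confident sample
after the run), so a 150 ms dip yields a 150 ms blink. Because the eyes are
closed during a blink, ROI attribution uses the last confident gaze point
before onset — the standard pre-blink-locus proxy.

## Hierarchical ROI attention

ROIs form a forest: mannequin, vital-signs monitor, paper ICU chart and AI
screen at the top level, with the AI-recommendation panel and four XAI
panels nested inside the AI screen. Boxes are sampled at video frame times
and held between frames (zero-order hold); before the first observation or
when flagged invisible an ROI is simply not visible. A gaze point is
assigned to the *smallest-area* visible ROI containing it plus all of that
ROI's ancestors, so panel gaze also counts as AI-screen gaze. Containment is
half-open (`x_min <= x < x_max`), which makes the four abutting panel
quadrants a partition — no point can belong to two panels. Area ties resolve
to the lexicographically smallest `roi_id`, a deterministic tie-break that
only matters for pathological overlapping layouts.

Per trial and ROI the summary reports gaze time (each sample contributes its
interval to the next sample, capped at twice the nominal period so tracking
dropouts do not inflate dwell), fixation count (attributed by the centroid at
the fixation's temporal midpoint — robust to box motion within the fixation;
a majority-of-member-samples variant would be a straightforward alternative
but midpoint attribution is the default), mean fixation duration (missing
when no fixation lands in the ROI), and blink rate. The blink-rate
denominator is the ROI's *own* gaze time rather than trial time: a
blinks-per-minute-of-dwell rate is the only version comparable across ROIs
with very different dwell. Gaze inside no ROI accumulates in an implicit
`elsewhere` row so gaze proportions over mutually exclusive top-level
regions sum to one.

### Chance-gaze correction

ROIs differ hugely in size, and participants move around the room, so raw
gaze proportions are not comparable across ROIs. The chance («visual
real-estate») baseline is the gaze share an ROI would receive from gaze
falling uniformly over the world-view: the time-weighted mean of the box
area clipped to the unit square, counting zero while invisible. The headline
quantity is the ratio of actual to chance gaze — 1 means an ROI draws
exactly what its footprint predicts. The test suite verifies the ratio is 1
within Monte-Carlo error for every ROI under 10^5 uniformly scattered
samples.

## Behaviour metrics

For initial (pre-reveal) dose \(P\), final dose \(F\) and AI advice \(A\):

* **Influence of AI** (weight on advice): \(I = (F－P)/(A－P)\), 0 = advice
  ignored, 1 = advice adopted. The metric is undefined when the advice
  essentially equals the prior estimate; the package treats
  \(|A－P| \le \varepsilon\) as undefined with per-drug tolerances of 1 ml/h
  (fluid) and 0.01 mcg/kg/min (vasopressor), counts such trials in QC, and
  excludes them from influence analyses. Because physicians can overshoot
  the advice or move away from it, the raw value can leave \([0, 1]\); the
  headline metric is winsorized to \([0, 1]\) by default and the raw value
  is kept alongside, so either convention can be analysed.
* **Practice variation**: \(v_i = |d_i - \bar d|\), the physician's absolute
  distance from the group-mean pre-reveal dose for that scenario and drug — a
  proxy for outlier prescribing. The mean includes the physician's own dose
  (the group average); a leave-one-out variant is available as an option.
* **Advice distance**: \(|F - A|\), a nonparametric adherence measure that
  needs no denominator.

Influence is invariant to affine rescaling of dose units; this is tested
property-style.

## Statistical layer

Safe-vs-unsafe comparisons use the independent two-sample *Student's*
(pooled-variance) t-test — Welch's correction is available but not the
default, matching the experiment's own analysis convention — with two-sided
p-values throughout and per-group 95% CIs from each group's own standard
error. Whether trials may be pooled across participants (independence) is
an assumption the data cannot settle at n = 19, so the report emits the
AI-screen comparison at both the trial level and on participant means,
labelled. Correlations are Pearson product-moment (Spearman optional) with
p from the t transform. Post-hoc power uses the noncentral t distribution
with noncentrality \(d\sqrt{n_1 n_2/(n_1+n_2)}\); an equal-n cross-check
against `power.t.test` and a 10^5-replicate Monte-Carlo oracle back it in
the tests. No multiple-testing adjustment is applied anywhere, and the
report footer states this.

The rating-vs-attention correlation (self-reported XAI usefulness against
fixations on that panel) is reported at two aggregation levels: per panel on
participant means, and pooled across the four panels at trial level. The
pooled trial-level variant is the better-powered summary of "does subjective
usefulness track objective attention" and is the one used in the acceptance
checks; per-panel values are emitted alongside.

## The synthetic experiment generator

The generator emulates the full study design so that every pipeline stage
can be exercised against known ground truth: 19 participants x 6 scenarios
(4 safe, 2 unsafe, first trial always safe, unsafe order varying across
participants), 120 Hz gaze, 5.4-minute trials (324 s, the study's mean
scenario completion time), and per-trial prescriptions.

**Gaze dynamics.** Each trial is an alternating sequence of fixations and
saccades. Fixation targets are drawn from the trial's attention weights;
centroids are uniform within the chosen ROI box (or, for `elsewhere`,
uniform outside all boxes); durations are lognormal with per-ROI means
(135 ms mannequin, 150 ms elsewhere, matching the reported scale) truncated
at a 90 ms physiological floor; within-fixation jitter is Gaussian with
SD 0.003 so long fixations stay inside the 0.03 dispersion threshold.
Saccades interpolate linearly over 30–80 ms. Blinks are inserted in the
inter-fixation gaps (physiologically, blinks co-occur with gaze shifts) as
confidence dips with lognormal durations truncated to 60–450 ms, at per-ROI
rates taken from the reported per-ROI blink rates (chart 6.1, mannequin
14.7, monitor 15.2, AI surfaces 19.9 bpm). Placing blinks between fixations
keeps the planted event list exactly consistent with the emitted stream.

**Scene and head motion.** The static layout gives the mannequin 12% of the
world-view, the chart 9%, the AI screen 6% (a recommendation strip plus four
panel quadrants) and the monitor 1.8%; combined with the attention weights
below this reproduces the reported actual-to-chance ratio ordering (monitor
highest, mannequin near 1). All boxes drift jointly under a capped Gaussian
random walk sampled at 5 Hz — the scene moves as the head moves — which
exercises the zero-order-hold box lookup; the walk is capped at ±0.04 so the
scene never leaves the view (at the cap the walk saturates rather than
reflecting, an acceptable simplification for these amplitudes). Panel
positions rotate between trials, so hit-testing cannot assume a static
layout.

**Attention model.** Attention is hierarchical: a participant draws stable
major-surface shares (mannequin/monitor/chart/AI-screen/elsewhere, expected
values 0.156/0.225/0.144/0.390/0.085) from a Dirichlet with concentration
17, and a stable within-AI-screen split (recommendation 0.574, each panel
0.1065) with concentration 50; each trial re-draws both around the
participant profile with concentrations 31 and 28. These four
concentrations were calibrated once, a priori, to the study's reported
dispersion: the participant-level and trial-level SDs they imply for
AI-screen fixation counts (~0.115 and ~0.086 in share units) reproduce the
reported 95% CIs for safe (704 [593, 814]) and unsafe (962 [861, 1063])
AI-screen fixations at n = 19, and the panel-level split reproduces the
per-panel CI width (75 [59, 90]). Under an unsafe recommendation the
*expected AI-screen share* is multiplied by `unsafe_ai_multiplier`
(default 962/704 ≈ 1.37, the reported unsafe/safe fixation-count ratio) and
the non-AI shares rescale so the total stays 1 — hence the planted ratio of
expected AI-screen fixation counts between conditions equals the multiplier,
and setting it to 1 plants exactly equal attention.

**Prescribing model.** Scenario reference doses (fluid 100–500 ml/h,
vasopressor 0.10–0.40 mcg/kg/min) act as the clinical consensus. Pre-reveal
doses are Gaussian around the reference (SD 270 ml/h and
0.05 mcg/kg/min, truncated at zero), chosen so the expected practice
variation matches the reported 217 ml/h and 0.04 mcg/kg/min scales. Safe
advice is the reference times 1.25 (fluid) or 1.3 (vasopressor) — within
clinically acceptable range but never identical to the consensus, so the
influence denominator stays defined even in noiseless configurations. Unsafe
advice is an extreme underdose (0 ml/h fluid) or overdose (reference + 0.35
mcg/kg/min vasopressor). Final doses follow
\(F = P + w(A - P) + \text{noise}\) with the planted weight
\(w \sim \text{Beta}(2,2)\) under safe and \(\text{Beta}(1,5)\) under unsafe
advice (physicians largely reject extreme advice) and post-reveal noise SDs
of 30 ml/h / 0.02 mcg/kg/min. With all noise SDs at zero the pipeline
recovers \(w\) exactly — an acceptance check. Usefulness ratings are drawn
per participant and panel from the reported rating model (mean 3.2, SD 1.0
for three panels; 1.4, SD 1.3 for training examples), rounded into 0–4, and
*independent of attention by construction* — the planted-null for the
rating-vs-fixations correlation check.

**Randomness.** All randomness flows from one integer seed: the experiment
seed draws one sub-seed per participant, and every per-participant stream is
generated under its own seed, so runs are bit-reproducible and stable
against changes in participant count.

**Ground truth** records, per trial, the realized planted events (fixation
and blink onsets/offsets and their ROIs), per-ROI tallies (fixation counts,
blink counts, dwell including blink hold time), the planted advice weights
and the expected attention shares. Recovery tests compare pipeline
measurements against these realized tallies; blink-rate comparisons use the
planted dwell for both sides so the two rates share a denominator (the
pipeline's own gaze-time denominator additionally includes saccade
pass-through time, which is a property of the metric, not a detector error).

## What the synthetic tests do and do not show

Passing the recovery and reproduction tests shows the pipeline is correct
against its own contracts and that, at the study's size and reported
dispersion, the planted unsafe-attention effect is reliably detected and a
planted-null correlation is reliably bounded. It does not validate the
generator as a model of real physicians: real gaze has smooth pursuit,
vestibulo-ocular stabilisation, off-ROI search structure and
participant-specific blink physiology none of which are modelled; ROI tracks
from real tag detection drop out when tags are occluded (the reader and
attribution handle invisibility, but the generator emits always-visible
boxes); and real prescriptions are rounded to clinical increments while the
generator's are continuous. Conclusions about real data rest on the
pipeline's contracts, not on the generator's realism.

## Problem sizes used by the test suite

Detector-oracle equivalence runs on streams of up to 50 samples (100 seeds);
the chance-gaze baseline uses 10^5 uniform samples; the planted-structure
recovery uses 204 one-minute trials; the noiseless influence recovery uses
the full 19 x 6 x 2 design; the headline reproduction uses 100 seeded
full-scale experiments (19 participants, 324 s trials at 120 Hz) and checks
that the safe-vs-unsafe AI-screen comparison is significant at alpha = 0.05
in at least 80% of them and that the planted-null pooled rating correlation
stays below |r| = 0.2 in at least 95%.
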