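---
title: "Methods: simulating and classifying autonomic responses to affective film stimuli"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying autonomic responses to affective film stimuli}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archepsy)
```

## The analysis problem

The package implements a complete evaluation pipeline for a question from
affective psychophysiology: when people are shown film stimuli designed to
elicit distinct psychological states — here four Jungian archetype
categories (anima, animus, hero, shadow) and four explicit emotion
categories spanning the circumplex (active/passive x pleasant/unpleasant) —
how well can the elicited state be recovered (a) from autonomic nervous
system signals and (b) from the person's own introspective report?

The design it targets: each subject watches one ~300 s film clip per class,
each preceded by a 40 s paced-breathing baseline at 14 breaths/min.
Four channels are recorded — ECG at 512 Hz, skin conductance at 256 Hz, a
respiration belt and a skin temperature probe — and after each clip the
subject reports arousal, valence and dominance on the 1–9 Self-Assessment
Manikin (SAM) scale. The full cohort is 25 subjects x 8 classes.

Because no public accession exists for recordings of this design, the
package ships a first-class synthetic cohort generator. All downstream
stages (signal processing, feature extraction, classification, resampling
statistics) are exercised against generated cohorts with known ground
truth.

## The synthetic cohort generator

### Signal models

The generators are intentionally minimal: downstream features depend only
on beat timing, band power, event rates and slow trends, so morphological
realism would add cost without adding test power.

* **ECG** — beat-to-beat (RR) intervals follow
  $RR_i = \overline{RR}\,\bigl(1 + s\,[a_{LF}\sin(2\pi\,0.1\,t_i) +
  a_{HF}\sin(2\pi\,0.25\,t_i)] + \varepsilon_i\bigr)$
  with modulation depths $a_{LF} = 0.03$, $a_{HF} = 0.025$, white jitter
  $\varepsilon_i \sim N(0, (0.01 s)^2)$ and a single variability dial $s$
  (`hrv_scale`). The two sinusoids give controllable LF (0.04–0.15 Hz) and
  HF (0.15–0.4 Hz) spectral power for frequency-domain tests. A Gaussian
  R-wave template (sd 8 ms) is placed at each beat time, and the exact beat
  times are returned as ground truth. No P/T waves, artifacts or sensor
  dropouts are simulated.
* **Skin conductance** — tonic level plus linear drift plus a slow 0.01 Hz
  sinusoid, with phasic responses of standard bi-exponential kinetics
  (~1 s rise, ~3 s decay) at Poisson onsets and log-normal amplitudes.
* **Respiration** — a sinusoid at `rate/60` Hz plus band-limited noise.
* **Skin temperature** — level plus linear drift plus low-amplitude noise.
* **SAM reports** — per class, normal draws per dimension rounded to
  integers and clipped to [1, 9]. The class means and standard deviations
  are the published per-class descriptive statistics of the study design
  this package emulates (e.g. anima arousal mean 5.320, sd 1.520).

### Class effects and variance structure

Between-subject variance enters through subject-level offsets drawn once
per subject: resting heart rate $N(70, 7^2)$ beats/min, tonic skin
conductance $N(5, 1)$ µS, baseline temperature $N(33, 0.5^2)$ °C, and a
log-normal HRV multiplier. Within-class (epoch-to-epoch) variance comes
from fixed jitter on the stimulus parameters: sd 3 beats/min on heart
rate, 0.05 µS/min on the conductance slope, 2 events/min on phasic rate,
1 breath/min on respiration and 0.015 °C/min on temperature drift.

Class effects are deltas from a neutral reference (0 bpm, slope 0,
3 events/min, 14 breaths/min, HRV multiplier 1). The `effect_size` dial in
`[0, 1]` linearly interpolates every profile between the reference (a null
cohort: all classes statistically identical) and the full per-class values;
SAM means interpolate toward the grand mean over the eight classes. No
published per-class autonomic parameters exist for this design, so the
shipped deltas are package defaults chosen once, with three aims:
physiologically plausible magnitudes (a few beats/min, a few phasic events
per minute, fractions of a µS/min); roughly 50% four-class leave-one-out
accuracy at `effect_size = 1` against the 25% chance level, matching the
mid-50s/40s accuracy regime typical of between-subject affect
classification; and slightly stronger autonomic differentiation of the
archetype classes than of the emotion classes, mirroring the ordering the
emulated study reports. Because the defaults are a stylized covariance
structure — independent parameter jitter, stationary epochs, no habituation
across the session, no subject-by-class interaction — passing tests show
the pipeline's machinery is correct, not that real recordings would reach
any particular accuracy.

All randomness flows from one root seed through deterministic per-subject,
per-epoch, per-channel substreams, so cohorts are reproducible regardless
of evaluation order.

## Signal processing

* **ECG conditioning** (`bandlimit_ecg`): 0.5 Hz high-pass, 100 Hz
  low-pass, 49–51 Hz band-stop. All filters are Butterworth (4th order; the
  band-stop uses a 2nd-order prototype, i.e. four poles) applied
  forward-backward with odd-reflection padding, so they are zero-phase and
  beat times are not shifted.
* **Beat detection** (`detect_beats`): a Pan–Tompkins-style detector —
  5–15 Hz band-pass, derivative, squaring, 150 ms moving-window
  integration, adaptive signal/noise thresholds with a 200 ms refractory
  period — then refinement of each detection to the local R-wave apex.
  RR intervals outside the physiological 200–3000 ms gate are removed; no
  further ectopic-beat correction is attempted.
* **Heart rate** (`heart_rate_windows`): per non-overlapping 10 s window,
  `60000 / mean(RR)` with each interval assigned to the window holding its
  ending beat. An empty window is imputed from the nearest populated window
  and flagged in the `imputed` attribute.
* **HRV** (`hrv_time_domain`, `hrv_frequency_domain`): SDNN, RMSSD and
  SDSD use the sample (n−1) standard-deviation convention; RMSSD divides
  the summed squared successive differences by their count. The spectrum is
  computed on the RR tachogram cubic-spline resampled at 4 Hz, linearly
  detrended, via a Welch average periodogram (Hann window, 256-sample
  segments or the full series if shorter, 50% overlap). Band powers are
  integrals over VLF 0–0.04, LF 0.04–0.15 and HF 0.15–0.4 Hz; total power
  is the 0–0.4 Hz integral, so the band decomposition is exact. Spectral
  measures require about a minute of beats.
* **Electrodermal split** (`scl_component`, `scr_component`): SCL is the
  1 Hz low-pass; SCR additionally passes a 0.5 Hz high-pass, leaving the
  0.5–1 Hz phasic band. Note this makes SCR a strict sub-band of SCL: at
  any single frequency the SCR gain cannot exceed the SCL gain; the
  components differ in which part of the spectrum they retain.
* **Respiration rate** (`respiration_rate_windows`): 0.1–10 Hz band-pass,
  breath-peak detection with a 1.2 s minimum separation, instantaneous rate
  from breath-to-breath intervals attributed to interval midpoints,
  averaged per 10 s window.
* **Temperature** (`temperature_windows`): linear resampling to 64 Hz,
  10 Hz zero-phase low-pass, per-window means.

## Feature extraction

Each stimulus epoch yields the canonical 158-entry vector: 30 heart-rate
segments, 8 HRV summaries, 30 SCL segments, 30 SCR segments (mean absolute
phasic amplitude — an event-free amplitude measure, since no SCR event
detector is part of the design), 30 respiration-rate segments and 30
temperature segments, with 10 s segments over a 300 s epoch.

Segment features are normalized in two steps. First the scalar baseline —
the mean of the same windowed measure over the class's 40 s pre-stimulus
epoch — is subtracted. Then values are min-max scaled to [0, 1], where the
extrema are taken per subject and per signal family across all of that
subject's stimulus epochs. This within-subject scope directly serves the
purpose of the normalization (removing between-subject level differences);
a pooled scope would reintroduce them. The eight HRV features enter
unnormalized. Normalization operates on the windowed (10 s) series, not on
raw samples, because the windowed series are what the classifier consumes;
with window length equal to segment length the segment means coincide with
the window values. A degenerate scale (max = min) yields zeros with a
classed warning; epochs shorter than the nominal duration are right-padded
by holding the last window value and flagged.

## Classification

Features are standardized column-wise and reduced by PCA; the cohort
default keeps 25 components of the 158. Classifiers: kNN with deterministic
tie-breaking (majority vote; ties by larger summed inverse distance, then
lexicographic class order; k = 20 for the archetype task, 25 for the
emotion task), Gaussian naive Bayes, and LDA with a small ridge
(1e-6 of the mean pooled variance) on the pooled covariance so degenerate
designs — constant features, identical rows — are handled rather than
fatal. Evaluation is leave-one-out cross-validation per four-class task.

Two leakage policies are supported. The default, `strict`, refits
standardization and PCA inside every fold on the training rows only, which
is the statistically clean choice. `paper` mode fits them once on the full
pooled eight-class matrix before cross-validation, mirroring the classical
workflow in which dimension reduction is a one-time preprocessing step;
it leaks fold information through the transform and typically flatters
accuracy by a few points. SAM reports are classified with the same LDA
under leave-one-out directly on the three rating dimensions.

## Triplet resampling and statistics

To compare accuracies statistically, the cohort is resampled into all
$\binom{25}{3} = 2300$ three-subject groups. Each group is a 12-sample
problem (3 subjects x 4 classes) evaluated with stratified 3-fold
cross-validation — each fold holds exactly one sample per class, so folds
have 8 training and 4 test rows — using kNN with k = 3, since larger
neighborhoods are meaningless with 8 training rows (2 per class).
Physiological group models run on the pooled 25-component PCA scores; SAM
group models on the raw three ratings. Per-group accuracies therefore lie
on the grid {0, 1/12, …, 1}.

Five paired t-tests (two-sided, df = 2299) summarize the design: each task
against the 0.25 chance level, archetypes versus emotions on physiology,
physiology versus SAM for archetypes, and SAM versus physiology for
emotions. Because the 2300 groups share subjects, the accuracy samples are
positively dependent and the nominal standard error understates the true
one — these t statistics are descriptive of the procedure, not valid
independent-sample inference. The package therefore also reports a
diagnostic on a seeded disjoint partition of the subjects
(`disjoint_partition_t`), whose groups are independent but few
(8 for a 25-subject cohort).

## Numerical choices and degenerate inputs

* Filters reject cutoffs at or beyond Nyquist; the ECG low-pass corner is
  capped below Nyquist for low sampling rates.
* `paired_t` returns the degenerate t = 0, p = 1 when every difference is
  exactly zero and raises a classed error when differences are constant but
  non-zero (no finite t exists).
* Flat-line or near-constant ECG raises an insufficient-signal error, as
  does an epoch with no detectable breaths.
* Classifier ties (kNN votes, LDA discriminants) break deterministically,
  lexicographically as the last resort, so runs are order-invariant.
* Fold assignments, SCR onsets and all generator noise derive from the
  root seed via integer-hash substreams below $2^{31}$.

## Problem sizes used by the test-suite and acceptance script

The acceptance script runs the full study conditions: 25 subjects, 8
classes, 300 s stimuli, 40 s baselines, 2300 triplets per condition. The
test-suite exercises the same code paths on smaller cohorts (3–6 subjects,
60–120 s stimuli, whose 6–12 segments per family scale the feature vector
accordingly), with full-width fixtures where layout is asserted, 200
label permutations for the chance-level check, and three seeds per effect
size for the monotonicity check.

## Known limitations

* In pooled between-subject evaluation each subject contributes exactly
  one epoch per class. When class signal is weak relative to residual
  subject-level structure, a held-out epoch's nearest neighbours are its
  own subject's epochs — all of *other* classes — so leave-one-out
  accuracy can drop systematically below chance in small cohorts. This is
  a property of the design, not of the implementation; it fades as the
  cohort grows and class effects dominate.
* The generator's class effects are stationary within an epoch; real
  responses habituate and drift, and film clips vary in length around five
  minutes, which the generator fixes at 300 s exactly.
* SCR segment features measure band-limited phasic amplitude, not scored
  SCR events; studies using trough-to-peak scoring would differ.
* The t-tests over overlapping triplets inherit the dependence issue
  described above.
* Accuracy figures obtained on synthetic cohorts characterize the
  pipeline under the generator's assumptions only; they are not estimates
  of any real-data accuracy.
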