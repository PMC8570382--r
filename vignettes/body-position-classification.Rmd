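---
title: "Measuring infant body position from wearable inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring infant body position from wearable inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imupose)
```

## The measurement problem

How an infant's day is distributed over body positions — supine, prone,
sitting, upright, or held by a caregiver — is a developmentally meaningful
quantity, but video observation can only cover short spans, requires an
observer whose presence changes behavior, and is laborious to code.
`imupose` implements a contactless alternative: a few inertial measurement
units (IMUs, each a 3-axis accelerometer plus 3-axis gyroscope) are worn
through the day; a brief video-coded period at the start of the day trains
a per-infant classifier, which then labels the remaining, unobserved hours.

The physical rationale is that body positions differ in two signal
families. First, at rest an accelerometer reads the gravity vector in its
own frame, so limb orientation (supine vs prone flips the anterior axis;
sitting vs standing re-orients the thigh) moves the *location* statistics
of the acceleration channels. Second, positions differ in motion dynamics
— gait bounce while upright or carried, alternating leg bursts while
crawling — which move the *dispersion and shape* statistics and the
gyroscope channels. A random forest over simple per-window summary
statistics can exploit both without hand-set thresholds.

## Pipeline

1. **Ingestion** (`readSensorCsv`, `resampleUniform`). Raw per-sensor CSVs
   are cleaned (duplicate timestamps collapsed, non-numeric rows dropped,
   out-of-order rows sorted) and linearly interpolated onto a uniform grid.
   Accelerations are held in g units (m/s² dialects are converted on
   input) so orientation features are device-independent. Dropout gaps
   longer than 0.5 s are never bridged: samples inside them are flagged
   invalid, and any window touching them is excluded. Interpolation is
   linear rather than nearest-sample because small Bluetooth timing jitter
   is smooth, while a long gap must not fabricate motion.
2. **Synchronization** (`detectSyncImpulse`, `alignSession`, `checkDrift`).
   The sensors are struck together in view of the camera; the time of the
   maximal deviation of the acceleration magnitude from 1 g defines time 0
   on each sensor's clock, and the video-coded strike defines time 0 for
   the annotations. Each sensor is aligned by its own peak (the strike is
   physically simultaneous). A closing impulse verifies drift:
   sensor-elapsed minus video-elapsed time between the two events, flagged
   above 0.5 s. No correction is applied by default; an affine correction
   for multi-hour sessions is deliberately out of the default path because
   the sessions this was designed for showed none.
3. **Annotation** (`readAnnotationCsv`, `sampleLabels`,
   `interraterAgreement`). Position codes are half-open `[onset, offset)`
   intervals; a configurable alias table folds task-level codes
   ("crawling", "highchair", "held_walking") onto the five classes.
   Transitions and sensor-off spans stay uncoded (`"none"`). With two
   coders, per-sample percent agreement and Cohen's kappa are reported,
   and samples where the coders disagree can be excluded from training
   windows (the default; an option extends the exclusion to evaluation).
   Agreement is computed per sample on the label grid — the natural
   resolution once annotations have been sampled to the sensor rate.
4. **Windowing** (`extractWindows`, `assignWindowLabel`). 4-s windows every
   1 s, anchored at the sync event, 200 samples each at 50 Hz. A window is
   labelled only if one class covers at least 75% of its *samples* (3 of
   4 s); the rule is operationalized on samples rather than wall-clock
   seconds so it is exact at any rate. Uncoded samples never count toward
   a class, so a window that is 3.2 s sitting + 0.8 s uncoded is sitting,
   while a 2 s + 2 s mix is excluded. Windows that overlap an uncoded gap
   but still reach 3 s of one class are kept — the rule as stated — though
   dropping them would be a defensible stricter variant.
5. **Features** (`featureRegistry`, `featurize`). Per window, 10 summary
   statistics (mean, SD, skew, kurtosis, min, median, max, 25th/75th
   percentile, sum) × placement × signal × axis: 180 base features for the
   3-sensor laboratory profile. Cross-sensor features (per signal × axis,
   the sum and the root-sum-of-squares of the per-placement window sums)
   and cross-axis features (the same across axes within a placement) add
   24, for 204 total. Conventions: sample SD (n−1), Fisher–Pearson g1
   skewness, excess kurtosis g2, linear-interpolation percentiles;
   zero-variance channels define skew = kurtosis = 0 rather than NaN. The
   registry (names, order, conventions) is hashed, and models refuse
   feature tables carrying a different hash. Pairwise axis/sensor
   correlation and mean-absolute-difference groups exist but are disabled
   by default: enumerating *all* such pairs would far exceed a 24-feature
   extension, so the canonical set is the auditable sum/magnitude scheme,
   with the pairwise groups as explicit opt-ins.
6. **Models** (`chronologicalSplit`, `trainIndividual`, `trainGroupLoso`,
   `predictPositions`). Random forests with 750 trees and
   mtry = floor(√features), over exactly the classes present in training
   (upright is simply absent for a pre-standing infant). The individual
   regime mimics intended field use: within each class, the
   chronologically first 60% of windows train the model and the rest test
   it (`round()` half-up decides the split size; with a 0.6 fraction no
   half-way ties can arise). Splitting within class keeps every position
   represented despite the sequential task order. The group regime is
   leave-one-subject-out over full sessions. Class imbalance is left
   unweighted, matching a stock forest. The forest backend is
   `ranger` (single-threaded, seeded, so fits are reproducible); a unit
   test pins its behavior against the independent `randomForest`
   implementation on a shared fixture.
7. **Evaluation** (`evaluatePredictions`, `landisKochBin`,
   `prevalenceCorrelation`, `compareModelTypes`, `timelineReport`).
   Confusion matrix, overall accuracy, unweighted Cohen's kappa with
   Landis–Koch verbal bins (kappa is first rounded half-up to 2 decimals;
   negative values fall in "Slight to Poor"), per-class sensitivity and
   PPV (a never-predicted class reports PPV as missing, not zero, and
   averages run over defined values only), prevalence, Pearson
   correlations between actual and predicted prevalence (per participant,
   or per fixed-length interval — default 7.5 min — within a session), a
   two-sided paired t comparing regimes, and merged-episode full-day
   timelines with removal-log gaps. Human-readable reports round to 2
   decimals; machine outputs keep full precision.

## The simulator: what it emulates, and what it does not

`simulateSession` generates, per sample, a jitter-rotated class- and
placement-specific gravity direction plus an activity oscillation plus
white noise for the accelerometer, and bursts/noise for the gyroscope;
8-g sync impulses open and close the session; the annotation track mirrors
the schedule with 2-s uncoded transition gaps. The default schedule is
nine 60-s guided activities followed by 300 s of free play in randomized
5–30 s bouts. A reliability coder is emulated by ±0.2 s boundary jitter
plus occasional short (2–6 s) mislabelled sub-spans within an event —
the brief confusions real coders produce. `simulateCohort` adds
per-participant orientation jitter (placement variability, default ≤10°)
and ability profiles (a "young" profile omits upright).

Default noise levels are 0.05 g (accelerometer) and 5 deg/s (gyroscope).
Under these defaults the five classes are cleanly separable — simulated
validation saturates near accuracy 1.0 — so passing the end-to-end checks
demonstrates that the *pipeline* (sync, labelling, windowing, features,
split, training, scoring) is wired correctly, **not** that the method
reaches any particular accuracy on real infants: real signatures vary
within class, transitions are not instantaneous blends, and sensors move
relative to the body. Those effects are exactly why the original
validation used real recordings; the simulator's role here is ground
truth for every stage, available without any data download.

## Numerical and design choices

* Timestamps are 64-bit seconds relative to file start; nominal rate
  detection snaps the median spacing to 50 or 62.5 Hz within 2%.
* The impulse detector requires a 2-g peak prominence by default; weaker
  closing impulses (e.g. a garment dropped rather than struck) can be
  accommodated per call, or entered manually.
* Undefined statistics fail loudly rather than silently: kappa with
  chance agreement 1, agreement with zero co-coded samples, paired t with
  zero-variance differences, and prevalence correlations with fewer than
  3 units all raise errors; zero-variance correlation inputs yield missing
  values with a warning.
* Windows may straddle the chronological train/test boundary (4-s windows,
  1-s step). The default mirrors the intended field protocol; a stricter
  purge of boundary-overlapping windows is easy to express by filtering
  window start times before splitting.
* Group (LOSO) models train on participants' full sessions, not just
  their training splits — the larger pool is what a group model would
  actually have available.

## Reproducing the validation analyses

`labValidationResults()` ships the per-participant accuracy/kappa table
from the original validation study of the method;
`labValidationReanalysis()` recomputes the summary statistics reported
there (mean kappas 0.95 individual / 0.82 group, 14 + 1 and 9 + 4 + 2
Landis–Koch bins, paired t ≈ 3.3 in favor of individual models).

`cohortValidation(seed)` runs the full simulated two-regime validation.
The problem sizes used by the test suite and by `scripts/acceptance.R` —
a 15-participant cohort with the default ~15-min schedule at 50 Hz,
750-tree forests — were chosen to exercise the complete study design at
desk scale; a single run takes a couple of minutes on one CPU.

```{r, eval = FALSE}
cv <- cohortValidation(seed = 1)
mean(cv$individual$accuracy)   # individual-model mean accuracy
mean(cv$group$accuracy)        # leave-one-subject-out mean accuracy
prevalenceCorrelation(cv$prevalence$actual, cv$prevalence$predicted)$pooled
```

## Known limitations

* The simulator is a pipeline test harness, not a biomechanical model;
  simulated accuracies do not transfer to real data.
* Single-sensor or home 4-sensor profiles are supported structurally
  (feature registries scale accordingly), but no claim is made about
  their accuracy without real validation data.
* Annotation ingestion expects interval exports (onset/offset/code);
  frame-table exports must be converted upstream.
* No frequency-domain features, feature selection, or non-forest models:
  the scope is the validated measurement pipeline.
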