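---
title: "Adaptive R-peak detection: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive R-peak detection: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpeakr)
```

## The problem

The R wave is the dominant deflection of the QRS complex and the fiducial
point from which every other ECG feature (RR intervals, heart-rate
variability, wave delineation) is measured. Ambulatory recordings make its
detection hard: baseline drift from respiration and electrode motion,
broadband muscle noise, tall P and T waves that masquerade as QRS complexes,
premature ventricular contractions (PVCs) whose R wave points *below* the
baseline, and beat-to-beat amplitude variation that defeats any fixed
threshold.

`rpeakr` implements a threshold-based detector designed for exactly these
conditions. It uses no machine learning and no search-back: a wavelet
band-selection front end, a mirroring step for inverted beats, a cheap
local-maximum scan, and two adaptive thresholds recomputed on every 10 s
segment.

## Stage 1: wavelet multiresolution enhancement

The record is decomposed to 8 levels with the biorthogonal 6.8 filter bank.
With a decimated dyadic decomposition, detail level $j$ spans
$(f_s/2^{j+1},\, f_s/2^{j}]$ Hz and the deepest approximation spans
$[0,\, f_s/2^{9}]$ Hz, so

* at $f_s = 360$ Hz: cD1 = 90–180 Hz, cA8 = 0–0.70 Hz;
* at $f_s = 250$ Hz: cD1 = 62.5–125 Hz, cA8 = 0–0.49 Hz.

cA8 — essentially the baseline drift — is always zeroed. cD1 is zeroed when
its whole band lies at or above 90 Hz (i.e. when $f_s/4 \ge 90$), which
drops it at 360 Hz and keeps it at 250 Hz; a `keep` argument overrides the
rule. Retained detail levels are soft-thresholded,
$\eta(c) = \mathrm{sign}(c)\,\max(|c| - \lambda_j, 0)$, with
$\lambda_j = \sigma \sqrt{2 \ln N_j}$ and
$\sigma = \mathrm{median}(|cD_1|)/0.6745$.

Two numerical choices deserve a note:

* **Periodized boundaries.** The transform uses circular extension (with
  odd-length levels padded by their final sample and trimmed on
  reconstruction). This gives exact perfect reconstruction at any length —
  the test suite checks `reconstruct(decompose(x)) == x` to below
  $10^{-8}\,\max|x|$ — and boundary handling is irrelevant to every
  property the detector depends on (band edges, drift removal).
* **Noise scale from the finest level only.** Estimating a separate
  "noise" scale per level is attractive on paper but wrong on a periodic
  signal: the deep levels (e.g. 2.8–5.6 Hz at 360 Hz) are dominated by the
  cardiac waves themselves, so a per-level median produces thresholds
  larger than the levels' largest coefficients and deletes signal bands
  wholesale (on the clean fixture it halved the R amplitude). Only cD1 is
  noise-dominated on an ECG, so $\sigma$ is estimated there once.

After this stage the signal has (near-)zero mean, which is what lets the
rest of the pipeline treat the baseline as 0.

## Stage 2: mirroring of large negative deflections

PVC-like beats place the R wave below the baseline. Rather than running a
second, negative-peak search, the detector reflects sufficiently dominant
troughs about the baseline. A negative local minimum at sample $k$ is
reflected when its absolute amplitude is at least `amplitude_multiple`
(default 1.5) times the absolute amplitude of **every** sample within
±`window_s` (default 0.278 s) of it — steep, isolated troughs qualify;
gentle T/P undulations and troughs with a comparable neighbour do not, and
a large positive neighbour (an ordinary R wave close by) vetoes the
reflection.

One reading of that predicate had to be resolved: the samples on the
trough's own flanks are themselves "adjacent points", and for any smooth
sampled wave the immediate neighbours are within a percent of the extremum,
so a literal all-samples comparison could never fire. The comparison
therefore excludes the contiguous negative run containing the trough — the
very run that gets reflected (`scope = "run"`, the default; with
`scope = "point"` only the trough sample is excluded and reflected, the
literal single-sample reading). An exhaustive per-sample oracle in the test
suite re-evaluates the predicate independently.

## Stage 3: local maxima

Candidates are located from the sign of the first forward difference:
$s[n] = \mathrm{sgn}(x[n+1] - x[n])$; a $+1 \to -1$ transition marks a
maximum one sample right of the $-2$ in $\Delta s$. Zero signs (plateaus)
are filled from the *following* nonzero sign, so a rise–plateau–fall
contributes exactly one maximum at the first plateau sample; a plateau that
resumes rising contributes none, and endpoints are never reported. The
suite pins this down against a brute-force scan on 1000 seeded signals,
including integer random walks that are plateau-rich.

## Stage 4: adaptive thresholding

The record is processed in contiguous, non-overlapping segments of
`segment_s` (default 10 s). Per segment:

$$a_t = K_{amp} \cdot \mathrm{MAX_{seg\_amp}}, \qquad
  ti_t = K_{time} \cdot \mathrm{AVE_{max\_dis}}$$

* $\mathrm{MAX_{seg\_amp}}$ is the maximum of the (mirrored, enhanced)
  signal in the segment. Candidates with amplitude $\le a_t$ are discarded.
* $\mathrm{AVE_{max\_dis}}$ is the mean spacing of the candidates that
  *survive* the amplitude threshold. Using raw maxima here would let noise
  ripples collapse $ti_t$ far below any plausible RR interval; with
  survivors, $ti_t \approx K_{time} \cdot \mathrm{RR}$. A segment with
  fewer than two survivors inherits the previous segment's $ti_t$, or
  bootstraps $K_{time} \cdot 0.82\,f_s$ (0.82 s being a representative
  average RR) at the start of a record.

Survivors closer than $ti_t$ are arbitrated pairwise: the narrower peak
(width along the baseline, each side capped at `width_cap_s`, default the
0.278 s mirroring window) wins; on a width tie the larger amplitude wins;
an exact amplitude tie resolves to the later candidate. The loser is
dropped and the winner keeps the reference role against the next candidate,
so accepted peaks are never closer than their segment's $ti_t$ — a property
asserted directly in the tests, alongside exact agreement with an
independent, deliberately naive transcription of the five-step procedure on
500 seeded candidate sets. The last accepted peak of a segment is carried
into the next segment's first comparison (and may be revoked if it loses
that arbitration), which suppresses duplicates across boundaries.

Defaults $K_{amp} = 0.25$, $K_{time} = 0.45$ follow the published
coefficient sweep; `threshold_sweep()` reproduces that protocol on any
record set, pooling TP/FN/FP across records before taking percentages
(pooled totals, not record averages — this is how the published totals rows
are computed from the per-record counts).

## Evaluation

Detections match reference beats one-to-one within ±50 ms
(`tol_s = 0.05`), greedily in time order with the nearest unclaimed
detection (ties to the earlier one). Because reference beats are farther
apart than twice the tolerance, greedy matching is optimal — the suite
verifies equality with a maximum bipartite matching on 200 seeded sets.
Metrics are the usual
$SEN = \frac{TP}{TP+FN}$, $+P = \frac{TP}{TP+FP}$,
$ACC = \frac{TP}{TP+FN+FP}$, in percent to two decimals. The bundled
per-record reference tables (48 MIT-BIH arrhythmia records, 82 QT-database
records) are pure arithmetic regression fixtures: `detection_metrics()`
reproduces every printed percentage from the printed counts.

## The synthetic generator

`synth_ecg()` renders each beat as a sum of five Gaussians (P, Q, R, S, T)
at RR-jittered, grid-snapped onsets, with exact R-centre annotations.
Defaults: R = 1.2 mV ($\sigma$ = 12 ms), T = 0.25 mV ($\sigma$ = 60 ms),
P = 0.15 mV, Q = −0.12 mV, S = −0.25 mV — an ordinary adult morphology.
The T amplitude is kept clearly below $K_{amp}$ times the R amplitude on
purpose: a T/R ratio numerically equal to the default $K_{amp}$ would sit
exactly on the amplitude threshold, making the fixture's behaviour depend
on rounding rather than on design. PVC-like beats negate and double-widen
the R Gaussian and enlarge T by 1.5; small-R beats scale R by 0.35.
Presets cover the structures the detector targets (clean, PVC, drift,
large-T, mixed amplitudes, broadband noise), each with a fixed seed;
RR intervals are floored at 0.3 s.

What the generator does **not** emulate: realistic QRS morphology variation
(notching, bundle-branch shapes), rhythm disturbances beyond isolated
PVC-like beats, electrode-motion transients, or non-stationary noise.
Passing the synthetic gates therefore demonstrates the mechanics of every
stage — drift removal, mirroring, arbitration, threshold adaptation — on
controlled inputs; it does not certify clinical-database performance, which
requires the PhysioNet recordings themselves (see the README on
reproducing results).

## Problem sizes and runtime choices

The test fixtures are 10–120 s at 250–360 Hz (up to 43 200 samples); oracle
suites use 1000/500/200 seeded cases for the maxima/recognition/matching
checks; the coefficient sweep runs a 6 × 6 grid on a 60 s record with the
stage outputs cached across cells. These sizes exercise every code path —
segment carry-over, bootstrap thresholds, SKIP-coded annotation gaps —
while keeping the whole suite under half a minute.

## Known limitations

* A segment dominated by large R waves raises $a_t$ above small R peaks
  mixed into it; the mixed-amplitude preset reproduces this failure mode,
  and the coefficient sweep shows the expected SEN/+P trade-off as
  $K_{amp}$ grows.
* The amplitude threshold compares against the segment *signal* maximum,
  so a single large artifact inflates $a_t$ for its whole segment.
* Only single-channel analysis is provided; WFDB support covers signal
  formats 16 and 212 and MIT-format annotations, not the full format zoo.
* Wall-clock performance is not benchmarked or asserted anywhere; an
  optional profiling script (`scripts/profile_detection.R`) exists for
  eyeballing scaling only.
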