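---
title: "Isolating the P wave: masked EMD with a minimum-arclength criterion"
author: "pwaveiso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isolating the P wave: masked EMD with a minimum-arclength criterion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwaveiso)
```

## The problem

The P wave of the surface ECG is the only direct electrical signature of
atrial depolarisation, and subtle changes in its duration, axis and
spatial dispersion precede atrial fibrillation. On a standard 12-lead
recording the P wave is dwarfed by the QRS complex (an order of magnitude
larger) and crowded by the T wave, so any feature computed "near the P
wave" is easily contaminated. This package implements a two-stage
decomposition that strips first the QRS complex and then the T wave and
residual drift away from an R-aligned averaged beat, leaving an isolated
P wave per lead, and then derives a 56-feature description of that P wave
for two-group (control vs at-risk) classification.

## The decomposition

Empirical mode decomposition separates a signal into a fast *detail* and a
slow *local mean* by averaging cubic-spline envelopes through the maxima
and minima. Two well-known failure modes matter here:

* the filter's cut-off is set by the spacing of the extrema, which an ECG
  does not provide uniformly — fixed by **uniform-phase masking**: a
  sinusoid of amplitude $a$ and frequency $f$ is added before sifting and
  the procedure is repeated over $K$ phases $\varphi_k = 2\pi k/K$. The
  ensemble of masks sums to zero, so averaging the $K$ sifted means
  cancels the mask while pinning the filter response at $f$. We
  additionally subtract each phase's sifted mask-alone mean (a
  second-order correction; for a pure sinusoid it is nearly zero).
* an impulse-like waveform (the QRS, or the P wave itself once the QRS is
  gone) drags the envelopes and leaks into the local mean — fixed by the
  **minimum-arclength criterion**: every envelope knot on the designated
  spike is replaced by the value minimising the arclength of the envelope
  between its flanking knots, i.e. the envelope is pulled taut across the
  spike and the spike stays whole in the detail.

Stage 1 uses a 30 Hz mask of amplitude 0.04 mV with $K = 4$ and applies
the arclength criterion at the Q, R and S points; its detail is the QRS
complex and its residual keeps P, T and baseline. Stage 2 repeats the
procedure on that residual with a 10 Hz mask of amplitude 0.02 mV,
$K = 4$, treating the whole `[P_on, P_off]` support as the spike; its
detail is the isolated P wave. Both stages are conservative by
construction: `qrs + p_wave + remainder` reproduces the input to machine
precision, which the test suite asserts on every random template.

### Numerical choices

* **Splines.** Envelopes are natural cubic splines through the extrema,
  with one extremum mirrored beyond each end (standard EMD boundary
  handling; with mirrored knots the end condition is immaterial, and the
  natural spline admits a fast tridiagonal solve that the arclength
  search exploits — the envelope is linear in any one knot value, so the
  1-D search objective is precomputed as `y0 + v * y1`).
* **Arclength.** Integrated by trapezoid on the sample grid with the
  vertical axis scaled at 0.01 mV per sample step, making the objective
  scale-stable across leads. The knot search is Brent's method bracketed
  between the flanking knot values expanded by 10%.
* **Coupled knots.** When several envelope knots sit on one spike (the
  usual case for a P wave spanning ~100 ms), the per-knot minimisations
  are coupled; up to three relaxation sweeps are run, which converges to
  the joint arclength minimum and markedly improves P recovery on
  low-amplitude leads.
* **Sifting.** At most 8 sifting iterations with the standard-deviation
  stopping ratio at 0.2. A signal with fewer than two maxima or two
  minima is returned unchanged as its own local mean, flagged.
* **Degenerate mask.** Amplitude 0 with $K = 1$ reduces exactly to plain
  one-component sifting; the suite checks this against an independent
  EMD implementation.
* **Spike neighbourhood.** Knots within 20 ms of a spike index are
  replaced. Stage 1 lists the Q, R, S points; stage 2 lists the whole
  `P_on:P_off` range, reading the spike set as "the sample indices of the
  waveform to be separated". With only the single P extremum listed, P
  flank knots escape replacement and P energy leaks into the mean; the
  all-support reading recovers the P wave with per-lead correlations
  above 0.97 on the default beat.

### What stage 2 cannot do

The 0.02 mV mask is small relative to a 0.4 mV T wave, so on the steep T
slopes the masked signal has sparse extrema and part of the T wave ends
up in the stage-2 detail *outside* the P window. The isolated P wave is
therefore trustworthy inside `[P_on, P_off]` (widened by 40 ms) and noisy
beyond it; the recovery error metric and the morphology features are
windowed accordingly. The loop and dispersion features use the full 1 s
window, as the P-wave matrix definition requires, and inherit some of
that leakage — an inherent property of the method at the published mask
amplitudes, shared by both extraction routes being compared.

## Preprocessing and delineation

Records are resampled to 500 Hz (polyphase), baseline wander is removed
by an 8-level Symlet-10 wavelet decomposition with the level-8
approximation zeroed (a 0–1 Hz stop band at 500 Hz), noise is removed by
a zero-phase 4th-order Butterworth filter, and 0.5 s is trimmed from each
edge. Two points deserve note:

* **The 32 Hz filter is a low-pass by default.** A 32 Hz *high*-pass
  would annihilate the P wave (P energy sits below ~15 Hz) and would
  contradict the 0.5–8 Hz band used by the comparison extractor; the
  high-pass mode remains available via `noise_filter(mode = "highpass")`.
* **The wavelet stage is implemented in-package** (periodised pyramid
  transform on a reflection-padded signal, hard-coded Symlet-10 filter
  bank) because no R wavelet package is available in the target
  environment; it was verified against an external DWT implementation
  during development, and its band behaviour (DC removal, 0.2 Hz
  rejection, 10 Hz transparency) is asserted in the tests. Because the
  level-8 basis functions are wide, re-applying the operator changes the
  interior of a 10 s record by under ~2% RMS — the projection is only
  approximately self-consistent across the un-pad/re-pad boundary, and
  the affected edges are trimmed downstream anyway.

R peaks come from a Pan–Tompkins-style detector (5–15 Hz band-pass,
derivative, squaring, 150 ms integration, 200 ms refractory) on the lead
with the largest peak-to-peak amplitude. Wave boundaries are rule-based:
the P is sought 300–60 ms before R and the T 120–450 ms after, each as
the largest deflection from a *linear* local baseline interpolated across
the search window (slow drift survives the wavelet stage, so a fixed
level biases the bounds), with onset/offset at the 5% deviation crossing.
Anything not found confidently is marked missing, never guessed.
Externally produced fiducial annotations, when attached to a record, are
returned verbatim. Beats are averaged over a 1 s window placed 0.4 s
before to 0.6 s after R, so both the P and the T wave fit.

## The synthetic study population

The hospital recordings behind the original study are private, so the
package ships a generator that emulates what the pipeline needs: a 3-D
cardiac dipole built from five Gaussian components (P, Q, R, S, T), each
with a centre, width, amplitude and unit direction, projected through the
classical Dower lead matrix for I, II and V1–V6, with the remaining limb
leads derived exactly (III = II − I and so on — an identity the tests
assert on every record, which is why noise is generated on the eight
independent leads and expanded). The defaults give a 60 bpm sinus beat
with a 1.2 mV R wave, a 0.22 mV P wave of 100 ms nominal duration
(defined as 5 Gaussian sigmas) 160 ms before R, broadband noise of
0.03 mV and a 0.25 Hz, 0.05 mV sinusoidal wander — values a clinical
engineer would call an unremarkable resting ECG. Fixed RR intervals keep
beat averaging exact; the closed-form P-only contribution is stored with
every record, which is what makes recovery scoring possible at all.

Two-group cohorts perturb the case group's P wave by a duration
prolongation (given in ms of the 5-sigma nominal duration), a rotation of
the atrial dipole about the anteroposterior axis, and/or an amplitude
change — the three axes along which atrial remodelling expresses itself
in the features. What the generator deliberately does **not** model:
heart-rate variability (off by default), ectopy, respiration or
electrode-motion artefacts, and any actual arrhythmia — the object of
study is the sinus-rhythm P wave. Passing tests on this population shows
the pipeline recovers known truth under controlled conditions; it says
nothing about hospital-grade artefacts or the real effect size separating
pre-AF patients from controls, which the original data alone could
establish.

## Features

From the isolated P wave and the averaged beat the package assembles
exactly 56 named features: P duration; P/Q/R/S/T amplitudes, PR/QRS/QT
intervals and mean ST voltage on the reference limb and chest leads (the
lead with the largest |R| in each group, fiducials located per lead);
the three eigenvalue fractions of the P-loop PCA; 28 inter-lead
dispersion angles; three grid loop descriptors; and three 20–50 / 1–20 Hz
band-power ratios of the PC time courses.

Choices that were genuinely open:

* **The PCA decomposes the uncentred second-moment matrix** $X^TX$ of the
  n × 8 P-wave matrix (leads I, II, V1–V6 over the full 1 s window).
  Centring is available via `pca_ploop(center = TRUE)` but off by
  default: the input is a baseline-removed P wave and the uncentred form
  matches the written definition. This is the highest-risk ambiguity in
  the feature block. Eigenvector signs are fixed by making each loading
  column's largest-magnitude entry positive; weights are reported as
  eigenvalue fractions of the total over all eight eigenvalues (raw
  eigenvalues are in the returned object for anyone who wants them).
* **Loop descriptors** grid the bounding rectangle of the closed
  (PC1, PC2) trajectory into 70 × 70 cells. The length is the count of
  cells the polyline traverses (Amanatides–Woo grid walking, verified
  exactly against a Liang–Barsky clipping oracle); the area is the
  percentage of cells whose centre lies strictly inside the closed
  polygon under the even-odd rule, which handles self-intersecting loops
  without further convention.
* **Angles** are reported in degrees in [0, 180]; zero-norm loading rows
  propagate missing angles.
* **The 20 Hz bin belongs to the numerator band.** With a 1 s series at
  500 Hz the DFT bins are integer frequencies; the numerator sums
  20–50 Hz (31 bins) and the denominator 1–19 Hz (19 bins), so the
  white-noise expectation of the ratio is 31/19 ≈ 1.63.

## Classification

The study stage is deliberately conventional: a label-stratified 80/20
split; features missing in more than 90% of training rows dropped (a
fixed drop-list mode reproduces the published six-feature drop, leaving
50); training-median imputation and training-only z-scoring; four model
families — RBF-kernel SVM, averaged perceptron, random forest and
gradient-boosted trees — each grid-searched by mean AUC under stratified
10-fold cross-validation (fold count reduced if a class is smaller);
decision thresholds from the Youden index on training scores (scanning
midpoints of consecutive unique scores, ties resolved toward higher
specificity); AUC, accuracy, sensitivity, specificity, precision and F1
on the holdout. The perceptron is implemented in-package (no R package
exposes a bare one) and has no probability output; its decision-function
scores feed the AUC and thresholding, a documented divergence from
probability-based scores. Hyperparameter grids are small conventional
defaults (SVM: C ∈ {0.1, 1, 10}, γ ∈ {1/p, 0.01, 0.1}; RF: 100/300
trees, depth unlimited/5/10; boosting: depth {2, 4, 6}, η {0.05, 0.1,
0.3}, 100/300 rounds; perceptron: no penalty or L2 with α {1e-4, 1e-3});
the original grids are not recoverable from the text.

Global feature importance is a sampling-based Shapley estimate: per
sampled permutation a background row is drawn and features are switched
from background to evaluation values in permutation order, crediting each
score change to the switched feature. The telescoping sum makes the
per-row values satisfy local accuracy exactly against the mean background
prediction; importance is the mean absolute value per feature.

## Problem sizes and determinism

The simulation sizes used by the test suite and the acceptance script
are: 100 random single-lead templates for the conservation check; 50
beat-morphology seeds × {noiseless, 0.03 mV noise} for the extractor
comparison; a 300-record zero-effect cohort for the chance-level check; a
400-record cohort (40 ms prolongation + 20° rotation, seed 7) for the
separability check; and 20 train/test re-splits of that cohort for the
full-versus-two-feature comparison. These sizes give stable medians and
keep a complete run in the tens of minutes on one core. Every stochastic
step — record noise, cohort assembly, splits, folds, model seeds,
Shapley sampling — is driven by explicit integer seeds, and rerunning any
entry point with the same seed reproduces its output bit for bit.

## Known limitations

* The wavelet baseline stage is only approximately idempotent near the
  record edges (see above); the edges are trimmed.
* Stage-2 T-slope leakage outside the P window, discussed above.
* The delineator is single-lead and rule-based; it is a stand-in for a
  full waveform limit locator, and external annotations are the intended
  path for real data.
* The generator's fixed-RR, Gaussian-bump world contains no artefact
  classes; classification results on it measure pipeline correctness,
  not clinical performance.
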