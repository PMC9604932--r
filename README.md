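# pwaveiso

Isolation of the P wave from 12-lead sinus-rhythm ECGs and extraction of
atrial-fibrillation screening features, in R.

The P wave — the ECG signature of atrial depolarisation — carries the
earliest surface evidence of the atrial remodelling that precedes atrial
fibrillation, but it is an order of magnitude smaller than the QRS
complex beside it. This package implements a two-stage decomposition
that removes first the QRS and then the T wave and baseline from an
R-aligned averaged beat, leaving an isolated P wave per lead, and builds
a 56-feature description of it (morphology, principal-component loop
geometry, inter-lead dispersion angles, band-power ratios) feeding a
conventional machine-learning stage. It is aimed at physiological
signal-processing researchers who need a tested, reproducible reference
implementation of the method and a synthetic ground-truth harness to
evaluate it.

## The method in brief

Empirical mode decomposition (EMD) separates a signal into a fast detail
and a slow local mean via cubic-spline envelopes through the extrema.
Two modifications make it usable on an ECG beat:

* **Uniform-phase masking** — a sinusoid `a·sin(2πft + φ_k)` is added
  before sifting, for K phases `φ_k = 2πk/K` spanning 2π. The mask pins
  the EMD filter cut-off at `f`; because the phase ensemble sums to
  zero, averaging the K sifted means cancels the mask itself.
* **Minimum-arclength criterion** — envelope knots lying on a designated
  impulse-like waveform (the Q/R/S points in stage 1, the whole
  `[P_on, P_off]` support in stage 2) are replaced by the value that
  minimises the arclength of the envelope between the flanking knots,
  pulling the envelope taut so the spike stays in the detail.

Stage 1 (30 Hz mask, 0.04 mV, K = 4) separates the QRS; stage 2 on its
residual (10 Hz mask, 0.02 mV, K = 4) separates the P wave from the T
wave and drift. Both stages conserve the signal exactly:
`qrs + p_wave + remainder` reproduces the input template to machine
precision. A zero-phase 0.5–8 Hz Butterworth extractor is included as
the conventional baseline the method is compared against.

Because the study data behind the method are private, the package ships
a synthetic 12-lead generator (Gaussian-component cardiac dipole through
a fixed lead matrix) with closed-form P-wave ground truth and two-cohort
label structure, so every stage is testable against known truth.

## Worked example

```r
library(pwaveiso)

spec <- dipole_beat_spec()                      # default sinus beat
rec  <- generate_record(spec, duration_s = 10, noise_sd = 0.03,
                        wander_amplitude = 0.05, seed = 42)
rec
#> <ecg_record> 12 leads x 5000 samples @ 500 Hz (10.00 s)
#>   leads: I II III aVR aVL aVF V1 V2 V3 V4 V5 V6
#>   annotations: 10 (R)

pp      <- preprocess_record(rec)               # resample, de-wander, 32 Hz LP, trim
r_peaks <- detect_r_peaks(pp)
tpl     <- average_beat(pp, r_peaks)
tpl
#> <beat_template> 12 leads x 500 samples @ 500 Hz, R at 201, 8 beat(s) averaged

iso <- isolate_p_wave(tpl)                      # the two-stage extraction
iso
#> <p_isolation> 12 leads x 500 samples @ 500 Hz; P boundaries located
```

Against the generator's exact P-wave truth, the masked-EMD extraction
recovers lead II with an RMSE of 0.0096 mV inside the P window, versus
0.1127 mV for the 0.5–8 Hz band-pass baseline on the same record — the
band-pass cannot keep the QRS from leaking into the P window. The
feature vector built from the isolated P wave:

```r
feats <- extract_features(tpl, iso$p_wave)
dplyr::select(feats, P_dur, L_AMP_P, PC1w, II_V4, LoopArea, r2050_PC1)
#>   P_dur L_AMP_P  PC1w II_V4 LoopArea r2050_PC1
#> 1   106   0.128 0.963  86.1     21.0         0
```

i.e. a 106 ms P wave of 0.128 mV on the reference limb lead, 96.3% of
the P-loop variance on the first principal component, an 86.1° dispersion
angle between the lead II and V4 loading vectors, a loop filling 21% of
its bounding grid, and essentially no 20–50 Hz power — a normal sinus P
wave. `generate_cohort()` + `cohort_features()` + `run_study()` run the
same pipeline over a labelled two-group cohort and fit the four
classifier families (SVM, perceptron, random forest, gradient boosting)
with cross-validated grid search, Youden-index thresholds and Shapley
feature importance; `tidy()`, `glance()` and `autoplot()` methods cover
the results.

A thin CLI over the same functions is installed at
`system.file("cli/pwaveiso", package = "pwaveiso")` with subcommands
`synth`, `preprocess`, `delineate`, `isolate`, `features`, `classify`
and `run`.

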