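# vibrotrace

Resting-state EEG in Alzheimer's disease (AD) differs from healthy aging
in its spectrum: slow bands (delta, theta) gain relative power while the
~10 Hz alpha rhythm and faster bands lose it. **vibrotrace** implements,
end to end and in simulation, a physical-computational chain that tries to
make that difference *visible* and then machine-classifiable:

1. **Group-average EEG** — per-group, channel-by-channel time-domain mean
   of multichannel recordings (EDF or plain-text matrices; 19-channel
   10–20 montage).
2. **Direct-mapping sonification** — amplitudes mapped linearly to sound
   pressure, peak-normalized, band-limited-resampled to PCM audio
   (no frequency modulation; the waveform morphology is preserved).
3. **Vibration-driven laser projection (simulated)** — the audio drives
   the fundamental (0,1) mode of a circular membrane,
   `f01 = (c01 / 2πa) · √(T/σ)` with `c01 ≈ 2.4048` the first zero of
   Bessel `J0`; a mirror on the membrane deflects a laser onto a screen,
   and a camera-style integrator renders the moving spot into 8-bit
   frames. The membrane physics (σ = m/A, tension from resonance) is
   exact; the opto-mechanical coupling is an explicit, documented model.
4. **Pattern isolation** — adaptive thresholding `T(x,y) = μ(x,y) − C`
   (31 px window, C = 2), morphological opening (3×3 elliptical element),
   and a contour-envelope mask around the largest projected structure.
5. **Descriptors** — per frame: active area, binary Shannon entropy,
   box-counting fractal dimension `D = slope of log N(ε) vs log 1/ε`,
   white-pixel centroid; across frames: centroid trajectory with step and
   cumulative displacements.
6. **Classification** — random forest (100 trees, Gini, √p features per
   split, seed 42) under an 80/20 stratified holdout plus stratified
   5-fold cross-validation, with Gaussian noise injection (σ = 5 intensity
   units) as a robustness perturbation, reporting confusion matrix,
   per-class precision/recall/F1/specificity, accuracy and ROC/AUC.

A seedable synthetic-EEG generator provides AD-like (slow-dominated) and
NC-like (alpha-dominated) group profiles, so the whole chain runs and is
testable at desk scale with no data downloads. It is aimed at researchers
who want to study *how much of a spectral group difference survives* a
sonification → vibration → vision → descriptor reduction, with every stage
inspectable and reproducible.

## Worked example

```r
library(vibrotrace)

# exact membrane physics: radius 4 cm, mass 2 g, measured resonance 187 Hz
membrane_spec(a = 0.04, m = 0.002, f01 = 187)
#> <membrane_spec>
#>    a = 0.04 m, m = 0.002 kg, A = 0.00503 m^2
#>    sigma = 0.398 kg/m^2, T = 152 N/m, f01 = 187 Hz (Q = 50)

# a desk-scale end-to-end run: 3 synthetic subjects per group, 60 s of
# audio per group, 600 frames per group at 10 fps
cfg <- pipeline_config(
  seed = 42,
  eeg = list(duration = 60, n_subjects = 3),
  sonify = list(fs_audio = 8000, time_scale = 1),
  render = list(width = 120L, height = 90L),
  frameproc = list(duration = NULL, trim_start_ad = 0, trim_start_nc = 0)
)
res <- run_all(cfg, quiet = TRUE)
res$report
#> <vib_report>
#>   test accuracy 0.6792, AUC 0.7186 (n = 240)
#>   CV accuracy 0.6615 +/- 0.0255; overfitting gap 0.0177
#>            predicted
#> true        Control Alzheimer
#>   Control        79        41
#>   Alzheimer      36        84

glance(res$report)
#> # A tibble: 1 × 7
#>   accuracy   auc cv_mean  cv_sd overfitting_gap n_train n_test
#>      <dbl> <dbl>   <dbl>  <dbl>           <dbl>   <int>  <int>
#> 1    0.679 0.719   0.661 0.0255          0.0177     960    240
```

Reading this: of 240 held-out frames, 68% were assigned to the correct
group and the ensemble's vote fractions rank a random Alzheimer-group
frame above a random control frame 72% of the time (AUC). Cross-validated
and test accuracy agree within 2 points, so the forest is not overfitting
frame noise. With identical profiles for both groups the same pipeline
classifies at chance (the test suite asserts accuracy ∈ [0.45, 0.57] over
ten seeds), so the separation above is carried by the spectral contrast,
not manufactured by the pipeline. `tidy(res$report)` gives the per-class
metric table, `autoplot(res$report)` the ROC curve.

Every result object is a tibble or has `tidy()`/`glance()` methods;
`autoplot()` is defined for trajectories, centroid paths and reports. A
thin command-line front end (`inst/cli/vibrotrace`) exposes each stage
(`synth-eeg`, `sonify`, `simulate`, `process`, `features`, `classify`,
`run-all`) for shell pipelines; `run-all` takes a YAML config
(`validate_config()` checks it) and writes `features.csv`, `report.json`,
`roc.csv` and a complete run manifest with checksums.

The methods vignette (`vignettes/vibrotrace-methods.Rmd`) documents the
generator, the simulator's assumptions and free parameters, the processing
conventions, and the measured limits of the descriptor set at desk scale.

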