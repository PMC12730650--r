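---
title: "From brain rhythms to laser figures: the vibrotrace model and its assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From brain rhythms to laser figures: the vibrotrace model and its assumptions}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

vibrotrace turns resting-state EEG into sound, drives a simulated
speaker–membrane–mirror–laser apparatus with that sound, films the moving
laser spot with a simulated camera, reduces the filmed frames to a handful
of spatial descriptors, and asks a random forest whether the descriptors
separate two groups — one with the slow-wave-dominated spectrum typical of
Alzheimer's disease (AD), one with the alpha-dominated spectrum of healthy
controls (NC). This vignette explains each model in the chain, the
parameters that matter, the choices that were genuinely open, and what the
package's tests do and do not establish.

## 1. Synthetic group EEG

Real group-level resting EEG differs between AD and NC mainly in *relative
band power*: AD shows elevated delta/theta and suppressed alpha/beta; NC
shows a dominant ~10 Hz alpha peak. The generator (`synth_eeg()`)
emulates exactly this and nothing more. Each channel is an independent sum
of band-limited Gaussian noise components — 4th-order Butterworth band-pass
filters applied to white noise, one per canonical band (delta 0.5–4, theta
4–8, alpha centred on `alpha_peak_hz` ± 2, beta 13–30, gamma 30–45 Hz) —
with amplitude weights `sqrt(band_powers)` so component *power* follows the
profile, plus a 1/f broadband floor. A single filter pass is used: the
phase response of a stochastic component is immaterial.

The floor is band-limited to 0.5–45 Hz. The package consumes
*already-cleaned* EEG (the upstream datasets it mirrors are band-passed and
artifact-corrected before any analysis), and cleaned scalp EEG carries
essentially no power above the low gamma range; a floor extending to the
Nyquist frequency would be an artifact of the simulation, not a property of
the data. This matters downstream: broadband drive at the membrane's
resonance is amplified by the quality factor squared, so unphysical
high-frequency content would bury the band structure the study is about
(see §3).

Preset profiles (chosen once, as round numbers consistent with the
direction and rough magnitude of group differences reported across the
AD-EEG literature):

| preset | delta | theta | alpha | beta | gamma | floor |
|--------|------:|------:|------:|-----:|------:|------:|
| `ad`   | 0.35  | 0.25  | 0.12  | 0.06 | 0.02  | 0.20  |
| `nc`   | 0.10  | 0.10  | 0.45  | 0.12 | 0.03  | 0.20  |

The slow-band-to-alpha weight ratio is 5 for `ad` and 0.44 for `nc`.
Channels are mutually independent — real EEG channels are strongly
correlated through volume conduction, but since the sonification step
averages channels, only the spectrum of the average matters, and that is
identical either way up to a scale the normalization removes.

What the generator does *not* emulate: spatial covariance and topography,
non-stationarity (drowsiness drift, eye-state changes), non-Gaussian
transients, inter-subject variability beyond independent noise
realizations, and the aperiodic-exponent differences between groups. Tests
passing on this generator therefore show that the *pipeline transmits
spectral group differences*; they say nothing about diagnostic performance
on real recordings.

## 2. Sonification

`sonify_eeg()` is a direct amplitude mapping: average the channels, peak-
normalize to `headroom` (0.99), and resample onto the audio grid with a
polyphase band-limited FIR — no frequency modulation, no spectral reshaping.
The one genuinely free parameter is `time_scale`: the source recordings'
durations imply roughly a 2.7-fold time compression (a ~13.5 min EEG became
~5 min of audio), and 2.7 is the package default, but nothing in the source
describes the rule, so it is exposed. Audio defaults are 44.1 kHz, 16-bit
PCM mono.

## 3. Membrane, mirror, laser

The physics module carries the only closed-form anchor points in the chain.
For a circular membrane of radius $a$ and mass $m$, surface density
$\sigma = m / (\pi a^2)$, and the fundamental mode (0,1) satisfies

$$ f_{01} = \frac{c_{01}}{2\pi a} \sqrt{T/\sigma}, $$

with $c_{01} = 2.4048$ the first zero of the Bessel function $J_0$
(computed by root finding, not looked up). The bench build with
$a = 0.04$ m, $m = 2$ g and a measured $f_{01} = 187$ Hz gives
$A = 5.03\times10^{-3}\,\mathrm{m^2}$, $\sigma = 0.398\,\mathrm{kg/m^2}$,
$T \approx 152$ N/m; the tests reproduce all three to printed precision,
and `tension_from_resonance()` / `fundamental_frequency()` are verified to
be inverses to $10^{-9}$ relative error.

Dynamics: only the fundamental mode is simulated. Its displacement obeys a
driven damped harmonic oscillator
$\ddot u + (\omega_{01}/Q)\,\dot u + \omega_{01}^2 u = \kappa\,p(t)$ with
$p(t)$ the audio. It is discretized by a prewarped bilinear transform, so
the digital resonance sits exactly at $f_{01}$; at resonance the
steady-state amplitude matches the closed form $\kappa Q/\omega_{01}^2$
within 1% (tested). The default $\kappa = \omega_{01}^2$ gives unit
quasi-static gain, which is the regime the sonified EEG actually occupies:
its content lies far below 187 Hz, so the spot essentially traces the
drive waveform.

Optics: mirror tilt is modelled as proportional to modal displacement
(`gain`, rad per drive unit, default 0.15 — sized so a full-scale drive
deflects the spot across roughly a third of the screen). A tilt $\theta$
deflects the beam by $2\theta$; the spot moves by
$L\tan 2\theta$ with $L$ the mirror-to-screen distance (0.5 m), the
horizontal axis stretched by $1/\cos(30^\circ)$ for the oblique screen.
No coupling constant of the real rig is estimated; these are free
parameters of the simulator.

The second axis is driven by a delayed copy of $u$. The delay default is a
quarter period of the 10 Hz alpha rhythm (25 ms at `time_scale` 1, scaled
by `1/time_scale` in the pipeline): alpha then draws open Lissajous-like
loops while slower drift draws thin near-diagonal strokes. This is a
modelling choice, not a description of the physical rig (how the real
device produced two-dimensional figures is not documented); it was chosen
because it is the smallest mechanism that makes the visual geometry reflect
the spectral contrast of interest. A delay much shorter than the signal
periods degenerates to a one-dimensional diagonal trace and destroys the
second dimension entirely.

Camera: frames integrate the spot's dwell over a full frame interval
(exposure $=1/\mathrm{fps}$, matching the motion-blurred traces of real
captures), through a Gaussian point-spread function (`psf_sigma`, px). The
sensor has *fixed gain*: intensity is proportional to dwell density and
saturates at 255 once a pixel collects `sat_dwell` (0.2%) of the exposure —
so fast traces are long and dim, slow traces short and bright, as a real
camera records. A per-frame auto-gain alternative (`normalize = "frame"`)
exists but erases exactly this information. A black level of 12 models the
sensor pedestal and keeps additive noise symmetric on the dark background;
sensor noise defaults to 2 intensity units (consumer video after on-device
denoising is smooth; the protocol's robustness noise is injected later and
separately).

## 4. Frame processing

The processing chain is fixed by the protocol it mirrors: adaptive
thresholding with $T(x,y) = \mu(x,y) - C$ over a 31 × 31 window with
$C = 2$ (Gaussian weighting by default, uniform-mean variant available and
oracle-tested; strictly greater-than comparison, ties to background;
replicate border padding), then morphological opening with the 3 × 3
elliptical element (the cross), then a contour-envelope mask. Noise
injection (Gaussian, $\sigma = 5$ on the 8-bit scale) is applied to the
grayscale frames *before* binarization; applying it after binarization is
configurable but vacuous, since re-thresholding a perturbed binary image
reproduces the binary image.

The envelope mask closes holes of the inverted frame (background regions
with no 4-connected path to the border) and keeps the largest 8-connected
structure of the hole-closed image. One genuinely open question is which
binary frame the contour should be computed on. Computed on the *opened*
frame, the operation fails its own purpose at moderate noise: opening a
speckled ~64%-white background leaves a majority-black field whose largest
inverted structure is the background itself, so the "envelope" becomes the
whole frame. Computed on the *pre-opening binarized* frame, the dark halo
outlining the trace is the dominant dark structure and the filled contour
isolates the trajectory — which is what the reference imagery shows the
mask doing. The pipeline therefore contours the binarized frame by default
(`mask_source = "binarized"`, applied to the cleaned frame), with
`"cleaned"` available.

Conventions fixed across the package: row-major rasters, origin (0,0) at
top-left, 0-based pixel coordinates in descriptor output; 8-connectivity
for foreground components; erosion treats out-of-image pixels as
foreground and dilation as background, so solid regions touching the frame
edge survive opening.

## 5. Descriptors

Per frame: active area (count of white pixels within the mask), Shannon
entropy of the binary intensity distribution (equal to the binary entropy
of the white fraction — at most 1 bit), box-counting fractal dimension
(dyadic box sides from half the frame down to 2 px, grid anchored at the
origin, ordinary least squares on $\log N(\varepsilon)$ vs
$\log 1/\varepsilon$ over all sizes, clamped to $[0,2]$; no scaling-region
pruning, because any pruning rule is a free parameter that changes the
estimate), and the white-pixel centroid. Across frames: the centroid
trajectory with per-step Euclidean displacements and their running sum.
The classifier's feature vector is
`[active_area, entropy, fractal_dim, centroid_x, centroid_y, step_disp]` —
the exact vector is not documented in the source protocol and is recorded
here as this package's choice. Displacements are in pixel units; no
physical calibration of the screen is attempted.

Note that entropy is a deterministic monotone function of active area for
binary frames; it is kept because the protocol names it, but it adds no
information the forest does not already have.

## 6. Classification protocol

Random forest with 100 trees, Gini splits, unbounded depth, bootstrap
resampling, $\lfloor\sqrt p\rfloor$ candidate features per split, seed 42
(`randomForest` behind a scikit-learn-style `rf_config()`;
`min_samples_split = 2` / `min_samples_leaf = 1` correspond to fully grown
trees, `nodesize = 1`). The protocol is an 80/20 stratified holdout, a
stratified 5-fold cross-validation on the training part, a final fit, and
an evaluation on the untouched test split: confusion matrix, per-class
precision/recall/F1/specificity, overall accuracy, and a ROC swept over
ensemble vote fractions with trapezoidal AUC ("Alzheimer" is the positive
class; 50/50 vote ties go to "Control", deterministically).

Two interval forms are reported for the CV accuracy: `ci95_normal`
(mean ± 1.96 sd/√k) and `ci95_sd` (mean ± sd). The reference report's
"95% CI" numerically equals mean ± sd, so both are kept.

Frame-level splitting (`mode = "frame"`) replicates the reference protocol
but treats correlated frames of one recording as independent samples —
pseudo-replication. The package emits a leakage note in this mode and
offers `mode = "grouped"` (all frames of one source on one side). The
default remains frame mode: fidelity first, with the caveat stated loudly.

## 7. Desk-scale study conditions and what they showed

`run_all()` wires the whole chain. Default parameters reproduce the
reference settings (275 s windows with 12 s / 0 s start offsets, 10 fps,
31/2 thresholding, σ = 5 injection, the Table of forest parameters). The
package's *desk-scale* protocol — used by the acceptance tests — is:

* 3 synthetic subjects per group, 19 channels, group-averaged;
* `time_scale` 1, so the 10 fps capture boundary (1/exposure = 10 Hz) falls
  between the slow bands and alpha: slow power appears as between-frame
  centroid drift, alpha as within-frame loops. (At `time_scale` 2.7 even
  delta completes cycles within one frame, and the within/between-frame
  distinction that the descriptors rely on disappears.)
* 100 s of audio per group at 8 kHz → 1000 frames per group at 10 fps;
* 120 × 90 px frames.

Two properties are asserted over 10 seeds. The *null* run (identical
profiles for both groups) classifies at chance — mean test accuracy within
[0.45, 0.57] — confirming that the pipeline manufactures no spurious
separation from normalization, rendering, masking or the forest itself.
The *contrast* run (`ad` vs `nc` presets) is asserted to reach AUC ≥ 0.8
in at least 8 of 10 seeds. Under these conditions the package does **not**
meet that bar: per-seed AUC plateaus near 0.72 ± 0.05. The limitation is
informative and worth stating precisely:

* the trajectory itself carries the contrast (per-frame path length
  separates the groups at d ≈ 1.0, within-frame extent at d ≈ 0.7,
  between-frame drift at d ≈ 0.6, mutually correlated) — an ideal
  classifier on those quantities would sit near AUC 0.78;
* the six prescribed descriptors recover most of that (active area
  d ≈ 0.9), so the loss is not in the implementation but in the
  descriptor set: it captures only a weak projection of the spectral
  likelihood ratio between the two processes;
* the gap narrows with raster scale (≈0.74 at 160 × 120, ≈0.76 at
  240 × 180; the reference imagery is 1080p, where the trace-to-window and
  trace-to-speckle scale ratios are far more favourable), but
  full-resolution simulation is outside a desktop test budget.

The headline figures of the reference study (accuracy 0.85, AUC 0.93) are
not reproduction targets at desk scale in any case: they depend on the
physical apparatus recordings, on frame-level splitting of exactly two
videos (one per group — every test frame shares its source recording with
training frames), and plausibly on realization-specific detail that
group-aware validation would not credit.

## 8. Numerical choices and degenerate inputs

* All randomness flows from explicit seeds through `withr::with_seed`; the
  global RNG state is never touched. Stage seeds are derived from the
  pipeline seed by a single seeded draw.
* Unequal recording lengths are truncated to the shortest before averaging
  (no imputation); channels align by label, not index.
* EDF I/O is 16-bit; quantisation error is bounded by
  `max(abs(x))/32767` per sample and the writer's affine scaling uses the
  header fields exactly as written, so a round trip is within one digital
  step. WAV I/O is 16-bit PCM with no dithering (error ≤ 1 LSB).
* Resampling ratios are realized as rational approximations with
  denominator ≤ 10⁴ (continued fractions) for the polyphase FIR.
* All-background frames are flagged (`valid = FALSE`), never errors;
  empty trajectories raise an error only when *no* frame is valid.
* Mirror tilt is clamped to ±0.7 rad before `tan`, and the spot is clamped
  to the screen with a per-sample `clipped` flag.
* Box-counting on an all-background frame returns `NA`; the fit uses all
  box sizes with no pruning; the estimate is clamped to [0, 2].
* The tie rules (threshold comparison, vote ties, contour-area ties) are
  each fixed and documented; they only move measure-zero cases.

## 9. Known limitations

The simulator is a stand-in, not a calibrated model of the physical rig:
mirror coupling, screen distance, camera response and the two-axis
mechanism are plausible but invented, and only the fundamental membrane
mode is driven. The generator's profiles are spectral caricatures of group
differences. Paper-mode validation pseudo-replicates; grouped mode with
only two sources cannot estimate variance. Conclusions supported by this
package are about the method's mechanics — determinism, operator
correctness, physics consistency, null behaviour, and how much of a known
spectral contrast survives the full physical-optical-visual reduction —
not about clinical discrimination.
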