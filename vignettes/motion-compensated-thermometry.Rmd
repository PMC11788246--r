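---
title: "Motion-compensated PRF thermometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-compensated PRF thermometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prftherm)
```

## The problem

MR thermometry by the proton resonance frequency (PRF) shift turns the phase
of a gradient-echo acquisition into a temperature change: water proton
frequency falls by about 0.0094 ppm per degree C, so the phase accumulated
over the echo time TE drops linearly with heating. During a thermal ablation
of a liver tumor two things break the naive "subtract the reference phase"
recipe:

1. **the organ breathes** — between dynamic frames the liver moves by
   several voxels, and the displacement also changes the local magnetic
   susceptibility and hence the background phase;
2. **the heated tissue loses magnitude signal** — close to the applicator
   the signal can drop by 50–80% during energy delivery. Optical-flow
   registration assumes intensity conservation, so this intensity change is
   misread as local motion, corrupting the motion estimate exactly where
   the temperature matters most.

This package implements the full processing chain for this setting, plus a
synthetic phantom generator with exact ground truth, so every stage can be
validated end to end.

## Temperature model

The forward PRF relation implemented in `phase_to_temperature()` is

$$\Delta\phi \;=\; 2\pi\,\gamma\,\sigma\,TE\,B_0\,\Delta T,$$

with $\gamma = 42.58\ \mathrm{MHz/T}$, $\sigma = -0.0094\ \mathrm{ppm/^{\circ}C}$,
and defaults $TE = 18\ \mathrm{ms}$, $B_0 = 1.5\ \mathrm{T}$. Note the
$2\pi$: with phase measured in radians and $\gamma$ in Hz/T it is required
for dimensional consistency (the relation is sometimes printed without it,
which only works if $\gamma$ is taken in rad/s/T). At the default
parameters one radian corresponds to $\approx -14.7\,^{\circ}\mathrm{C}$, and a
phase difference wraps at $|\Delta T| \approx 46\,^{\circ}\mathrm{C}$ — ablations
exceed this, so `temporal_unwrap()` accumulates the per-voxel phase time
course under the assumption (guaranteed by the frame rate relative to the
heating rate) that the true frame-to-frame change stays below $\pi$.

## Registration

**Conventional optical flow.** `estimate_flow_hs()` is a slice-wise 2D
Horn–Schunck solver: brightness-constancy data term plus
$\alpha^2 \|\nabla u\|^2$ smoothness, solved coarse-to-fine (downscale
$\times 2$ per level, Gaussian anti-alias prefilter) with warp updates and
Jacobi sweeps per level. The linearization is taken about the current warp
but solved for the *total* field, so the smoothness term regularizes the
full flow. Defaults: $\alpha = 0.1$ on unit-normalized intensities, 3
pyramid levels, 3 warp updates per level, 100 iterations per warp or a mean
update below $10^{-3}$ voxels. These are standard, well-conditioned values;
all are exposed through `hs_params()`. The method is deliberately 2D — the
acquisition is a stack of thin slices oriented to minimize through-plane
motion, and through-plane flow is out of scope.

**PCA-constrained optical flow.** During a preparative learning phase
(default frames 1–15, before energy delivery) Horn–Schunck flows are
collected and `build_flow_basis()` performs a PCA of the mean-removed,
flattened $(u, v)$ fields, all slices concatenated. Components are retained
until 95% of variance, capped at 5. From frame 16 on, `estimate_flow_pca()`
estimates only the coefficients of this basis by Gauss–Newton on the
linearized residual, spatially weighted by local gradient magnitude. Two
design choices deserve mention:

* the coefficient fit is a $k \times k$ normal system with a tiny ridge for
  conditioning; the small $k$ *is* the method's regularization;
* each coefficient is clamped at $\pm 3$ learning-score standard deviations
  (`score_bound`). Breathing during intervention that resembles learning is
  untouched; what this removes is the pathological case where an intensity
  artifact projects onto a low-variance component and drives its
  coefficient far outside anything seen during learning. This is the
  statistical-motion-model reading of the method: motion during
  intervention is a combination of motions observed during learning, with
  comparable amplitudes.

When the learning flows are identical (no motion at all) the basis
degenerates to zero components with a warning and the PCA estimator returns
the mean flow — which is the correct answer in that situation, and is what
makes the estimator immune to heating artifacts in the motionless limit.

**Reference position.** `select_reference_frame()` estimates the
displacement of each of the first 10 frames against the first, reduces each
to a scalar (spatial mean of the dominant-axis flow component) and picks
the frame at the lower median position — near end-exhale for gated series,
mid-cycle for fixed-frequency series, minimizing the displacements later
applied. The standard (no-registration) workflow uses frame 1 unless an
explicit `reference_frame` is supplied, because selecting a reference by
optical flow would contradict its definition as registration-free.

## Susceptibility phase correction

Breathing displacement modulates the background phase. After registration
this is modelled per voxel as a first-order function of a small set of
motion descriptors: `fit_susceptibility_model()` runs a per-voxel OLS of
the registered, temporally unwrapped learning phases against
`[1, descriptors]`, and `predict_background_phase()` evaluates the model at
the current motion state during intervention. The descriptors are the PCA
motion-basis coefficients — for the PCA workflow directly from the fit, for
the conventional workflow by projecting the Horn–Schunck flow onto the same
basis — capped at 3 by default, so both workflows share one model form. The
model is frozen after the learning phase: refitting during heating would
absorb the heating phase itself into the "background".

## Drift correction and filtering

Scanner drift adds a slow, spatially smooth phase ramp. `drift_correct()`
fits, per frame and slice, a first-order 2D polynomial to the temperature
of unheated in-body voxels (exclusion: any voxel whose $|\Delta T|$ exceeded
3 degrees C at any earlier frame, cumulative) and subtracts the fitted
surface. At least 50 unheated voxels are required, otherwise the slice is
left untouched with a warning.

`lowpass_filter()` is a causal first-order digital Butterworth (bilinear
transform, prewarped cutoff) applied per voxel along time, cutoff 0.14 Hz.
Causality matters because the clinical use is real-time display; zero-phase
filtering would use future frames. Gated series sampled near 4–5 s per
frame cannot support a 0.14 Hz cutoff (it sits at or above Nyquist); the
pipeline then skips temporal filtering with a warning rather than silently
filtering at a different frequency. Gated series with irregular timestamps
use the mean interval for the filter coefficient — the jitter is at most a
few hundred ms on multi-second intervals.

## Dosimetry

`accumulate_cem43()` implements the Sapareto–Dewey cumulative equivalent
minutes at 43 degrees C with the canonical constants $R = 0.5$ above the
43 degree breakpoint and $R = 0.25$ below, on the absolute temperature
(37 degrees C baseline plus the filtered, drift-corrected $\Delta T$).
Lesion masks use the standard 240-minute cell-death threshold. Frames in
which a voxel's temperature is undefined (out-of-bounds after warping, or
outside the body mask) contribute zero dose and a per-voxel valid fraction
is reported; temperatures are not clipped before accumulation. The pipeline
marks air voxels invalid throughout: PRF phase in air is noise, and feeding
it to an exponential dose model would manufacture lesions out of nothing.

## The phantom generator

`generate_series()` builds everything in *material* (tissue) coordinates
and then deforms per frame, so the deforming field, temperature and lesion
extent are exact ground truth:

* **template** — an elliptical liver-like body with two-scale smooth
  texture and dark vessel-like structures. The texture scale is chosen so
  that optical flow is as well-conditioned as on real EPI liver images;
  an overly flat template makes Horn–Schunck noise-dominated in a way real
  data is not.
* **motion** — a dominant head–foot translation modulated by a smooth
  spatial envelope (making the field non-rigid), with a small transverse
  component. The temporal waveform is an asymmetric breathing profile
  $\sin^4(\pi t/T)$ with a flat end-exhale plateau; its cycle mean is
  exactly 3/8, which the tests exploit. Defaults: period 4.5 s (ventilated
  patient), amplitude 4 voxels. Gated mode samples near end-exhale with a
  small positional jitter (0.2 voxels); fixed-frequency mode samples the
  cycle at 2 s.
* **phase** — baseline field map (smooth ramps plus a smooth random field,
  about 1 rad of spatial variation), plus a susceptibility term linear in
  the local displacement (0.05 rad/voxel), plus the forward PRF phase of
  the true temperature, plus a uniform drift (0.002 rad/frame).
* **heating** — a Gaussian hotspot ramping to +50 degrees C with a
  saturating rise and exponential cooling; the magnitude drop (up to 50%
  by default, 80% observed clinically) is time-locked to the temperature
  rise. No heating means no dropout.
* **noise** — additive complex Gaussian before magnitude/phase extraction,
  giving physically consistent Rician magnitude statistics (2% of peak
  magnitude by default).

What the generator does **not** emulate: through-plane motion, gas-bubble
susceptibility transients, EPI ghosting and distortion, coil shading, and
the post-ablation hyperintense rim. Passing tests on these phantoms
therefore demonstrate the correctness and the qualitative failure-mode
behaviour of the processing chain, not clinical performance on patient
data.

Because ground truth lives in material coordinates while workflow outputs
live on the selected reference frame's grid, `true_flow_to_reference()` and
`true_temperature_at_reference()` map the truth onto the reference grid
(exact for translations, first-order in the envelope's spatial variation
otherwise).

## Evaluation design

The package's acceptance experiments (see `scripts/acceptance.R` in the
source repository) use two controlled phantoms at deliberately modest
problem sizes — 64 x 64 x 3 voxels, 60–70 frames — so a full three-workflow
comparison runs in seconds:

* a **motionless, noise-free gated phantom with 50% hotspot dropout**: the
  cleanest isolation of the intensity-artifact mechanism. Conventional
  optical flow produces several voxels of spurious deformation inside the
  hotspot and underestimates the lesion volume; the PCA-constrained flow is
  immune. With realistic noise added, a floor of 0.2–0.4 voxels of apparent
  flow appears for *both* OF variants — dominated by the noise of the
  single reference frame, which biases all flows coherently — matching the
  sub-millimetre residual reported for the constrained method on clinical
  gated data. The noise-free experiment separates the mechanism under test
  from that floor.
* a **breathing fixed-frequency phantom** (4-voxel amplitude, 0.5 Hz
  sampling, 2% noise) with heating: uncompensated phase subtraction is off
  by more than 5 degrees C RMS in the hotspot ROI, while the full
  PCA workflow (registration + susceptibility correction + drift + filter)
  recovers the true temperature to well under 1 degree C RMS with
  negligible bias.

Metrics follow the field's conventions: whole-image intercorrelation
averaged over slices; root-mean-square error in intensity or degrees C
(the conventional "NRMSE" name is kept although the printed formula is not
normalized — a `normalize` flag is available); endpoint error in mm over a
19 x 19 ROI centred on the ablation, restricted to voxels that exceeded
10 degrees C at any frame; Bland–Altman agreement of lesion volumes over
the last 10 frames. The ablation centre is supplied explicitly (ground
truth in synthetic mode) — needle localization is out of scope. AEE pools
all included voxels across slices.

## Degenerate inputs and numerical details

* Zero-variance images yield a zero flow with a warning; non-finite inputs
  are rejected.
* Out-of-bounds warp samples are marked invalid (`NA`) and excluded from
  metrics and dose rather than extrapolated.
* Phase is always warped through its complex representation (real and
  imaginary parts interpolated separately), never interpolated directly
  across wraps.
* The susceptibility OLS falls back to a QR pseudo-solve when descriptors
  are rank-deficient (e.g. constant in a motionless series).
* Tie-breaks: reference-frame selection takes the earliest frame at the
  median position.
* All randomness is confined to the generator and controlled by the config
  seed; the processing pipeline is deterministic, so identical inputs give
  bit-identical outputs.

## Known limitations

* 2D slice-wise flow cannot represent through-plane motion; a strong organ
  contraction during ablation (observable as a drop in the
  intercorrelation trace) invalidates the motion model.
* The susceptibility model is first-order in the motion descriptors and
  frozen after learning; large excursions outside the learned motion range
  are bounded by the coefficient clamp but not extrapolated.
* DICOM ingestion is not built in; series are expected as NIfTI (the
  stored-phase integer dialect and a vendor override are handled by
  `rescale_phase()` / `normalize_phase()`).
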