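# prftherm

Motion-compensated PRF MR thermometry and thermal dosimetry for MRI-guided
ablation of mobile organs.

## The problem

During percutaneous thermal ablation of liver tumors, MRI can map the
temperature in every voxel in real time through the proton resonance
frequency (PRF) shift: the image phase changes linearly with temperature,

```
Δφ = 2π · γ · σ · TE · B0 · ΔT,     γ = 42.58 MHz/T, σ = −0.0094 ppm/°C
```

so subtracting a pre-heating reference phase yields ΔT (about −14.7 °C per
radian at TE = 18 ms, 1.5 T). On a breathing patient this breaks twice
over: the liver moves by several voxels between frames (and the motion
modulates the background phase through magnetic susceptibility), and the
heated tissue loses up to 50–80% of its magnitude signal, which
intensity-based registration misreads as local motion — corrupting the
temperature estimate precisely at the ablation site.

`prftherm` implements three complete processing workflows over dynamic
magnitude/phase series:

* **standard** — fixed-reference phase subtraction (the gold standard when
  there is no motion);
* **conventional_of** — per-frame deformable registration by Horn–Schunck
  optical flow, plus motion-parameterized susceptibility phase correction;
* **pca_of** — optical flow constrained to a PCA basis of breathing motion
  learned from a 15-frame preparative phase: during intervention the
  motion estimate is a linear combination of eigen-motions, so localized
  heating artifacts cannot masquerade as deformation.

All three share the downstream chain: temporal phase unwrapping, spatial
drift correction, causal 0.14 Hz Butterworth filtering, Sapareto CEM43
thermal dose with the 240-min cell-death threshold, and lesion-volume
estimation. A synthetic abdominal phantom generator with exact ground
truth (respiratory motion, gated vs 0.5 Hz fixed-frequency sampling,
motion-coupled susceptibility phase, PRF heating with signal dropout,
complex noise, drift) plus the field's evaluation metrics
(intercorrelation, NRMSE, endpoint error, Bland–Altman) complete the
package.

## Worked example

Simulate a breathing patient sampled at 0.5 Hz with a +50 °C ablation and
50% signal dropout, then run and compare the three workflows against the
known ground truth:

```r
library(prftherm)

cfg <- phantom_config(grid = c(64, 64, 3), n_frames = 70, frame_interval = 2,
                      mode = "fixed_frequency", displacement_amplitude = 4,
                      heating_window = c(16, 55), peak_delta_t = 50,
                      max_signal_drop = 0.5, seed = 202)
gen <- generate_series(cfg)
gen$series
#> dynamic_series: 64 x 64 x 3 voxels, 70 frames, dt = 2 s, spacing = 2.5 x 2.5 x 3 mm

cmp <- compare_workflows(gen$series,
  list(standard     = workflow_config("standard"),
       conventional = workflow_config("conventional_of"),
       pca          = workflow_config("pca_of")),
  truth = gen$truth)
cmp
#> workflow_comparison
#>   standard         median T-RMSE =  6.22 degC | final lesion = 2.62 cm^3 | volume bias = -0.37 cm^3
#>   conventional     median T-RMSE = 10.38 degC | final lesion = 1.71 cm^3 | volume bias = -1.33 cm^3
#>   pca              median T-RMSE =  0.63 degC | final lesion = 2.79 cm^3 | volume bias = -0.19 cm^3
```

Reading the report: per-frame temperature RMSE is computed over a 19 × 19
ROI centred on the ablation (only voxels that exceeded 10 °C are included)
against the ground-truth temperature warped to each workflow's reference
position. Uncompensated subtraction is off by ~6 °C RMS because the organ
breathes; conventional optical flow is *worse* near the hotspot (~10 °C)
because the signal dropout bends its motion field; the PCA-constrained
workflow recovers the temperature to well under 1 °C and the most accurate
lesion volume (truth: 2.98 cm³). A `drift correction skipped` warning for
the standard workflow is expected here — its motion artifacts exceed the
heated-voxel exclusion threshold across the body, which is the
conservative intended behaviour.

The `inst/cli/prftherm.R` script exposes `simulate`, `run` and `evaluate`
subcommands over the same functions for shell use.

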