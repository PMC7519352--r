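# flotr

Fluorescence laminar optical tomography (FLOT) in silico: simulate a
line-scan FLOT acquisition of a photosensitizer-filled capillary inside a
scattering phantom, reconstruct the 3-D fluorophore distribution through a
Monte-Carlo-derived Born sensitivity matrix with Tikhonov/L-curve
inversion, and quantify how much depth-dependent signal loss the
tomographic reconstruction recovers compared with plain maximum intensity
projection (MIP) imaging.

## Who this is for

Researchers in mesoscopic fluorescence imaging (laminar optical
tomography, photodynamic-therapy dosimetry, photosensitizer imaging) who
want a tested, reproducible digital twin of the classic phantom
experiment: a 100-µm capillary of photosensitizer tilted 23.5° into an
intralipid-like slab (µa = 0.01 mm⁻¹, µs = 15 mm⁻¹, g = 0.9, n = 1.33;
µs′ = 1.5 mm⁻¹ at 690 nm), scanned with a 20-µm line beam at 135°
incidence over 300 stage positions and imaged by a 12-bit camera.

## The model

Under the first Born approximation, the background-subtracted
fluorescence measured with the source line at *r*ₛ and a detector pixel
at *r*_d is

ΔF(*r*ₛ, *r*_d) = Σ_v G(*r*_d − *r*_v) · O(*r*_v) · Φ(*r*_v − *r*ₛ) · ΔV,

with Φ the excitation fluence, G the emission escape (Green's) function —
both computed by voxel Monte Carlo photon transport (Henyey–Greenstein
scattering, Fresnel surface, track-length estimator) — and O ≥ 0 the
voxel fluorophore yield. Writing ΔF = W·ΔO, the volume is recovered by
Tikhonov regularization, min ‖WΔO − ΔF‖² + λ²‖ΔO‖², with λ chosen by the
L-curve criterion and an optional per-layer depth-compensation weighting
(exponent γ ∈ [0, 3]) that counteracts the shallow bias of
reflection-geometry sensitivity.

## Worked example

```r
library(flotr)

cfg <- pipeline_config(data_seed = 101, w_seed = 202)
run <- run_pipeline(cfg)   # ~4 min on one core
print(run)
```

```
<flot_run>
  lambda* = 0.04133
  1/e depth: FLOT 958 um, MIP 162 um
  FWHM: XY 87 um, XZ(0) 89 um, XZ(600) 344 um
  max detectable depth: 1.13 mm
```

Reading these numbers: the raw-stack MIP signal, normalized at the
surface, falls to 1/e of its surface value within ~160 µm — the steep
near-surface attenuation of an ideal-optics line-scan measurement —
while the FLOT reconstruction holds its normalized signal to ~1 mm
before crossing 1/e, and the reconstructed capillary stays above the
blank N + 3σ detection threshold down to ~1.1 mm. The capillary
cross-section reconstructs at ~90 µm FWHM near the surface (the phantom
capillary is 100 µm wide) and smears axially as depth grows.

```r
autoplot(run$comparison)        # FLOT vs MIP depth-decay curves
tidy(fit_exponential(run$mip_curve))  # effective attenuation of the MIP
run$resolution                  # FWHM table (XY, XZ at 0 and 600 um)
```

Individual stages are exposed as plain functions if you want to swap any
piece: `phantom_recipe()`, `simulate_fluence()` / `emission_green()` /
`mc_kernels()`, `simulate_scan()`, `build_weight_matrix_conv()`,
`depth_compensate()`, `tikhonov_solve()` / `l_curve_select()` /
`reconstruct_volume()`, `orthogonal_stack()` / `mip()`, and the metrics
layer (`depth_profile()`, `one_over_e_depth()`, `fwhm()`,
`limit_of_detection()`, `compare_flot_mip()`). Stacks and volumes
round-trip through multi-page 16-bit TIFF with JSON sidecars
(`write_stack()`, `read_stack()`, `write_volume()`), curves through CSV.

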