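---
title: "Depth-resolved fluorescence laminar optical tomography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved fluorescence laminar optical tomography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(flotr)
```

## The problem

Widefield fluorescence imaging of a fluorophore embedded in a scattering
medium — a photosensitizer-filled capillary in an intralipid phantom or in
brain tissue — loses signal roughly exponentially with depth, because both
the excitation light on its way in and the emission on its way out are
attenuated by scattering. Laminar optical tomography (LOT) exploits the
mesoscopic regime: photons re-emitted farther from the illumination line
have, on average, travelled deeper, so a camera that records many
source–detector separations at once contains enough information to
reconstruct a three-dimensional fluorophore distribution and to compensate
the depth-dependent signal loss that a plain maximum intensity projection
(MIP) cannot.

`flotr` implements this experiment end to end in silico:

1. a voxel Monte Carlo photon-transport engine (excitation fluence and
   adjoint emission Green's functions);
2. a synthetic line-scan acquisition with a CCD noise model, producing the
   300-frame oblique measurement stack;
3. assembly of the Born sensitivity matrix `W` from the Monte Carlo
   kernels, with optional per-layer depth compensation;
4. Tikhonov inversion with L-curve selection of the regularization
   strength;
5. the quantification layer: MIP comparators, depth-decay curves, 1/e
   depths, exponential attenuation fits, FWHM resolution profiles, and the
   N + 3σ limit of detection.

## Forward model

Under the first Born approximation the background-subtracted fluorescence
measured with the source line at $r_s$ and a detector pixel at $r_d$ is

$$\Delta F(r_s, r_d) \;=\; \sum_{v} G(r_d - r_v)\, O(r_v)\,
\Phi(r_v - r_s)\, \Delta V,$$

where $\Phi$ is the excitation fluence per launched photon, $G$ the
probability density that emission from voxel $v$ reaches the pixel, and
$O \ge 0$ the per-voxel fluorescence yield. In a homogeneous slab both
$\Phi$ and $G$ are translation invariant along the scan, so one Monte Carlo
kernel pair serves all 300 stage positions (a block-convolutional forward
model). The same kernels generate the synthetic data and the sensitivity
matrix — but always from *different* random seeds and budgets, enforced by
the pipeline's inverse-crime guard.

## Monte Carlo transport

The engine is a standard voxel Monte Carlo: exponential step sampling at
$\mu_t = \mu_a + \mu_s$, Henyey–Greenstein scattering with anisotropy $g$,
continuous absorption weighting, Russian roulette below weight $10^{-4}$
(survival 0.1), unpolarized Fresnel reflection/refraction at the $z = 0$
surface against ambient $n = 1$, and termination at the lateral and bottom
faces. Fluence uses the track-length estimator, which remains defined for
non-absorbing media and gives far lower variance than absorption-site
scoring at $\mu_a = 0.01\,\mathrm{mm^{-1}}$. The generator is a
self-contained xoshiro256++ stream, so results are bit-reproducible for a
given seed regardless of R's RNG state. Excitation and emission use the
same 690-nm optical properties (the emission band is ~700–735 nm; only
690-nm properties are available for the phantom).

Verification: Beer–Lambert decay to 2% at optical depth 1 in the
absorbing-only mode; agreement within 15% at $z = 3$ mm with the
semi-infinite diffusion solution (isotropic point source at one transport
length, extrapolated boundary from numerically integrated Fresnel
moments); an energy audit `(absorbed + escaped)/launched = 1` to $10^{-3}$
on every run; source-swap reciprocity; $\sqrt{N}$ error scaling.

### Detector model

The camera sits behind an imaging objective, normal to the surface. A
surface-contact detector accepting the full inward hemisphere
(cosine-weighted) is dominated by the $1/r^2$ near field of the voxel
directly beneath the pixel — its Green value drops ~50× over the first
100 μm — which no objective-imaged camera observes and which would make
every depth metric a statement about the first two voxels. The adjoint
launch is therefore cosine-weighted *within an acceptance cone* of
numerical aperture `collection_na` (default 0.12, a low-magnification
imaging objective; the instrument's NA is unpublished). The full-hemisphere
contact detector and a normal-pencil adjoint (used by the reciprocity
cross-check against `simulate_fluence()`) remain available through
`emission_green()`.

## The digital phantom

`phantom_recipe("paper_phantom")` encodes the study conditions: a
homogeneous slab with $\mu_a = 0.01$, $\mu_s = 15\,\mathrm{mm^{-1}}$,
$g = 0.9$, $n = 1.33$ (so $\mu_s' = 1.5\,\mathrm{mm^{-1}}$ at 690 nm),
containing a 100-μm-ID capillary of yield 2.5 (concentration units)
descending at 23.5° from the surface in the scan-direction vertical plane.
The glass wall is not modelled. The acquisition is a 300-position stage
scan under a 20-μm-FWHM line beam incident at 135°, recorded by a 12-bit
camera whose 2.9-μm pixels are binned to the 25-μm voxel pitch; detector
offsets extend to 2.4 mm from the line (source–detector separations of
roughly twice the target depth carry the deep sensitivity, and the
camera's ~2.9-mm field of view spans them). CCD noise is Poisson shot
noise on counts, Gaussian read noise (σ = 5 counts) and a dark level of
100 counts; exposure scales the brightest noiseless pixel to half full
scale, and the source-line light leakage is rendered as a saturated column
that every downstream stage masks.

Desk-scale choices (stated once here): 25-μm voxels on a
224 × 52 × 56 grid (5.6 × 1.3 × 1.4 mm), 10^6 photons per Monte Carlo
kernel, every 5th stage position and every 4th offset column as sensitivity
rows, and 25 reconstructed along-line columns. The `"paper_exvivo_analog"`
recipe is a synthetic uniform brain-like slab (μs = 20, μa = 0.02,
n = 1.37 — typical cortex-scale values, not measured ones) with the 150-μm
capillary of the ex vivo protocol.

## Inversion

`reconstruct_volume()` solves two coupled views of the 2.5-D inverse
problem with the shared x–z sensitivity matrix:

* the **along-line-summed** measurements, whose line-detector forward
  model matches `W` exactly: this yields the quantitative x–z image used
  for every depth metric;
* **each along-line column independently**, which resolves the lateral
  (y) structure near the surface and supplies the XY resolution profile.
  Deep emission spreads over many columns, so per-column amplitudes
  under-weight depth — measured at roughly a factor of ten at 500 μm —
  which is why depth quantification never reads this view.

The solver is damped CGLS (conjugate gradients on the regularized normal
equations) on the sparse `W`, with a block right-hand side so that all
columns advance in lockstep; entries of `W` below $10^{-6}\,\max W$ are
dropped as Monte Carlo shot-noise floor. Nonnegativity is imposed by
clipping after the linear solve. The regularization strength is chosen by
the L-curve criterion: 20 log-spaced values spanning
$[10^{-4}, 10^{2}] \times \sigma_1(W)$, with the sweep's
residual/solution norms evaluated through a single Golub–Kahan
bidiagonalization of the system (one Krylov basis shared by all λ values;
independently under-converged per-λ iterative solves flatten the
small-λ branch of the curve and generate spurious curvature maxima).
The corner is the maximum signed finite-difference curvature of
$(\log\rho, \log\eta)$, ties broken toward larger λ; curvature is not
evaluated on numerically flat stretches.

### Depth compensation

Tikhonov inversion of a reflection-geometry sensitivity matrix places
objects too shallow: without compensation the reconstructed capillary-axis
depth saturates near ~400 μm while the true axis keeps descending. The
depth-compensation weighting counters this with a per-layer diagonal
built from maximum singular values of the layer blocks of `W`, assigned in
reverse depth order and raised to an adjustable exponent
$\gamma \in [0, 3]$; the compensated system `W D` is solved and the
solution mapped back through `D`. (The source equation for this weighting
is printed ambiguously — "the forward matrix from the first to the l'th
layer" — and defines only the diagonal; this implementation follows the
cited depth-compensation literature: per-layer blocks, reversed
assignment, column scaling, "max single value" read as maximum singular
value.) The pipeline default is $\gamma = 1$: it is the smallest strength
at which the reconstructed axis depth tracks the ground truth
monotonically over the full descent of the phantom capillary; at
$\gamma \gtrsim 1.3$ (the optimum reported for a centimeter-scale diffuse
tomography geometry) shallow segments are thrown into deep artifacts,
and at $\gamma \le 0.5$ deep segments collapse toward the surface.

## Quantification

The MIP comparator is the per-pixel maximum of the orthogonally stacked
raw frames (leakage masked, no shear correction), exactly the 2-D image a
projection of the oblique stack gives. Depth-decay curves are extracted
along the known capillary track: for each scan position the peak intensity
near the expected location, averaged over five track samples (the
capillary's circular cross-section projects onto
$\mathrm{ID}/\sin 23.5^\circ \approx 250\,\mu m$ of scan travel, so
adjacent samples see the same physical segment and the average suppresses
voxel-scale ringing), background-subtracted, then normalized at the
shallowest fully-submerged sample. The 1/e depth is the first linear
interpolated crossing of $e^{-1}$; curves that never cross report the
deepest sampled depth with a flag. `fit_exponential()` fits
$I(z) = I_0 e^{-\mu_{\mathrm{eff}} z}$ log-linearly. FWHM is measured
between linearly interpolated half-maximum crossings after subtracting
the profile-tail background (a Gaussian-fit variant was considered and
rejected as the default because the reconstructed cross-sections are
visibly non-Gaussian). The limit of detection is $N + 3\sigma$ of a blank
acquisition; to apply it to the reconstruction the blank *stack* is
reconstructed with the same `W`, λ and γ, and the threshold is
$N + 3\sigma$ of that blank reconstruction — like units compared with
like. The FLOT-vs-MIP dominance check allows the MIP curve a 2%-of-surface
tolerance, the positive bias of a max-statistic extraction's noise floor.

## What the synthetic data does and does not emulate

The generator reproduces the geometry, optics, scanning, quantization and
first-order noise of the instrument. It does **not** model the objective's
point-spread function, lens vignetting, the capillary's glass wall
(OD 0.17 mm) or refractive contrast, motion blur, or exposure saturation.
Consequences worth knowing when reading the test numbers:

* Reconstructed cross-sections are *sharper* than the instrument's
  (surface XZ FWHM ~90 μm versus the reported 143 ± 15 μm): ideal optics
  plus a 20-μm line make the in-silico system better-resolved than the
  physical one.
* The simulated MIP decays much faster near the surface (1/e at
  ~160–170 μm versus 588 ± 27 μm): an ideal-optics line-scan measurement
  of this phantom genuinely collapses within the first two hundred
  micrometres. The published gentle MIP decay is quantitatively consistent
  with shallow pixels saturating a 12-bit camera exposed to retain deep
  signal; the generator deliberately never saturates (exposure pinned at
  half full scale), so this discrepancy is expected and documented rather
  than tuned away.
* Depth metrics that probe the *reconstruction* (FLOT 1/e depth around
  1.0–1.1 mm, ~60–80% signal retention at 500 μm, detectability to
  ~1.0–1.2 mm) land close to the published figures, because they are
  dominated by transport physics and the inversion rather than by camera
  optics.

## Numerical choices and degenerate inputs

Isotropic voxels only; anisotropic grids are rejected. Half-open voxel
intervals, $z = 0$ at the surface. Zero-scatter media are permitted only
in the flagged analytic test mode. `tikhonov_solve()` iterates to a
relative gradient tolerance of $10^{-8}$ by default (volume solves use
$10^{-6}$ and an iteration cap of 150 at desk scale); λ = 0 on a
rank-deficient system returns the minimum-norm solution with a warning
flag. Degenerate L-curve sweeps (single point, identical points) are
flagged or rejected. Stage positions are rounded to the voxel lattice for
the convolutional `W`; the simulated frames use the exact positions, a
deliberate sub-voxel model mismatch that keeps the inversion honest.

## Known limitations

The 2.5-D treatment cannot deconvolve along-line blur, so XY resolution
reflects the measured y-spread rather than a true 3-D inversion. The
homogeneous-slab fast path does not apply to heterogeneous media (the
general per-source assembly exists but is desk-intractable for the full
recipe). Reported depth metrics beyond ~1.2 mm are limited by the 1.4-mm
grid. The ex vivo analog recipe uses synthetic optical properties and is
not a quantitative stand-in for brain tissue.
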