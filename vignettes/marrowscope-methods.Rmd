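---
title: "Methods: quantitative imaging of the bone-marrow vascular niche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative imaging of the bone-marrow vascular niche}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marrowscope)
```

# Scope

`marrowscope` implements the quantitative readouts used to characterize
bone-marrow vasculature in cardiovascular-disease models: macromolecular
DCE-MRI (fractional blood volume and permeability), intravital
vascular-leakage and target-to-background quantification, line-scan
velocimetry with the acetylcholine Δvelocity statistic, and vessel
morphometry. A synthetic-phantom module generates every input with known
ground truth, so each stage is validated by parameter recovery rather than
by visual inspection.

# The DCE-MRI chain

## Signal model

Variable flip-angle (VFA) acquisitions are modeled with the steady-state
spoiled gradient-echo (FLASH) equation

$$S(\alpha) = S_0 \sin\alpha \, \frac{1 - E_1}{1 - E_1\cos\alpha},
  \qquad E_1 = e^{-\mathrm{TR} \cdot R_1},$$

the standard model for this acquisition (the source protocol states only a
"nonlinear best fit" on VFA FLASH data). `fit_vfa_r1()` minimizes the
least-squares residual of this model over $(R_1, S_0)$, starting from the
DESPOT1 linearization ($S/\sin\alpha$ against $S/\tan\alpha$) and refining
with Nelder–Mead in log-parameters. Restarts use *fixed* perturbations of
the start so the fit never consumes global RNG state: analyses are
deterministic by construction. A flat signal across flip angles spanning
2–70° is inconsistent with the model and raises an error rather than
returning a meaningless fit.

Post-contrast images are acquired at a single flip angle (default 50°), so
$R_1(t)$ comes from the closed-form inversion

$$E_1 = \frac{S_0\sin\alpha - S(t)}{S_0\sin\alpha - S(t)\cos\alpha},$$

using $S_0$ from the pre-contrast fit. The model saturates at
$S_0\sin\alpha$; signals at or beyond saturation (or at zero) are
non-physical and raise errors. In pixelwise maps such pixels are flagged,
counted, and excluded from mask means instead.

## Concentration, normalization, and the two-parameter model

Contrast concentration is $C = (R_1(t) - R_{1,\mathrm{pre}})/r_1$ with the
relaxivity $r_1$ defaulting to 145 mM⁻¹ s⁻¹, the macromolecular
albumin–GdDTPA value (the source prints "145 mM s⁻¹", which we read as the
conventional per-mM-per-second unit; it is configurable). Negative
differences, which arise from noise, are clamped to zero *and counted* —
the clamp count is part of every run report as a data-quality signal.

Tissue concentration is normalized to the blood-pool concentration from a
vena-cava ROI. For a macromolecular agent that (over a 4-minute window)
leaks slowly and unidirectionally, the normalized curve is linear in time:

$$\frac{C_t(t)}{C_b(t)} = \mathrm{FBV} + \mathrm{PS}\cdot t,$$

so ordinary least squares gives the fractional blood volume as the
intercept extrapolated to the time of contrast administration ($t = 0$)
and the permeability–surface-area product PS as the slope, reported in
min⁻¹ regardless of the input time unit. Time points where the blood
concentration is non-positive are dropped, not imputed. Timestamps are
always taken from metadata; the module never assumes a frame rate.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `relaxivity` | 145 | mM⁻¹ s⁻¹ | published macromolecular agent value |
| `flip_angles_pre` | 2, 6, 9, 15, 25, 50, 70 | deg | published protocol |
| `flip_angle_post` | 50 | deg | published protocol |
| `tr` | 25 | ms | published protocol |
| `sample_times` | 25–240 by 25 | s | dynamics every 25 s for 4 min |

# Leakage and target-to-background

Vascular leakage follows the published procedure literally: the first
post-injection frame is thresholded (Otsu within the marrow ROI; a fixed
threshold can be supplied) to segment the vasculature; later frames never
influence the mask. Per post-injection frame, $I_{in}$ is the mean
intensity over the mask and $I_{out}$ the mean over the marrow outside the
mask and the osseous exclusion; the leak rate is the OLS slope of
$I_{out}/I_{in}$ over time, per minute. Because it is a ratio of means, it
is exactly invariant to global intensity rescaling. The source does not
state whether the vessel mask was dilated before defining the out-region
or whether background was subtracted; we do neither by default and expose
dilation as a switch.

TBR is the ratio of the mean maximum-intensity projection over the marrow
ROI to the mean over the osseous background ROI, with a configurable
projection depth (default 16 slices, the published setting).

# Velocimetry

Erythrocytes appear as dark streaks in bright labelled plasma, so
kymographs are inverted and per-line medians subtracted (removes
illumination drift without affecting slope). For a candidate streak slope
$s$ px/line the image is projected along the sheared direction
$b = x - s t$; the projection profile is sharpest — maximal
count-weighted variance of the bin means — when $s$ matches the streaks.
Pixel weight is splatted linearly between the two adjacent bins so the
score varies smoothly in angle; a 2° coarse pass is followed by the 0.25°
grid around the coarse peak and parabolic interpolation. Velocity is
$\tan\theta \cdot \text{pixel size}/\text{line period}$ (μm/ms ≡ mm/s),
signed by direction along the scan line; a peak at the angle-grid edge is
flagged unresolvable (cell faster than the scan). Mirror symmetry
(position-axis flip negates velocity) is enforced by construction and
tested.

Δvelocity = stimulated − baseline, per vessel; positive is the healthy
vasodilation response to acetylcholine, negative the impaired response
characteristic of endothelial dysfunction. Per-animal summaries are
unweighted means across the 2–6 scanned arterioles, computed after the
per-vessel Δ (the source does not state the order; we document ours).

# Morphometry

Vessel masks come from Otsu thresholding within the marrow ROI
(overridable). Skeletons use Zhang–Suen thinning; branch points are
skeleton pixels with ≥3 skeleton neighbours in 8-connectivity, with
adjacent branch pixels merged into one junction. Projected crossings are
counted as junctions *without* superimposition correction, mirroring the
published analysis; counts therefore overestimate true 3-D branching in
dense networks.

Sprouts are skeleton endpoints traced back to the nearest junction. The
protrusion length is the geodesic path length (diagonal steps √2 × pixel
size) **plus the local mask half-width at the tip**: thinning retracts
stroke tips by roughly the capsule radius, and without the correction a
true 10 μm sprout measures ≈8 μm — fatal under the strict ">8 μm" counting
rule, which we apply exactly (a sprout of exactly 8 μm is not counted).
Endpoints closer to the image border than their own half-width + 2 px are
vessels leaving the field of view, not sprouts, and are excluded.

Cell-to-vessel proximity uses the exact Euclidean distance transform
(Felzenszwalb–Huttenlocher) of each vessel mask, sampled at thresholded
cell *pixels* (not segmented cells, per the published procedure) outside
the osseous ROI, reported in μm with <40/≥40 μm bin counts. Distances are
center-to-center to the nearest vessel *mask* pixel (vessel surface, not
centerline) — the natural reading of "distance to the nearest blood
vessel".

# The synthetic world

The generators state the acquisition the package expects:

- **Leakage stacks**: 25 frames at 1.2 s (the published time-lapse),
  vessels at a constant intravascular intensity, extravascular marrow
  rising linearly at the true rate from the injection frame, osseous
  region held at background. Vessels here are rendered with *hard* edges:
  the closed-form check leak_rate = slope/inside-intensity requires the
  mask-mean intravascular signal to equal the nominal intensity exactly,
  which a soft edge breaks by ~5%. Morphometry scenes keep the 1-pixel
  anti-aliased edge (stable segmentation is what matters there).
- **Kymographs**: Gaussian-profile dark streaks advancing
  `velocity × line period / pixel size` px/line, with uniform expected
  streak coverage per line; zero density yields a flagged uniform image.
- **VFA/DCE phantoms**: SPGR signals at the published flip angles/TR; the
  tissue curve encodes `(FBV + PS·t)·C_blood(t)`; cohort mode draws
  per-phantom FBV from Normal(0.208, 0.044) truncated to (0, 1) — the
  published healthy-marrow mean ± s.d. (n = 6). The default blood pool is
  0.05 mM: with relaxivity 145 this gives post-contrast blood R1 ≈ 8 s⁻¹
  (T1 ≈ 125 ms), a physiologic post-injection value.
- **Morphometry scenes**: capsule vessels plus sprout protrusions with
  analytic ground truth (pairwise centerline intersections for branch
  points; stated sprout lengths; distance-to-capsule-surface for cells).

Noise is additive Gaussian clipped at zero; fluorescence phantoms at this
scale do not need full Poisson–Gaussian mixtures, and the zero-noise limit
keeps closed-form checks exact. The cohort preset's measurement noise
(noise_sd = 0.1 a.u.) comes from ROI-averaging physics: pixel SNR ≈ 50 at
the post-contrast tissue signal (≈115 a.u., i.e. pixel noise ≈ 2 a.u.)
averaged over a femur ROI of ~400 voxels. Seeds are mandatory spec fields,
never global state, and generators restore the caller's RNG stream.

What a green test does **not** establish: phantoms have no motion, no
photobleaching, no point-spread function, no B1/flip-angle bias, no
arterial input dynamics beyond the stated blood curve, and no 3-D vessel
geometry. Recovery on phantoms validates the computational chain, not the
biology; group differences between diseased and healthy animals require
real imaging data and are out of scope.

# Numerical choices

- Otsu thresholding uses a 256-bin histogram over the ROI; constant
  regions raise errors rather than returning arbitrary thresholds.
- The VFA fit treats convergence to a residual below 1e-12 of the signal
  energy as exact and skips remaining restarts.
- Negative concentrations clamp to 0 with counting; blood time points with
  non-positive concentration are dropped from the regression.
- The distance transform is exact (two-pass 1-D lower envelopes), verified
  against exhaustive search on random scenes up to 128×128.
- Junction clustering merges adjacent (8-connected) branch pixels; this
  approximates the published tool's junction merging without reproducing
  its internals, which is explicitly out of scope.
- CSV outputs carry units in every numeric column header and are written
  deterministically; reruns with the same config are byte-identical.

# Known limitations

- The branch-point count inherits the projection superimposition bias of
  the published procedure by design.
- The sheared-projection estimator assumes one dominant streak population;
  kymographs with two crossing cell streams return the dominant slope.
- The TIFF codec reads only what the package writes (uncompressed
  grayscale baseline TIFF); compressed or tiled files from microscopes
  should be converted first. An OME-TIFF importer is a documented
  extension point.
- Pixelwise parametric maps fit each pixel independently; no spatial
  regularization is applied.
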