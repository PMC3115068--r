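---
title: "Methods: simulating and analysing post-mortem whole-brain diffusion MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing post-mortem whole-brain diffusion MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pmdti implements the analysis workflow for diffusion-weighted MRI of whole,
fixed, post-mortem human brains acquired on clinical 3 T hardware with 3D
segmented-EPI spin-echo sequences. Fixed tissue differs starkly from the
living brain: diffusivity is roughly ten-fold lower (white matter MD around
0.07--0.09 x 10^-3 mm^2/s), anisotropy is halved (white matter FA around
0.22--0.32), and the specimen is immersed in a proton-free, susceptibility-
matched fluid that contributes no signal. Acquisitions therefore use strong
diffusion weighting (b = 4500 s/mm^2), many averages, and day-long scan
times, and the analysis has to contend with scanner drift accumulated over
those hours. This vignette records the models the package implements, the
choices made where the design was genuinely open, and what the synthetic
tests do and do not establish about real data.

## The digital specimen

`build_specimen_phantom()` generates the ground-truth object every other
module is tested against. Its tissue classes are parameterised by axial and
radial diffusivity (units 10^-3 mm^2/s throughout) with axially-symmetric
tensors, using the fixed-tissue group means for five white matter ROIs (CC,
SLF, Opt, Cing, PLIC) and three deep gray ROIs (Thal, Caud, Put). One
printed caudate axial diffusivity (2.01) is inconsistent with its own MD and
radial diffusivity; the value implied by MD = (D_ax + 2 D_rad)/3, 0.201, is
used instead.

Geometry, in order of assignment priority:

* two straight white matter slabs (CC analog along x, SLF analog along y)
  that cross in the specimen centre, plus three rods; structures are 3--4
  voxels thick, matching the thin-tract regime that makes high-resolution
  post-mortem imaging interesting in the first place;
* three deep-gray spheres;
* a folded cortical ribbon generated by the surface
  z = z0 + A sin(2 pi c x / nx). Cortical tensors point along the analytic
  surface normal (radial cortical anisotropy). The deepest cortical layer is
  a "dark band" whose thickness tracks the local surface slope, 0 voxels at
  gyral crowns to 2 voxels on sulcal walls, with nearly-isotropic tensors so
  its FA sits below both cortex and white matter; a white matter layer lies
  directly beneath the ribbon;
* a near-isotropic tissue "matrix" filling the deep interior, so that white
  matter borders tissue rather than immersion fluid. This matters for the
  distortion experiments: a structure bordered by zero-signal background is
  invisible to misregistration in FA, because background mixing rescales all
  volumes of a voxel equally;
* zero-signal background everywhere else, and a smooth multiplicative S0
  modulation (amplitude 0.1, coil-shading-like) over tissue, which gives the
  mutual-information cost useful intensity structure.

The forward model is the noiseless tensor signal S = S0 exp(-b g' D g);
Rician noise (magnitude of a complex Gaussian) is added separately, the
standard model for magnitude MR images. The phantom does not emulate:
susceptibility effects, non-mono-exponential decay (relevant at b = 4500,
acknowledged and out of scope), spatially-varying SNR from coil placement
beyond the smooth S0 field, or anatomically realistic folding. Passing tests
therefore establish algorithmic correctness under the tensor + Rician model,
not performance on real specimens.

## Distortion and correction

Two artifact mechanisms are simulated (`distort_series()`): B0 drift from
gradient heating, a translation along the slow phase-encode (partition)
axis, linear in repeat index; and eddy-current distortions, an affine map
per diffusion direction with per-axis scale 1 + alpha |g_i| and shears
coupling the fast phase-encode axis to the other axes, beta g_fast g_other.
The eddy map depends only on g, so repeated directions distort identically
and b = 0 volumes receive drift only. Defaults alpha = 0.02, beta = 0.01,
drift 0.3 voxels per repeat; all are configuration-exposed since the source
acquisition does not quantify them.

`correct_series()` mirrors the pre-processing pipeline: (1) per-repeat drift
registration, constrained to a single shift along the slow phase-encode
axis, estimated from each repeat's mean b = 0 image by bracketed 1-D search
with parabolic refinement of a mutual-information cost; (2) averaging of
repeats per direction; (3) per-direction 12-degree-of-freedom registration
of each averaged DW volume to the mean b = 0 image, by coordinate descent
over translation, rotation, scale and shear with coarse-to-fine (x2, x1)
downsampling. Numerical choices worth recording:

* **MI implementation**: 64-bin joint histogram with bilinear partial-volume
  weighting over voxels where either image is nonzero; entropies in nats.
* **Pre-smoothing (sigma 0.8 voxels)** of both images inside the cost. On
  piecewise-constant synthetic images, the single interpolation of each
  candidate resample reduces MI more than a small misalignment does, biasing
  the optimum toward identity; smoothing both images makes the resample
  cost-neutral and the surface unimodal. This is a property of sharp digital
  phantoms more than of real, noisy images.
* **One resample per raw volume**: the estimated drift translation and eddy
  affine are composed and applied to the raw volumes in a single tricubic
  (Catmull-Rom) interpolation, then averaged. Sequential trilinear
  resampling left corrected maps visibly interpolation-bound.
* MI rather than least squares is not cosmetic: on the DW-versus-b0 contrast
  (attenuated white matter), the SSD cost misestimates scale several-fold,
  which the test suite demonstrates by running both costs on one fixture.

The corrected-versus-uncorrected comparison is scored as median |FA error|
against phantom truth over white matter. At the strong end of the simulated
distortion range (drift 1 voxel/repeat, alpha 0.04) correction reduces the
median error to about a third. At milder settings (drift 0.5, alpha 0.02)
the noiseless median is bounded below by interpolation itself -- even
correcting with the *true* transforms gives a higher median than leaving the
data alone, because sub-voxel misalignment of centrally-placed structures
damages only the upper quartile of the error distribution, where correction
wins by about threefold. The suite therefore asserts the median contrast at
the strong setting and the upper-quartile contrast at the mild one.

## Tensor fitting and scalar maps

`fit_tensor()` uses two-pass weighted log-linear least squares: an OLS fit
of log S against the 7-column design (intercept plus the six quadratic
gradient terms), then a weighted pass with weights equal to the squared
predicted signals, the standard correction for the log-transform's
heteroscedasticity. It is exact on noiseless data (the acceptance suite
checks recovery to machine precision), deterministic, and cheap at the low
SNR of individual post-mortem DW volumes. Non-positive intensities are
clamped to 1e-6 of the series maximum and flagged; flagged voxels are
excluded from ROI statistics. Negative eigenvalues are clamped to zero for
FA/MD with a flag rather than refit under a positivity constraint. Gradient
directions are interpreted in the voxel frame and are not reoriented when
volumes are resampled -- the simulated distortions are small scale/shear
perturbations for which reorientation effects are second-order; this is a
documented limitation, not an oversight.

## Cohort regression

`build_cohort()` draws (PMI, SI) -- post-mortem interval in hours, scan
interval in months -- from truncated Gaussians (46.2 +/- 19.9 h on [21, 69];
25.2 +/- 14.5 months on [2, 40]) coupled by a Gaussian copula with latent
correlation 0.32. A single correlation is the only coupling information
available, which a copula encodes without inventing marginal structure.

Diffusivity declines linearly with PMI: lambda(PMI) = lambda_ref - m (PMI -
46.2), with slope magnitudes m(MD) = 0.0122 and m(D_ax) = 0.0149 (10^-3
mm^2/s per hour) applied, negatively signed, to the five white matter ROIs;
the D_rad slope is derived as (3 m_MD - m_Dax)/2 = 0.01085 so the MD slope
holds exactly (the printed 0.0111 is this value within table rounding).
These per-hour magnitudes are an order of magnitude larger than fixed-tissue
diffusivities integrated over the PMI range, so they cannot coexist with the
fixed-tissue baselines: the cohort's reference diffusivities are therefore
the fixed-tissue values scaled by 10 (configuration `reference_scale`),
which is also the in-vivo-to-post-mortem MD ratio -- the *relative* decline
per hour then corresponds to the reported effect sizes on in-vivo-scale
diffusivities, FA at reference is unchanged, and every specimen's tensors
remain positive over the full PMI range. An FA-PMI slope for the SLF analog is exposed but disabled by
default: the printed magnitude (0.019 per hour) would drive FA out of [0, 1]
within the PMI range.

`analyze_cohort()` reproduces the reporting structure: per column (five WM
ROIs plus an Average column, each specimen's mean over the five) and per
index, single regressions on PMI and on SI (the slopes one would plot) and a
multiple regression on PMI + SI for inference (residual df = 11 - 3 = 8).
P-values are corrected across the family of 4 indices x 6 columns per
predictor -- Bonferroni by default, any `p.adjust` method accepted, since
the correction procedure is not otherwise specified -- and slopes with
corrected p > 0.25 are suppressed from the reported column.

The statistical suite (slope recovery, type-I error over 500 zero-slope
cohorts, copula calibration over 200 cohorts) runs on analytically-derived
per-ROI means plus Gaussian ROI-level noise (sd 0.02 x 10^-3 mm^2/s),
not on 500 x 11 full image simulations; the imaging chain itself
(simulate, fit, ROI means) is validated separately at full scale. The
noiseless ROI mean equals what the imaging chain recovers to machine
precision, so nothing is lost by the shortcut except imaging noise, which
the ROI-level noise term stands in for.

## Partial-volume simulation

`resolution_sim()` blurs every raw volume with the Gaussian kernel whose
FWHM is the quadrature difference sqrt(target^2 - native^2) -- the kernel
convention is not otherwise fixed, and quadrature addition is the reading
under which "effective resolution" composes -- then refits the tensor on the
native grid, and compares with blurring the FA map or the six tensor-element
maps. Convolution is zero-padded (the background carries no signal) and all
outputs are masked to the native foreground. On a gray-white boundary
fixture with perpendicular cortical anisotropy the expected ordering holds:
blurring FA is a much worse predictor of the refit FA than blurring tensor
elements, while MD, nearly linear in the signal at these attenuations,
agrees with its blurred map to better than 5% away from the field-of-view
edge. Apparent tract thickness is measured as the mean suprathreshold extent
of the linearly-interpolated FA profile (0.1-voxel sampling; threshold half
the slab's interior FA) so that sub-voxel thinning is visible; an 8-voxel
slab thins monotonically through 2 mm and 3.5 mm effective resolutions.

## Tractography

`track()` implements deterministic tensor-line streamlining: bidirectional
Euler integration along the trilinearly-interpolated principal diffusion
direction with per-corner sign alignment (the eigenvector sign minimising
bending), stopping on FA below 0.10, bending above 45 degrees per step,
leaving the field of view, or exceeding maximum length; the step is half a
voxel. The upstream Bayesian multi-fibre machinery is a cited external
method and is out of scope -- what this module reproduces is the *global*
gating strategy: seed a large region encapsulating the tract, retain exactly
the streamlines that pass through both inclusion masks, with no exclusion
masks. Retention is verified against a brute-force per-streamline oracle,
and a quarter-circle phantom bounds the integration error below one voxel.
An optional per-step angular jitter emulates probabilistic spread but is off
by default.

## Protocol arithmetic

`volume_time()` computes ceil(PE lines / lines per segment) x partitions x
TR. The printed per-volume times of both protocols (6:22 at 0.94 mm; 17 min
at 0.73 mm) are consistent only with full PE-line coverage, despite the
stated partial-Fourier factor, so timing ignores partial Fourier by default
and exposes it behind a flag. The 0.73 mm diffusion session,
(64 + 5) x 5 x 17.152 min = 98.6 h, lands just under the quoted 100 h.
`snr_efficiency()` models the TR tradeoff as fully-spoiled steady-state
signal per unit square root of scan time; it is labelled exploratory because
with T1 = 340 ms it places the optimal TR near 430 ms, below the quoted
500--700 ms range -- the model behind that range is unknown, and
`optimal_tr()` warns accordingly rather than silently agreeing.

## Problem sizes and reproducibility

The test and acceptance suites use 48^3 phantoms (54 + 6 directions for
tensor recovery; 12 + 2 for registration experiments; 3 repeats), 32^3
phantoms for unit-level registration and tractography, 500 replicate
cohorts for type-I error and 200 for copula calibration. These sizes were
chosen so the full suite completes on a single CPU in well under half an
hour while keeping every Monte-Carlo tolerance derived from its oracle run.
All randomness flows through explicit seeds; pipeline stages derive their
seeds from a master seed and the stage name, so any stage can be reproduced
in isolation.
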