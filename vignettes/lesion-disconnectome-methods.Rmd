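---
title: "Methods: lesion disconnectomes, normative atrophy, and their voxel-wise association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion disconnectomes, normative atrophy, and their voxel-wise association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

White-matter (WM) lesions and gray-matter (GM) atrophy are the two
best-established MRI markers of multiple sclerosis, yet they are usually
interpreted as distinct facets of the disease. A mechanistic link is
plausible: a demyelinating lesion transects axons, and axonal transection
leads to degeneration of the connected gray matter. `lesionDisco`
implements the computational machinery needed to test that link at the
whole-brain voxel level:

1. a **disconnectome map** per patient — a GM image of how strongly each
   voxel is potentially disconnected by that patient's WM lesions, given a
   normative tractogram;
2. a **normative atrophy map** per patient — how much GM the patient is
   missing relative to a healthy-control expectation given age, sex and
   head size;
3. **voxel-wise association** between the two across patients,
   cross-sectionally and longitudinally, with false-discovery-rate control.

Everything runs on a common reference grid (all volumes must share shape
and affine exactly; the package never resamples).

# The disconnectome model

For a binary lesion mask $L$ and a tractogram of fibers $f_1, \dots, f_F$
(polylines in world mm):

1. **Voxelization.** Each fiber's polyline vertices are mapped to
   continuous voxel coordinates and rounded under the voxel-centre
   convention (a coordinate belongs to index $i$ iff it lies in
   $[i-0.5, i+0.5)$ per axis); consecutive vertex voxels are joined by the
   classic driving-axis 3D Bresenham line (26-connected). The fiber's
   voxel set is the deduplicated concatenation: a fiber looping through a
   voxel twice counts it once.
2. **Scoring.** The fiber's score is $s_f = |P_f \cap L|$, the number of
   lesion voxels on its path — a plain count, with no length or volume
   normalization.
3. **Endpoint projection.** Each fiber adds $s_f$ at the voxels of its
   first and last polyline points (its anatomical endpoints); fibers with
   $s_f = 0$ contribute nothing.
4. **Smoothing and masking.** The endpoint image is smoothed with a
   Gaussian kernel (default FWHM 8 mm, the structural-neuroimaging
   convention) and then masked to gray matter. The order is fixed:
   smooth, then mask. Endpoints outside the GM mask still contribute to
   the raw image and are only removed by the final mask.

## Linearity and the per-voxel index

Every step above is linear in the lesion indicator: scores are sums over
lesion voxels, endpoint projection is linear in scores, and smoothing and
masking are linear maps. Hence the disconnectome of any lesion mask is the
sum of the disconnectomes of its individual voxels. `buildVoxelIndex()`
precomputes, for every voxel any fiber traverses, the raw endpoint-count
image a one-voxel lesion there would generate, stored as a sparse
endpoint-by-lesion-voxel count matrix. `fastDisconnectome()` sums the
relevant columns and smooths/masks once. The identity
`fastDisconnectome == disconnectomeMap` is exact in exact arithmetic and
is enforced by tests; storing raw rather than pre-smoothed contributions
is an equivalent but far smaller representation.

## Numerical choices

* **FWHM, not sigma.** The smoothing parameter is a full width at half
  maximum; $\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})$ per axis in voxel
  units, so anisotropic voxels get per-axis sigmas. The 8-mm default is
  read as FWHM, the dominant convention; it is a plain argument wherever
  smoothing occurs.
* **Kernel truncation at $4\sigma$, zero-padding boundary, no boundary
  renormalization.** Mass leaving the field of view is lost; an impulse
  at least $4\sigma$ from every face conserves its sum to within the
  kernel-truncation error (about $10^{-6}$ relative at these sizes).
* **Bresenham, not supercover.** The classic driving-axis integer line is
  what the name denotes; corner-touching voxels may be skipped. One
  consequence worth knowing: rasterization is *not* invariant under
  inserting collinear midpoints into a polyline — the rounded midpoint
  need not lie on the original Bresenham line, and the two paths may
  weave differently while both staying within one voxel (max-norm) of the
  continuous segment. Axis-aligned segments are invariant. Tests assert
  exactly this.
* **0-based voxel indices** in all public geometry (matching the NIfTI
  affine convention); world coordinates are mm.
* **Out-of-grid handling.** Fiber portions outside the grid are silently
  clipped (with a per-tractogram warning); an endpoint outside the field
  of view is an `NA` marker and simply does not accumulate.

# Normative atrophy maps

A voxel-wise ordinary-least-squares model is fitted on healthy controls:
GM value regressed on an intercept and mean-centred age, sex
(female = 1), and total intracranial volume. Centring affects only
conditioning, never predictions; the centring means are stored with the
model. Rank-deficient designs (e.g. a single-sex control cohort) abort
with the collinear column named. Voxels with constant GM across controls
get zero slopes and that constant as intercept — no NaNs propagate.

A patient's atrophy map is `predicted - observed`: positive where GM is
below the normative expectation. Negative values are retained (clipping
would bias the correlations). A percent-of-predicted mode is available;
the default is the absolute difference, since the generative simulations
operate in GM-probability units. For longitudinal data each timepoint's
atrophy uses the subject's age at that scan; the model itself is
cross-sectional.

# Statistical analysis

`voxelwiseCorrelation()` computes, at every voxel of an analysis mask,
the sample Pearson correlation across patients between disconnection and
atrophy, with two-sided p values from the t transform on $n-2$ degrees of
freedom (two-sided is the conservative choice). Voxels with zero variance
in either variable — including variance that is zero only up to rounding,
as happens when a covariate explains a voxel exactly — are flagged and
reported as $r = 0$, $p = 1$.

"Extended by a control variable" is implemented as partial correlation:
both variables are residualized on an intercept plus the covariate
(per-subject WM lesion volume, or new-lesion volume longitudinally) and
the residuals are correlated, with $n-3$ degrees of freedom. A constant
covariate falls back to the plain correlation with a warning.

Benjamini–Hochberg adjustment is applied over the in-mask voxels of one
analysis at a time (cross-sectional and longitudinal are separate
families), via `stats::p.adjust`; significance means $q <$ the FDR level
(default 5%). Per-region summaries take, within each atlas label, the
significant voxel with the largest $|r|$ (reported with its sign, peak
location and significant-voxel count); regions without significant voxels
are marked not significant.

The default analysis mask keeps GM voxels where at least 90% of subjects
have nonzero disconnection (threshold configurable). Longitudinal
families are much sparser — many patients form few or no new lesions — so
`runLongitudinal()` defaults to 50%; if a rule empties the mask entirely
the full GM mask is used and the degenerate voxels are flagged instead.

# The synthetic cohort generator

No deposited data exist for this design, so the generator is a
first-class module producing a phantom "study" with known ground truth.

* **Phantom.** A 48³ grid at 2 mm isotropic (a scale at which the full
  pipeline runs in seconds to minutes on one CPU) holding an ellipsoidal
  brain, K = 8 disjoint spherical GM regions (the atlas labels), WM as
  the remaining brain interior, and a smooth GM probability template
  peaking in the regions.
* **Tractogram.** Quadratic-Bezier polylines between random voxels of
  region pairs (default: all pairs, 36 fibers each, ~1000 fibers), with
  4-mm midpoint jitter; endpoints always lie inside their regions.
* **Lesions.** A Poisson number of spheres with lognormal radii
  (median 3 mm), centres uniform over WM, clipped to WM. Lesion *burden*
  is overdispersed the way clinical relapsing-remitting cohorts are
  (lesion-volume sd exceeding its mean): each patient draws a lognormal
  burden multiplier (log-sd 1.1, giving a load cv of about 1.6) that
  scales both the baseline rate (mean 8 lesions) and the new-lesion rate
  at follow-up (mean 4.5, preserving the roughly 0.55 new-to-baseline
  load ratio of such cohorts), so loads are heavy-tailed and correlated
  within patient.
* **Controls and patients.** Controls follow the normative model exactly:
  template plus linear age/sex/TIV effects (−0.003 per year, −0.01 for
  female, 10⁻⁴ per mL) plus Gaussian noise (total sd 0.015 in GM units).
  Patients additionally lose `alpha × D / M` of GM, where `D` is their
  true disconnectome computed by the package's own pipeline and `M` the
  cohort maximum, so `alpha` is the loss at the most disconnected voxel.
* **Effect-size calibration.** By default `alpha` is not fixed but
  calibrated: it is chosen so that the median (over core affected voxels)
  between-subject sd of the injected loss equals half the noise sd — a
  design signal-to-noise ratio of 0.5, which makes the attainable
  voxel-wise correlation at the median core voxel about
  $0.5/\sqrt{1.25} \approx 0.45$. Passing `alpha = 0` produces a null
  cohort.
* **Noise structure.** Per-scan noise decomposes into a persistent
  per-subject anatomical deviation and scan-specific noise (sd 0.006 of
  the 0.015 total). Cross-sectionally only the total matters;
  longitudinally the anatomical part cancels in difference maps, as it
  does in real repeated-measures morphometry, which is what makes
  atrophy-increase maps informative at realistic scan noise.
* **Ground truth.** The dataset records the injected mean loss map, an
  `affectedSupport` mask (any injected loss) used to score the precision
  of significant voxels, and an `affectedCore` mask (mean loss ≥ 10% of
  its maximum) used to score recovery strength — correlations at voxels
  carrying only a sliver of smoothed signal are attenuated by design and
  would say nothing about recovery.
* **Determinism.** All randomness flows from one master seed through
  fixed per-component substreams; identical seeds give bit-identical
  datasets.

What the generator does **not** emulate: MRI contrast and acquisition
artifacts, registration error, lesion-segmentation error, anatomically
realistic fiber geometry, within-GM direct lesion pathology, and
atrophy from causes other than disconnection. Passing recovery tests on
the phantom therefore validates the computational pipeline and its
statistical behaviour, not the biological claim on real data.

# Problem sizes used by the test suite

The heavier tests and the acceptance script use the default phantom
(48³ voxels, ~1000 fibers) with 60 controls and 120 patients — sizes
chosen so the whole suite completes in a few minutes on one CPU while
keeping per-voxel counts high enough for the statistical checks (e.g.
binomial standard errors on FDR fractions). Unit tests run on 16³–36³
grids.

# Known limitations

* TRK tractograms are not read; convert to TCK or the documented
  plain-text format. TCK reading assumes Float32LE data.
* No resampling: inputs on mismatching grids are rejected rather than
  interpolated.
* The normative model is linear; nonlinear age effects, site effects and
  scanner harmonization are out of scope.
* Surface-based (vertex-wise) analysis is out of scope; all statistics
  are voxel-wise.
* Region summaries merge hemispheres only if the supplied label volume
  does.
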