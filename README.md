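# lesionDisco

Gray-matter (GM) atrophy and white-matter (WM) lesions are the two
workhorse MRI markers of multiple sclerosis, and they are usually read as
separate things — ongoing neurodegeneration versus focal demyelination.
But a lesion transects axons, and transected axons let the connected gray
matter wither. `lesionDisco` is an R package for testing that mechanism
voxel by voxel across the brain. It is aimed at neuroimaging researchers
who have, in one common reference space: binary WM lesion masks, GM
density/probability images, a whole-brain tractogram, and a covariate
table — or who want to exercise the full method on a synthetic phantom
cohort with known ground truth, which the package generates itself.

## The method

**Disconnectome maps.** For each fiber *f* of a tractogram, the voxels it
passes through are found with the classic driving-axis 3D Bresenham line
(26-connected), and the fiber is scored by its lesion overlap,

> s_f = | path(f) ∩ L |,

the number of lesion voxels on its path. Each fiber projects its score to
its two endpoints; the summed endpoint image is smoothed with an 8-mm
FWHM Gaussian and masked to gray matter. Because every step is linear in
the lesion indicator, the disconnectome of any lesion mask equals the sum
of single-voxel-lesion disconnectomes — `buildVoxelIndex()` precomputes
these sparsely, and `fastDisconnectome()` then maps any lesion mask to
its disconnectome in milliseconds, exactly.

**Normative atrophy maps.** A voxel-wise OLS model fitted on healthy
controls predicts GM from age, sex and total intracranial volume; a
patient's atrophy map is `predicted − observed` (positive = tissue loss).

**Association.** Disconnectome and atrophy maps are correlated across
patients at every voxel (Pearson; optionally partial, controlling for
total WM lesion volume), with Benjamini–Hochberg FDR control at 5% and
per-region maximum-r summaries. Longitudinally, new-lesion masks
(timepoint 2 minus 1) yield disconnection-increase maps, correlated with
atrophy-increase maps, optionally controlling for new-lesion volume.

See `vignettes/lesion-disconnectome-methods.Rmd` for the full model,
parameter and design discussion.

## Worked example

```r
library(lesionDisco)

phantom <- makePhantom(seed = 1)              # 48^3 at 2 mm, 8 GM regions
tract   <- makeTractogram(phantom, seed = 1)  # ~1000 synthetic fibers
lesion  <- simulateLesions(phantom@wmMask, seed = 1)

dmap <- disconnectomeMap(lesion, tract, phantom@gmMask, fwhm = 8)
idx  <- buildVoxelIndex(tract)
fast <- fastDisconnectome(lesion, idx, phantom@gmMask, fwhm = 8)
max(abs(fast@data - dmap@data))

cohort <- simulateCohort(phantom, tract, seed = 1)   # 60 controls, 120 patients
bundle <- runCrossSectional(cohort)
head(bundle$regionTable, 3)
```

This prints:

```
BrainPhantom on 48x48x48 grid: 8 GM regions (2136 GM, 33264 WM, 35400 brain voxels)
Tractogram: 1008 streamlines (12096 points) on 48x48x48 grid
BinaryMask on 48x48x48 grid; 174 voxels set
DisconnectomeMap on 48x48x48 grid; FWHM 8 mm, 1008 fibers, 174 lesion voxels; max 0.2457
[1] 0
cohortDataset: 60 controls, 120 patients on 48x48x48 grid (alpha = 0.119123, noise sd = 0.015, seed = 1)
analysisBundle (cross_sectional): n = 120 patients, 2136 mask voxels, 2094 significant
  label     name     max_r peak_i peak_j peak_k n_sig_voxels
1     1 region_1 0.7009980     19     33     23          264
2     2 region_2 0.6752364     27     18      8          261
3     3 region_3 0.7549630     18     29     13          264
```

Reading the numbers: the simulated lesion mask covers 174 WM voxels; its
disconnectome peaks at 0.246 (smoothed endpoint counts, GM-masked). The
index-based fast path reproduces the direct computation to the last bit
(`max |fast − direct| = 0`). In the simulated cohort the injected effect
size is calibrated to the noise (`alpha ≈ 0.119` GM units at the most
disconnected voxel), and the cross-sectional analysis finds 2094 of 2136
GM voxels significantly coupled to atrophy, with per-region peak
correlations around 0.67–0.75 at the listed voxel locations.

Real data enter through `readMask()` / `readVolume()` (NIfTI),
`readTck()` or `readTractogramText()` (tractograms), and
`readCovariates()` (CSV schema documented on its help page);
`runCrossSectional()` / `runLongitudinal()` accept any dataset laid out
by `writeCohortDataset()`.

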