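Package: lesionDisco
Title: Lesion Disconnectome Maps and Normative Gray-Matter Atrophy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes individual white-matter lesion disconnectome maps from a
    binary lesion mask and a whole-brain tractogram: each streamline is scored
    by the number of lesion voxels it passes through (3D Bresenham
    voxelization), scores are projected to the two fiber endpoints, the
    resulting endpoint image is Gaussian-smoothed and masked to gray matter.
    A sparse per-lesion-voxel index exploits the linearity of the pipeline to
    recompute disconnectomes in milliseconds. The package also fits voxel-wise
    normative models of gray-matter density on healthy controls (age, sex,
    total intracranial volume), converts patient images to atrophy maps
    (predicted minus observed), and relates disconnection to atrophy with
    voxel-wise Pearson and partial correlation under Benjamini-Hochberg false
    discovery rate control, cross-sectionally and longitudinally. A seeded
    synthetic brain phantom, tractogram, lesion and cohort generator provides
    ground-truth data for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
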