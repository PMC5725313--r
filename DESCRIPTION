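Package: icnengage
Title: Quantifying Intrinsic Connectivity Network Engagement of fMRI
    Statistical Maps
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Describes fMRI statistical maps in the framework of intrinsic
    connectivity networks (ICNs). Builds winner-take-all label atlases from
    sets of ICN prototype Z-score volumes, labels input statistical maps
    against them, and computes a family of eleven ICN-specific and four
    global engagement metrics covering spatial overlap (involvement,
    Sorensen-Dice, Jaccard), activation strength and density, and spatial
    correlation. Includes test-retest reliability analysis via two-way
    consistency intra-class correlation at three pooling levels, a
    voxel-wise mode-of-ICC summary, top-k cross-atlas agreement, a
    two-stage principal-axis factor analysis with varimax rotation for
    metric-set reduction, and a fully deterministic synthetic-fixture
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
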