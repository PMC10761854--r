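Package: rovnet
Title: Individual-Variability Mapping and Connectome-Based Prediction for Task fMRI Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Maps inter-subject variability in task fMRI cohorts and links it to
    behavior. Computes voxelwise between- to within-subject variance ratio (F)
    maps from contrast and residual mean-square images, across-subject standard
    deviation maps of grey-matter volume, and group one-sample t masks;
    thresholds variance maps at the change point of their sorted values and
    extracts spherical regions of variance (ROVs) around cluster peaks; builds
    per-subject functional connectivity networks from multi-voxel ROV series
    (task beta-series or resting BOLD) with the unbiased (U-centered)
    distance-correlation estimator; and predicts individual behavioral scores
    with connectome-based predictive modeling (leave-one-out cross-validation,
    positive/negative edge models, permutation inference). A seeded synthetic
    cohort generator with known ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
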