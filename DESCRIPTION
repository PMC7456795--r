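Package: seegaccuracy
Title: Automated Accuracy Metrics for Stereoelectroencephalography
    Electrode Implantation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Automated quantification of stereoelectroencephalography (SEEG)
    electrode implantation accuracy. Estimates implanted trajectories from
    segmented bolts and contacts (bolt axis and line-of-best-fit variants),
    intersects trajectories with head-surface meshes to define entry points,
    computes lateral-shift, Euclidean, depth and angle deviations against
    planned trajectories, pairs planned with implanted electrodes
    automatically, and provides the method-agreement statistics used to
    validate such pipelines (Box-Cox, D'Agostino-Pearson, Bland-Altman,
    Wilcoxon signed-rank, Mann-Whitney U, correlation and regression).
    Includes a synthetic implantation phantom generator with ground truth,
    scalp/skull meshes and rasterized CT volumes for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    RNifti,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
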