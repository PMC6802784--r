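Package: stprf
Title: Spatiotemporal Population Receptive Field Modeling for Visual fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modeling and estimation of spatiotemporal population
    receptive fields (pRF) from BOLD fMRI time-series, aimed at subcortical
    visual structures such as the lateral geniculate nucleus. The model
    combines a two-dimensional Gaussian spatial receptive field with
    rectified sustained and transient temporal channels mixed by a weight
    parameter, convolved with a delayed double-gamma hemodynamic response.
    Includes bar-sweep and full-field flicker stimulus construction,
    two-phase voxelwise fitting (adaptive coarse grid search followed by
    downhill-simplex refinement) with yoked session-wide hemodynamic delay
    and temporal dispersion, framewise-displacement volume censoring and run
    averaging, model-free agglomerative clustering of voxel time-series with
    label regression, circular statistics of the sustained-to-transient
    weight gradient, bootstrap reliability curves over scanning runs, and a
    synthetic phantom generator so the whole pipeline is testable without
    scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite,
    nnet,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'geometry.R'
    'stimulus.R'
    'kernels.R'
    'model.R'
    'fitting.R'
    'preprocess.R'
    'segmentation.R'
    'gradient.R'
    'reliability.R'
    'synthetic.R'
    'io.R'
    'cli.R'
    'utils.R'
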