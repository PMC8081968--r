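Package: neuroqc
Title: Automated Quality Control for Filesystem-Backed Neuroimaging Projects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained quality-control toolkit for neuroimaging
    projects stored on a local filesystem. Provides a validator framework
    running ordered, self-tested checkpoints over MR and PET imaging
    sessions (DICOM-derived metadata sanity checks, NIfTI conversion
    checks, pipeline-output checks on manifests, software versions,
    execution times, segmentation label completeness and volume safety
    intervals), JSON/Markdown validation reports with provenance,
    segmentation snapshot rendering (static PNG grids and animated GIF
    overlays), project-wide aggregation of test outcomes and FreeSurfer
    aseg.stats volumes into spreadsheets, an assisted visual review score
    store with checkpoint-aware navigation, and a synthetic-data generator
    producing complete projects with controllable defects for
    continuous-integration self-checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    png,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    utils,
    stats,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
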