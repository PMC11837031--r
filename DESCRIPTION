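Package: idpscreen
Title: Dementia-Informed Imaging-Derived Phenotypes, Staged Quality
    Control and Hierarchical FDR Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Extracts dementia-informed imaging-derived phenotypes (IDPs)
    from grid-aligned brain maps (lobar grey-matter volumes with lesion
    masking, tract-wise white-matter-hyperintensity volumes, nucleus
    basalis of Meynert volumes, peak width of skeletonised mean
    diffusivity, tractography tract volumes, partial-volume-weighted
    regional diffusion metrics), applies staged automated quality control
    (interquartile-range outlier flagging of image-quality metrics and
    DSE variance decomposition of 4D time series), and screens IDPs
    against age, cognition and ordered diagnosis with mass-univariate
    linear and proportional-odds models under a two-stage hierarchical
    false-discovery-rate procedure (per-modality Simes omnibus tests,
    then Benjamini-Hochberg within selected modalities at an adjusted
    level). Includes a synthetic phantom and cohort generator with exact
    countable ground truth so every stage is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
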