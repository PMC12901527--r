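Package: vatslice
Title: Craniocaudal Visceral Adipose Tissue Profiles and Single-Slice
    Volume Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the craniocaudal distribution of visceral
    adipose tissue (VAT) in axial Dixon MRI of the trunk and for estimating
    total VAT volume from a single axial slice. Per-slice VAT areas from
    binary segmentation masks are standardized to an anatomical grid built
    from spine landmarks (vertebral bodies L5 to Th10, intervertebral discs,
    and 26 equidistant points between the femoral heads and L5), stratum
    mean profiles are computed per sex, BMI group and age group,
    age-independent reference locations are found as the intersection of
    age-group profiles, and sex- and BMI-specific scaling factors convert a
    single-slice VAT area (cm2) into an estimated total volume (liters).
    A synthetic-cohort generator with calibrated covariates, spine
    geometries, planted profile structure and voxelized phantom masks makes
    the whole pipeline testable without access-restricted cohort data.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    grDevices,
    jsonlite,
    RNifti,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
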