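Package: airwayct
Title: Quantifying Murine Airway Remodeling from Micro-CT by Peribronchial Attenuation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automatic quantification of bronchial remodeling in murine
    micro-computed tomography. Segments the bronchial lumen and the aerated
    lung by seeded bi-threshold volume growing, builds a peribronchial shell
    by 3D morphological dilatation and subtraction, and computes the
    peribronchial mean attenuation (PBA), total lung attenuation (TLA) and
    the normalized statistic 1 - (PBA/TLA). Includes Hounsfield-unit
    calibration from in-field air/water standards, NIfTI/MetaImage/DICOM
    volume input, method-agreement statistics (Bland-Altman, Pearson,
    intraclass correlation, Spearman, Mann-Whitney), and a synthetic
    thorax-phantom generator with ground-truth masks for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
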