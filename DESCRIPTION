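Package: ihcscore
Title: Automated Tumor-Cell PD-L1 Scoring and Assay Concordance for
    Brightfield Immunohistochemistry Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated scoring of PD-L1 membrane positivity on
    brightfield H-DAB immunohistochemistry images and for concordance
    analysis across diagnostic assays. Provides colour deconvolution into
    hematoxylin and DAB optical-density channels, nucleus segmentation with
    membrane-ring feature extraction, tumor versus immune cell
    classification, per-sample tumor proportion scoring, rigid serial-section
    co-registration with annotation transfer, agreement statistics (overall
    percentage agreement and F1) over exhaustive cutoff-pair grids, and an
    exhaustive threshold-optimization workflow that re-fits cell positivity
    criteria against a reference assay. A synthetic slide generator with
    planted ground truth makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    grDevices,
    jsonlite,
    mgcv,
    png,
    rlang,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
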