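Package: lymphspec
Title: Hyperspectral Imaging Pipeline for Objective Staging of Secondary Lymphedema
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for near-infrared hyperspectral reflectance
    imaging of the upper extremity in secondary lymphedema. Provides an ENVI
    hypercube data model, spectral tissue indices built from absorption-band
    statistics (lipid-to-water ratio, tissue water index, tissue lipid index,
    tissue oxygenation), body-versus-background segmentation by fused-index
    Otsu thresholding, central region-of-interest spectrum extraction with L1
    normalization, affected-minus-unaffected interlimb delta metrics,
    clustering-based spectral disease staging, the accompanying nonparametric
    statistics (Mann-Whitney U, Spearman correlation, normality omnibus,
    Fisher-z power), and a synthetic-cohort generator emulating the acquisition
    so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
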