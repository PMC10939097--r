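Package: fiberMSI
Title: Spatial Metabolomics of Skeletal Muscle Fiber Types by MALDI Mass
    Spectrometry Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for MALDI mass spectrometry
    imaging (MSI) of skeletal muscle sections: imzML import/export,
    spectrum-level preprocessing (morphological baseline removal, RMS
    normalization, MAD-based peak picking, ppm peak alignment), NaN-aware
    median denoising of ion images, spatially resolved K-means segmentation
    with centroid dendrograms and operator-guided class merging, landmark
    co-registration of immunofluorescence fiber-type masks, per-feature
    discrimination (ROC AUC) and reproducibility (two-way mixed ICC)
    screening, PCA and PLS-DA with VIP-based biomarker selection,
    ppm-tolerance metabolite annotation, quantitative metabolite set
    enrichment via a globaltest-style Q statistic with permutation null,
    and cross-validation against LC-MS feature tables. A synthetic phantom
    generator plants fiber-type regions, fingerprint metabolites and
    replicate variance components so every stage is verifiable against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    xml2,
    jsonlite,
    yaml,
    png,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    mixOmics,
    cluster
Config/testthat/edition: 3
RoxygenNote: 7.3.3
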