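Package: aquarocket
Title: Aquaphotomics and Chemometrics Pipeline for NIR Shelf-Life Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for monitoring the freshness of ready-to-eat
    leafy vegetables stored under modified atmospheres. Provides spectral
    dataset handling for portable NIR instruments (reflectance to absorbance,
    packaging-reference subtraction, truncation, replicate averaging), the
    standard chemometric pretreatments (moving-average smoothing,
    Savitzky-Golay derivatives, Norris gap derivative, SNV, MSC) and the
    aquaphotomics column standardisation, PCA and PLS regression of the
    electrolyte-leakage index of leaf damage on spectra, water absorbance
    band (WAB) selection inside the twelve water matrix coordinates
    (C1-C12) and aquagram (radar chart) construction, one-way ANOVA with
    LSD and Tukey HSD post-hoc tests for leakage and electronic-nose
    sensor tables, and a synthetic-data generator that emulates the
    storage-dependent bound-to-free water redistribution the analysis is
    designed to detect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    withr,
    jsonlite,
    yaml,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
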