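Package: sproutspec
Title: NIR Aquaphotomics Chemometrics for Sprouting Legume Extracts
Version: 0.1.0
Authors@R:
    person("Sproutspec", "Maintainers", email = "maintainers@sproutspec.dev",
           role = c("aut", "cre"))
Description: Chemometric analysis of near-infrared (NIR) absorbance spectra of
    germinating mung bean extracts and ascorbic acid standard solutions.
    Provides a spectral data container with CSV input/output, Savitzky-Golay
    smoothing and standard normal variate pretreatment, principal component
    analysis, PCA-score linear discriminant classification of germination time
    with replicate-fold cross-validation, partial least squares regression
    with grouped cross-validation and RMSECV-based latent-variable selection,
    aquagram computation over the first O-H overtone water matrix coordinates,
    iodometric titration and gravimetric water-content calculators, one-way
    ANOVA from summary statistics with Duncan's multiple range test, and a
    seeded synthetic spectra generator emulating the germination study design
    so that every stage of the pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
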