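Package: pzpas
Title: Photoacoustic Spectroscopy Simulation and Chemometrics for Noninvasive Glucose Sensing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modelling and chemometric analysis for mid-infrared
    photoacoustic spectroscopy with piezoelectric (PZT) ultrasound detection,
    aimed at noninvasive monitoring of blood components such as glucose.
    Provides a layered Beer-Lambert optical model of skin (stratum corneum
    over interstitial fluid), a one-dimensional quarter-wave acoustic
    standing-wave resonance model, synthesis of photoacoustic spectra in the
    optically thick regime where the signal is inversely proportional to the
    absorption coefficient, a generator of synthetic oral glucose tolerance
    test (OGTT) spectral datasets with configurable acquisition noise, the
    standard preprocessing chain (laser-power normalisation, min-max scaling,
    band selection), a from-scratch NIPALS PLS-DA classifier with
    leave-one-out Q2 latent-variable selection and stratified k-fold
    cross-validation, and Clarke error grid evaluation of predicted glucose.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tools,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    mixOmics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
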