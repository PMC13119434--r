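Package: chladapt
Title: Condition-Aware Domain-Adaptive Retrieval of Leaf Chlorophyll from Canopy Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrieves leaf chlorophyll content (micrograms per square
    centimetre) from canopy reflectance spectra measured under discrete
    shading regimes, where each shading level changes both the spectral
    distribution and the spectrum-to-chlorophyll mapping. Provides spectral
    preprocessing (band cropping, Savitzky-Golay smoothing, continuum
    removal, standard normal variate, first derivative), band-wise Fisher
    discriminant ratio and PERMANOVA separability diagnostics, two-stage
    feature selection (Pearson screen plus a Boruta shadow-feature wrapper
    around random forests), a surrogate radiative-transfer-style forward
    model with Latin-hypercube lookup-table construction for the simulated
    source domain, a synthetic shaded field-campaign generator, and a family
    of residual-network regression models with condition embeddings,
    correlation alignment (CORAL), target-conditioned CORAL, a
    heteroscedastic prediction head, and condition-level uncertainty
    weighting, together with the pretrain/adapt/evaluate protocol and the
    five-variant ablation grid.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    signal,
    lhs,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
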