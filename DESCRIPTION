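Package: flynmr
Title: 1H-NMR Metabolomics Pipeline with PQN, PLS/OPLS-DA and Permutation Validation
Version: 0.1.0
Authors@R:
    person("flynmr", "maintainers", email = "flynmr@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a 1H-NMR metabolomics workflow for
    discriminating experimental groups of whole-fly extracts (unmanipulated,
    sham-injured, and sepsis-survivor Drosophila): spectral bucketing at 0.001
    ppm with water-region exclusion, probabilistic quotient normalization,
    from-scratch PCA/PLS/OPLS latent-variable models with leave-one-out Q2Y,
    permutation and CV-ANOVA validation, correlation-loading based discriminant
    metabolite selection against a chemical-shift library, and local metabolic
    pathway mapping. A synthetic-spectrum generator with Lorentzian lineshapes,
    planted group effects, multiplicative dilution and additive noise stands in
    for raw spectra so that every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
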