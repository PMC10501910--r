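Package: catena
Title: Latent-Variable Modeling of Catecholaminergic Nuclei MRI Contrast and Memory
Version: 0.1.0
Authors@R:
    person("catena", "developers", email = "catena@example.org", role = c("aut", "cre"))
Description: A reusable pipeline linking MRI-derived integrity of the locus
    coeruleus (LC) and substantia nigra-ventral tegmental area (SN-VTA) to
    cognitive performance. Provides semiautomatic peak-intensity-ratio
    extraction from multimodal brain volumes (MT+, MT-, FSE) against
    white-matter reference regions, a self-contained structural equation
    modeling engine with full-information maximum likelihood under
    missingness, multi-group estimation, fit indices, likelihood-ratio
    tests and the measurement-invariance ladder, declarative builders for
    modality-specific, multimodal, cognitive, neurocognitive, stability,
    latent change score and prediction models, and a synthetic cohort
    generator with known latent ground truth so that the entire pipeline is
    testable without access-restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
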