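Package: enhancerNoise
Title: Stochastic Models of Shadow Enhancer Transcriptional Noise and Fidelity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds mass-action chemical reaction networks for arbitrary
    shadow-enhancer configurations (any number of enhancers, each with any
    number of transcription factor binding sites) and computes stationary
    transcriptional noise (coefficient of variation of mRNA), fidelity
    (TF-mRNA correlation) and Fano factors by second- or third-order
    zero-cumulant moment closure and by exact Gillespie simulation.
    Supports additive, subadditive, superadditive, saturating and
    synergistic enhancer interaction regimes, enhancer duplication and
    splitting transforms, configuration-grid sweeps with monotone-trend
    verdicts, and brute-force truncated master-equation oracles for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    withr,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
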