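Package: mutmech
Title: Pathogenicity Scoring and Molecular Mechanism Inference for
    Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts the pathogenicity of amino acid substitutions with a
    bagged ensemble of feed-forward neural networks trained by resilient
    propagation under a positive-unlabeled regime, and infers ranked
    molecular mechanisms (loss or gain of structural and functional
    protein properties) with calibrated posterior probabilities and
    empirical p-values.  Includes class-prior (mixture proportion)
    estimation from score distributions, label-noise-corrected AUC,
    sequence-identity-aware cross-validation, fragment-based redundancy
    filtering, false-positive-rate-calibrated enrichment statistics, and
    a fully synthetic fixture generator so that the package builds and
    tests without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
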