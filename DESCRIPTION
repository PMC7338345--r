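Package: taguchiBiocat
Title: Taguchi Orthogonal-Array Optimization and Bioprocess Calculators
    for Enzymatic Esterification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the quantitative workflow of Taguchi-optimized
    biocatalysis experiments: construction and validation of three-level
    orthogonal arrays (L9), larger-is-better signal-to-noise analysis with
    main-effects response tables and delta ranking, pooled analysis of
    variance with percent contribution, predicted-optimum estimation, and
    the upstream bioprocess calculators used in enzymatic esterification
    studies (titration-based acidity index and free-fatty-acid conversion,
    p-nitrophenyl butyrate hydrolytic activity, enzyme immobilization
    parameters, and first-order thermal-deactivation half-life). Includes
    a synthetic-data module that emulates the additive main-effects
    structure the analysis assumes, so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
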