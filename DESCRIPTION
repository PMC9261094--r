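Package: semsim
Title: Semantic Similarity of Descriptive Speech with Default Bayesian Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes distributional-semantic similarity metrics for short
    speech transcripts (average similarity of words over the full description,
    ASW-F, and over a 10-word moving window, ASW-10) from GloVe-format word
    vectors, together with cognitive summary scores (Stroop interference by the
    Golden method, digit-symbol substitution totals) and a default-prior
    Bayesian analysis battery (JZS t tests, Jeffreys correlation, g-prior
    one-way ANOVA, Gunel-Dickey contingency tables). Includes a synthetic
    cohort generator that emulates two-group, two-timepoint picture-description
    studies so every stage of the pipeline is testable without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
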