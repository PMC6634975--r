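Package: wmpop
Title: Behavioral and Neural Population Analysis for Olfactory Working-Memory Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for trial-structured rodent olfactory working-memory
    experiments: trial-outcome classification and behavioral performance metrics
    (correct rate, d-prime, lick efficiency, well-trained windows, exponential
    memory-decay fits), permutation and bootstrap resampling statistics, a
    candidate-GLM model-comparison framework with bootstrap AIC, single-unit
    odor-selectivity analyses (selectivity index, auROC, selective-fraction time
    courses), Gaussian-response-model mutual information, and population decoding
    with RBF-kernel support vector machines including cross-temporal decoding.
    Includes a synthetic-data generator producing Poisson spike trains and
    behavioral sessions with the statistical structure these analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
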