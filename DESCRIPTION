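Package: pseudovalence
Title: Form and Semantic Models of Pseudoword Valence with Best-Worst Scaling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how affective valence can be assigned to
    pseudowords (out-of-vocabulary letter strings). Provides surface-form
    featurization of strings (letter, bigram and word-boundary counts),
    composition of semantic vectors for arbitrary strings from character
    4-gram embeddings, ordinary-least-squares valence models with R-squared,
    correlation and AIC model comparison, uniform-coverage stimulus sampling
    and balanced best-worst trial designs with catch trials, an Elo-style
    value-learning scorer turning best-worst choices into continuous valence
    indexes with split-half reliability, orthographic (optimal string
    alignment) and semantic (cosine) nearest-neighbor predictors, and a
    synthetic-data generator with planted ground truth so the whole pipeline
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
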