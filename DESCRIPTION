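Package: foodlex
Title: Food-Word Lexicon Expansion and Energy-Density Prediction from
    Word Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expands a seed dictionary of food words by clustering their
    word-embedding vectors with Gaussian mixture models and harvesting new
    vocabulary inside probability-level hyperellipses around the fitted
    cluster centroids. Seed terms are built from food-composition tables and
    labelled by energy density (kcal/g) under the British Nutrition
    Foundation scheme, collapsed to a binary low/high energy-density class.
    A benchmark of ten classifiers predicts the energy-density class of
    newly discovered words from their embedding vectors, and a dictionary
    matching module counts multi-word food terms in review corpora with
    per-district percent-increase and Welch t-test summaries. A synthetic
    data generator provides embedding spaces, seed lexicons and review
    corpora with known ground truth so the full pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    stringi,
    jsonlite,
    MASS,
    nnet,
    rpart,
    class,
    e1071,
    kernlab,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
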