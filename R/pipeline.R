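# End-to-end seeded run over synthetic ground truth: embedding space ->
# seed lexicon -> mixture calibration -> expansion -> ED labelling ->
# review corpus -> district report. Deterministic given the master seed.

#' Run the full pipeline on synthetic data
#'
#' Generates an embedding space with planted food clusters, draws a seed
#' lexicon, calibrates a Gaussian mixture on the seed vectors by AIC,
#' expands the lexicon at the given (similarity, probability)
#' configuration, labels the discoveries with an ED classifier trained on
#' the seeds, plants a review corpus from the expanded lexicon, and
#' produces the district report comparing the seed and expanded lexicons.
#'
#' @param seed Master integer seed; every stage derives from it.
#' @param spec A [synthetic_spec()]; defaults to the standard study
#'   conditions with this seed.
#' @param seed_fraction Fraction of each cluster used as seeds.
#' @param K_grid Component-count grid for [calibrate()]; defaults to
#'   1 up to the planted cluster count plus 5.
#' @param cov_types Covariance families searched.
#' @param config An [expansion_config()].
#' @param classifier_model Name of the ED classifier trained on the seeds.
#' @param n_outlets,districts,mean_terms_per_outlet Corpus parameters.
#' @return List with every intermediate artifact: `spec`, `space`,
#'   `truth`, `seeds`, `held_out`, `calibration`, `model`, `expansion`,
#'   `precision`, `recall`, `ed_model`, `predicted`, `expanded_lexicon`,
#'   `corpus`, `report`.
#' @export
run_pipeline <- function(seed,
                         spec = synthetic_spec(seed = seed),
                         seed_fraction = 0.5,
                         K_grid = NULL,
                         cov_types = c("diag", "spherical"),
                         config = expansion_config(0.65, 0.75),
                         classifier_model = "SVM",
                         n_outlets = 60L,
                         districts = c("east", "west", "north"),
                         mean_terms_per_outlet = 30) {
  emb <- generate_embedding_space(spec)
  seeds <- generate_seed_lexicon(emb$truth, fraction = seed_fraction,
                                 ed_ranges = spec$ed_ranges, seed = seed + 1L)
  X <- word_vectors(emb$space, seeds$lexicon$surface)

  if (is.null(K_grid)) K_grid <- seq_len(spec$n_food_clusters + 5L)
  calib <- calibrate(X, K_grid, cov_types = cov_types, seed = seed)
  model <- calib$best

  expansion <- expand_lexicon(seeds$lexicon, emb$space, model, config)
  food_words <- emb$truth$word[!is.na(emb$truth$cluster)]
  precision <- if (nrow(expansion) > 0L)
    evaluate_precision(expansion, truth = food_words)$precision else NA_real_
  recall <- mean(seeds$held_out$word %in% expansion$word)

  ed_model <- fit_ed_model(X, seeds$lexicon$ed_class, classifier_model,
                           seed = seed)
  predicted <- predict_ed(ed_model, expansion$word, emb$space)

  expanded_lexicon <- lexicon(rbind(
    as.data.frame(seeds$lexicon),
    data.frame(surface = predicted$word, n_words = 1L,
               ed_kcal_per_g = NA_real_, bnf_class = NA_character_,
               ed_class = predicted$ed_class, source = "expanded",
               stringsAsFactors = FALSE)))

  corpus <- generate_review_corpus(expanded_lexicon, n_outlets = n_outlets,
                                   districts = districts,
                                   mean_terms_per_outlet = mean_terms_per_outlet,
                                   seed = seed + 2L)
  report <- district_report(corpus$reviews, seeds$lexicon, expanded_lexicon)

  list(spec = spec, space = emb$space, truth = emb$truth,
       seeds = seeds$lexicon, held_out = seeds$held_out,
       calibration = calib, model = model, expansion = expansion,
       precision = precision, recall = recall,
       ed_model = ed_model, predicted = predicted,
       expanded_lexicon = expanded_lexicon,
       corpus = corpus, report = report)
}
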