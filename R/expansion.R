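# Harvest new candidate food words around the fitted mixture centroids.
#
# A word is discovered when (i) its cosine similarity to at least one
# centroid reaches the similarity level s, and (ii) at least one mixture
# component accepts it at the probability level p (posterior responsibility
# or p-mass ellipsoid; see membership()). Raising either threshold can only
# shrink the discovered set, which is the trade-off between the number of
# new words and the chance that they are food words.

#' Expansion configuration
#'
#' @param similarity_level Cosine-similarity threshold s in \[0, 1\] around
#'   each centroid, bounding candidate retrieval.
#' @param probability_level Probability level p in (0, 1) governing
#'   hyperellipse membership.
#' @param mode Membership interpretation, `"posterior"` or `"quantile"`
#'   (see [membership()]).
#' @param max_candidates Per-centroid cap on retrieved candidates (highest
#'   similarity kept), bounding the membership-testing cost. `Inf` scans the
#'   whole similarity ball.
#' @param word_pattern Regular expression a candidate word must match;
#'   the default admits only lowercase letters and underscores, excluding
#'   the digit- and symbol-bearing tokens that large news-trained
#'   vocabularies carry (clean food phrases contain neither).
#' @return Object of class `expansion_config`.
#' @export
expansion_config <- function(similarity_level, probability_level,
                             mode = c("posterior", "quantile"),
                             max_candidates = 1e5,
                             word_pattern = "^[a-z_]+$") {
  mode <- match.arg(mode)
  stopifnot(is.numeric(similarity_level), length(similarity_level) == 1L,
            similarity_level >= 0, similarity_level <= 1,
            is.numeric(probability_level), length(probability_level) == 1L,
            probability_level > 0, probability_level < 1,
            max_candidates >= 1)
  structure(list(similarity_level = similarity_level,
                 probability_level = probability_level,
                 mode = mode, max_candidates = max_candidates,
                 word_pattern = word_pattern),
            class = "expansion_config")
}

#' Discover new words around the mixture centroids
#'
#' For each component centroid, retrieves the vocabulary words with cosine
#' similarity at least `s` (capped at `max_candidates` per centroid), pools
#' them, and keeps those accepted by at least one component at probability
#' level `p`. Seed surfaces are excluded case-insensitively. A word accepted
#' through several centroids is reported once, under its highest-similarity
#' centroid.
#'
#' @param lex A `food_lexicon` of seed words (non-empty).
#' @param space An `embedding_space` of the same dimension as the model.
#' @param model A fitted `food_gmm`.
#' @param config An `expansion_config`.
#' @return Object of class `expansion_result`: data frame with columns
#'   `word`, `component`, `similarity`, `membership`, plus attributes
#'   `config` and `n_candidates` (pool size before membership testing).
#' @export
expand_lexicon <- function(lex, space, model, config) {
  stopifnot(inherits(lex, "food_lexicon"), inherits(space, "embedding_space"),
            inherits(model, "food_gmm"), inherits(config, "expansion_config"))
  if (nrow(lex) == 0L) stop("seed lexicon is empty", call. = FALSE)
  if (model$d != space$d) stop("model dimension (", model$d,
                               ") does not match embedding dimension (",
                               space$d, ")", call. = FALSE)

  s <- config$similarity_level
  p <- config$probability_level

  unit <- .unit_rows(space$vectors)
  cmu <- model$means
  cmu_norm <- sqrt(rowSums(cmu^2))
  if (any(cmu_norm == 0)) stop("zero-norm centroid", call. = FALSE)
  sims <- unit %*% t(cmu / cmu_norm)            # |vocab| x K

  eligible <- grepl(config$word_pattern, space$vocab) &
    !(tolower(space$vocab) %in% tolower(lex$surface))

  cand <- logical(length(space$vocab))
  for (k in seq_len(model$K)) {
    hits <- which(eligible & !is.na(sims[, k]) & sims[, k] >= s)
    if (length(hits) > config$max_candidates) {
      hits <- hits[order(-sims[hits, k])][seq_len(config$max_candidates)]
    }
    cand[hits] <- TRUE
  }
  cand_idx <- which(cand)

  empty <- function() {
    res <- data.frame(word = character(0L), component = integer(0L),
                      similarity = numeric(0L), membership = numeric(0L),
                      stringsAsFactors = FALSE)
    structure(res, config = config, n_candidates = length(cand_idx),
              class = c("expansion_result", "data.frame"))
  }
  if (length(cand_idx) == 0L) return(empty())

  mem <- membership(model, space$vectors[cand_idx, , drop = FALSE], p,
                    mode = config$mode)
  acc <- if (is.matrix(mem$accepted)) mem$accepted else
    matrix(mem$accepted, nrow = 1L)
  inside <- rowSums(acc) > 0
  if (!any(inside)) return(empty())

  idx <- cand_idx[inside]
  sim_in <- sims[idx, , drop = FALSE]
  best_comp <- max.col(sim_in, ties.method = "first")
  best_sim <- sim_in[cbind(seq_along(idx), best_comp)]
  val <- if (is.matrix(mem$value)) mem$value[inside, , drop = FALSE] else
    matrix(mem$value, nrow = 1L)
  # the governing value: max responsibility, or min Mahalanobis distance
  mem_val <- if (config$mode == "posterior") apply(val, 1L, max) else
    apply(val, 1L, min)

  res <- data.frame(word = space$vocab[idx], component = best_comp,
                    similarity = best_sim, membership = mem_val,
                    stringsAsFactors = FALSE)
  res <- res[order(-res$similarity, res$word), ]
  rownames(res) <- NULL
  structure(res, config = config, n_candidates = length(cand_idx),
            class = c("expansion_result", "data.frame"))
}

#' @export
print.expansion_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Expansion: %d new words (s = %.2f, p = %.2f, mode = %s)\n",
              nrow(x), cfg$similarity_level, cfg$probability_level, cfg$mode))
  if (nrow(x) > 0L) {
    print.data.frame(utils::head(x, 10L))
    if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more\n")
  }
  invisible(x)
}

#' Sweep expansion over a grid of configurations
#'
#' One row per configuration, identical to calling [expand_lexicon()] per
#' config: number of words discovered, precision against ground truth when
#' supplied, and the L-ED/H-ED percentage split when a trained classifier is
#' supplied.
#'
#' @inheritParams expand_lexicon
#' @param configs List of `expansion_config` objects.
#' @param truth Optional character vector of true food words (for precision).
#' @param classifier Optional `ed_model` (see [fit_ed_model()]) used to
#'   label discoveries.
#' @return Data frame with columns `similarity_level`, `probability_level`,
#'   `mode`, `n_discovered`, `precision`, `pct_L_ED`, `pct_H_ED`.
#' @export
sweep_expansion <- function(lex, space, model, configs, truth = NULL,
                            classifier = NULL) {
  stopifnot(is.list(configs), length(configs) >= 1L)
  rows <- lapply(configs, function(cfg) {
    res <- expand_lexicon(lex, space, model, cfg)
    n <- nrow(res)
    prec <- if (!is.null(truth) && n > 0L)
      evaluate_precision(res, truth = truth)$precision else NA_real_
    pctL <- pctH <- NA_real_
    if (!is.null(classifier) && n > 0L) {
      pred <- predict_ed(classifier, res$word, space)
      pctL <- 100 * mean(pred$ed_class == "L_ED")
      pctH <- 100 * mean(pred$ed_class == "H_ED")
    }
    data.frame(similarity_level = cfg$similarity_level,
               probability_level = cfg$probability_level,
               mode = cfg$mode, n_discovered = n, precision = prec,
               pct_L_ED = pctL, pct_H_ED = pctH, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate expansion precision
#'
#' With ground truth: exact precision (fraction of discovered words that are
#' true food words). Without: draws a seeded uniform sample of
#' `sample_size` discoveries for export to human annotation; precision is
#' then computed externally once annotations exist.
#'
#' @param result An `expansion_result` (non-empty).
#' @param truth Character vector of true food words, or a named logical
#'   vector (names = words).
#' @param sample_size Number of words to sample when no truth is given.
#' @param seed Seed for the annotation sample.
#' @return List with `precision` (NA when sampling for annotation),
#'   `n_evaluated`, and `sample` (the words drawn, if sampling).
#' @export
evaluate_precision <- function(result, truth = NULL, sample_size = 100L,
                               seed = 1L) {
  stopifnot(inherits(result, "expansion_result"))
  if (nrow(result) == 0L) {
    stop("precision is undefined for an empty expansion result", call. = FALSE)
  }
  if (!is.null(truth)) {
    is_food <- if (is.logical(truth)) {
      if (is.null(names(truth))) stop("logical `truth` must be named", call. = FALSE)
      unname(truth[result$word])
    } else {
      result$word %in% truth
    }
    is_food[is.na(is_food)] <- FALSE
    return(list(precision = mean(is_food), n_evaluated = nrow(result),
                sample = NULL))
  }
  if (sample_size > nrow(result)) {
    stop("sample_size (", sample_size, ") exceeds the number of discoveries (",
         nrow(result), ")", call. = FALSE)
  }
  set.seed(seed)
  list(precision = NA_real_, n_evaluated = sample_size,
       sample = sort(sample(result$word, sample_size)))
}
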