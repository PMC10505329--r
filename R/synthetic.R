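# Synthetic ground-truth generators: clustered food-word embedding spaces
# with per-cluster ED classes plus background vocabulary, seeded seed
# lexicons, and review corpora with planted per-outlet term counts. Every
# generator is deterministic given its seed, so the whole pipeline can be
# exercised end to end without external data.
#
# Word strings are opaque letter codes ("w" / "b" + letters), so nothing
# about a word's label leaks into matching or classification, and the
# identifiers stay inside the letters-and-underscores shape that the
# expansion candidate filter admits.

# index -> opaque lowercase letter code, e.g. 123 -> "aabcd"-style
.letter_code <- function(i, width = 6L) {
  chartr("0123456789", "abcdefghij", sprintf(paste0("%0", width, "d"), i))
}

#' Specification for a synthetic embedding space
#'
#' Food clusters are isotropic Gaussians (SD `sigma`) around centers placed
#' on a radius-`radius` shell with pairwise separation of at least
#' `min_separation` SDs; background words lie beyond `background_offset`.
#' With `background_offset > radius + 4 * sigma` the background is
#' separable from every cluster.
#'
#' @param n_food_clusters Number of planted food clusters.
#' @param words_per_cluster Words per cluster.
#' @param n_background_words Background (non-food) vocabulary size.
#' @param d Embedding dimension (25 by default: large enough for realistic
#'   mixture geometry, small enough that full-covariance fits stay cheap).
#' @param radius Shell radius for cluster centers.
#' @param sigma Within-cluster standard deviation.
#' @param background_offset Minimum norm of background vectors; must exceed
#'   `radius`.
#' @param min_separation Minimum pairwise center distance, in units of
#'   `sigma`.
#' @param ed_class_per_cluster Character vector (recycled) of `"L_ED"` /
#'   `"H_ED"` labels per cluster.
#' @param ed_ranges ED value range (kcal/g) drawn for seeds of each class;
#'   the defaults sit strictly inside the class intervals so a drawn value
#'   always classifies back to its class.
#' @param seed Mandatory integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_food_clusters = 10L, words_per_cluster = 50L,
                           n_background_words = 1000L, d = 25L,
                           radius = 10, sigma = 1, background_offset = 30,
                           min_separation = 8,
                           ed_class_per_cluster = c("L_ED", "H_ED"),
                           ed_ranges = list(L_ED = c(0.05, 1.45),
                                            H_ED = c(1.55, 6.0)),
                           seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  if (background_offset <= radius) {
    stop("infeasible geometry: background_offset must exceed radius",
         call. = FALSE)
  }
  stopifnot(n_food_clusters >= 1L, words_per_cluster >= 2L, d >= 2L,
            sigma > 0, min_separation > 0)
  structure(list(
    n_food_clusters = as.integer(n_food_clusters),
    words_per_cluster = as.integer(words_per_cluster),
    n_background_words = as.integer(n_background_words),
    d = as.integer(d), radius = radius, sigma = sigma,
    background_offset = background_offset, min_separation = min_separation,
    ed_class_per_cluster = rep_len(ed_class_per_cluster, n_food_clusters),
    ed_ranges = ed_ranges, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a synthetic embedding space with known cluster structure
#'
#' @param spec A [synthetic_spec()].
#' @return List with `space` (an `embedding_space`) and `truth`: data frame
#'   `word`, `cluster` (integer, `NA` for background), `ed_class` (`NA` for
#'   background). Word order in the space is a seeded permutation.
#' @export
generate_embedding_space <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  K <- spec$n_food_clusters; d <- spec$d

  # centers on the shell, resampled until pairwise separation holds
  centers <- matrix(0, K, d)
  for (k in seq_len(K)) {
    repeat {
      u <- stats::rnorm(d)
      c_k <- spec$radius * u / sqrt(sum(u^2))
      if (k == 1L) { centers[k, ] <- c_k; break }
      dists <- sqrt(rowSums((centers[seq_len(k - 1L), , drop = FALSE] -
                               matrix(c_k, k - 1L, d, byrow = TRUE))^2))
      if (all(dists >= spec$min_separation * spec$sigma)) {
        centers[k, ] <- c_k; break
      }
    }
  }

  n_food <- K * spec$words_per_cluster
  food <- centers[rep(seq_len(K), each = spec$words_per_cluster), ] +
    matrix(stats::rnorm(n_food * d, sd = spec$sigma), n_food, d)
  cluster <- rep(seq_len(K), each = spec$words_per_cluster)

  nb <- spec$n_background_words
  bg <- matrix(0, nb, d)
  if (nb > 0L) {
    u <- matrix(stats::rnorm(nb * d), nb, d)
    u <- u / sqrt(rowSums(u^2))
    r <- stats::runif(nb, spec$background_offset,
                      spec$background_offset + spec$radius)
    bg <- u * r
  }

  vectors <- rbind(food, bg)
  words <- c(paste0("w", vapply(seq_len(n_food), .letter_code, character(1L))),
             if (nb > 0L)
               paste0("b", vapply(seq_len(nb), .letter_code, character(1L))))
  truth <- data.frame(
    word = words,
    cluster = c(cluster, rep(NA_integer_, nb)),
    ed_class = c(spec$ed_class_per_cluster[cluster], rep(NA_character_, nb)),
    stringsAsFactors = FALSE)

  perm <- sample(nrow(vectors))
  vectors <- vectors[perm, , drop = FALSE]
  rownames(vectors) <- words[perm]
  truth <- truth[perm, , drop = FALSE]
  rownames(truth) <- NULL
  list(space = embedding_space(vectors), truth = truth)
}

#' Draw a seed lexicon from planted food clusters
#'
#' A seeded random fraction of each cluster becomes seed words with ED
#' values drawn uniformly from the class-consistent range; the remaining
#' food words are the held-out expansion targets.
#'
#' @param truth Truth table from [generate_embedding_space()].
#' @param fraction Fraction of each cluster used as seeds (0 < fraction < 1).
#' @param ed_ranges Per-class ED ranges (kcal/g).
#' @param seed Integer seed.
#' @param source Source tag for the seed terms.
#' @return List with `lexicon` (a `food_lexicon`) and `held_out` (data
#'   frame of the remaining food words with their cluster and class).
#' @export
generate_seed_lexicon <- function(truth, fraction = 0.5,
                                  ed_ranges = list(L_ED = c(0.05, 1.45),
                                                   H_ED = c(1.55, 6.0)),
                                  seed = 1L, source = "usda") {
  stopifnot(fraction > 0, fraction < 1)
  set.seed(seed)
  food <- truth[!is.na(truth$cluster), , drop = FALSE]
  seed_rows <- integer(0L)
  for (k in sort(unique(food$cluster))) {
    idx <- which(food$cluster == k)
    n_seed <- round(fraction * length(idx))
    if (n_seed == 0L) {
      warning("fraction leaves cluster ", k, " without seeds", call. = FALSE)
      next
    }
    seed_rows <- c(seed_rows, sample(idx, n_seed))
  }
  seeds <- food[sort(seed_rows), , drop = FALSE]
  held_out <- food[-sort(seed_rows), , drop = FALSE]

  ed <- numeric(nrow(seeds))
  for (cls in names(ed_ranges)) {
    sel <- seeds$ed_class == cls
    ed[sel] <- stats::runif(sum(sel), ed_ranges[[cls]][1L], ed_ranges[[cls]][2L])
  }
  lex <- lexicon(data.frame(surface = seeds$word, ed_kcal_per_g = ed,
                            source = source, stringsAsFactors = FALSE))
  rownames(held_out) <- NULL
  list(lexicon = lex, held_out = held_out)
}

#' Generate a review corpus with planted term counts
#'
#' Outlets are split round-robin across districts. For each outlet, the
#' number of occurrences of each lexicon term is drawn from a Poisson
#' distribution; the occurrences are interleaved with filler tokens (which
#' share no lexicon word) in seeded random order, with at least one filler
#' token between planted terms so greedy matching recovers the planted
#' counts exactly.
#'
#' @param lex A `food_lexicon` (may be empty: filler-only corpus).
#' @param n_outlets Number of outlets.
#' @param districts Character vector of district labels.
#' @param mean_terms_per_outlet Poisson mean of total planted term
#'   occurrences per outlet (spread uniformly over the lexicon).
#' @param filler_vocab Character vector of filler tokens; defaults to a
#'   generated non-food vocabulary.
#' @param seed Integer seed.
#' @return List with `reviews` (data frame `outlet_id`, `district`,
#'   `text`) and `planted` (data frame `outlet_id`, `district`, `surface`,
#'   `n_words`, `count` over nonzero plantings).
#' @export
generate_review_corpus <- function(lex, n_outlets = 60L,
                                   districts = c("east", "west"),
                                   mean_terms_per_outlet = 20,
                                   filler_vocab = NULL, seed = 1L) {
  stopifnot(length(districts) >= 1L, mean_terms_per_outlet >= 0)
  set.seed(seed)
  if (is.null(filler_vocab)) {
    filler_vocab <- paste0("zf", vapply(seq_len(50L), .letter_code,
                                        character(1L), width = 4L))
  }
  surfaces <- if (nrow(lex) > 0L) lex$surface else character(0L)
  district <- rep_len(districts, n_outlets)
  outlet_id <- sprintf("outlet_%03d", seq_len(n_outlets))

  reviews <- vector("list", n_outlets)
  planted <- vector("list", n_outlets)
  for (i in seq_len(n_outlets)) {
    counts <- if (length(surfaces) > 0L) {
      stats::rpois(length(surfaces), mean_terms_per_outlet / length(surfaces))
    } else integer(0L)
    terms <- rep(surfaces, counts)
    if (length(terms) > 0L) terms <- sample(terms)
    # at least one filler between consecutive planted terms
    n_slots <- length(terms) + 1L
    fillers <- replicate(n_slots, paste(
      sample(filler_vocab, 1L + stats::rpois(1L, 2)), collapse = " "))
    pieces <- character(0L)
    for (j in seq_along(terms)) {
      pieces <- c(pieces, fillers[j], gsub("_", " ", terms[j], fixed = TRUE))
    }
    pieces <- c(pieces, fillers[n_slots])
    reviews[[i]] <- data.frame(outlet_id = outlet_id[i],
                               district = district[i],
                               text = paste(pieces, collapse = " "),
                               stringsAsFactors = FALSE)
    nz <- which(counts > 0L)
    planted[[i]] <- if (length(nz)) data.frame(
      outlet_id = outlet_id[i], district = district[i],
      surface = surfaces[nz],
      n_words = lengths(strsplit(surfaces[nz], "_", fixed = TRUE)),
      count = counts[nz], stringsAsFactors = FALSE) else NULL
  }
  list(reviews = do.call(rbind, reviews),
       planted = do.call(rbind, planted))
}
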