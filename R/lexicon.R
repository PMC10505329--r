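# Seed food-word dictionary with energy-density classification.
#
# Energy density (ED, kcal/g) is classified under the British Nutrition
# Foundation four-level scheme (very low / low / medium / high) and collapsed
# to a binary class at 1.5 kcal/g: L_ED (very low + low) vs H_ED (medium +
# high).

#' Normalize a free-text food item name
#'
#' Lowercases, folds diacritics to ASCII, strips punctuation and any other
#' non-word characters, and joins the remaining tokens with underscores, so
#' multi-word items become phrase tokens (`"Sweet Potato Fries!"` becomes
#' `"sweet_potato_fries"`). Digits are kept.
#'
#' @param raw Character vector of raw item names.
#' @return Character vector of normalized surfaces. Elements that are empty
#'   after cleaning become `NA` with a warning; callers are expected to drop
#'   them.
#' @examples
#' normalize_term(c("Sweet Potato Fries!", "beer"))
#' @export
normalize_term <- function(raw) {
  if (!is.character(raw)) stop("`raw` must be a character vector", call. = FALSE)
  if (any(!nzchar(trimws(raw)) | is.na(raw))) {
    stop("`raw` contains empty or missing names", call. = FALSE)
  }
  x <- stringi::stri_trans_general(raw, "Latin-ASCII")
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  x <- trimws(x)
  x <- gsub(" +", "_", x)
  bad <- !nzchar(x)
  if (any(bad)) {
    warning(sum(bad), " item name(s) reduced to nothing after cleaning; returned as NA",
            call. = FALSE)
    x[bad] <- NA_character_
  }
  x
}

#' British Nutrition Foundation energy-density class
#'
#' Four-level scheme on energy density in kcal/g: `very_low` below 0.6,
#' `low` in \[0.6, 1.5), `medium` in \[1.5, 4\], `high` above 4.
#'
#' @param ed Numeric vector of energy densities (kcal/g), nonnegative.
#' @return Character vector in `c("very_low", "low", "medium", "high")`.
#' @seealso [classify_ed()] for the binary collapse.
#' @export
classify_bnf <- function(ed) {
  if (!is.numeric(ed)) stop("`ed` must be numeric", call. = FALSE)
  if (any(is.na(ed)) || any(ed < 0)) {
    stop("energy density must be nonnegative and non-missing", call. = FALSE)
  }
  out <- character(length(ed))
  out[ed < 0.6] <- "very_low"
  out[ed >= 0.6 & ed < 1.5] <- "low"
  out[ed >= 1.5 & ed <= 4] <- "medium"
  out[ed > 4] <- "high"
  out
}

#' Binary energy-density class
#'
#' Collapses the four BNF levels at 1.5 kcal/g: `L_ED` (very low + low,
#' ED < 1.5) vs `H_ED` (medium + high, ED >= 1.5).
#'
#' @inheritParams classify_bnf
#' @return Character vector in `c("L_ED", "H_ED")`.
#' @export
classify_ed <- function(ed) {
  if (!is.numeric(ed)) stop("`ed` must be numeric", call. = FALSE)
  if (any(is.na(ed)) || any(ed < 0)) {
    stop("energy density must be nonnegative and non-missing", call. = FALSE)
  }
  ifelse(ed < 1.5, "L_ED", "H_ED")
}

#' Construct a food term record
#'
#' A food term is a normalized surface (lowercase tokens joined by `_`) with
#' optional energy density and the class labels derived from it.
#'
#' @param surface Normalized surface string (see [normalize_term()]).
#' @param ed_kcal_per_g Energy density in kcal/g, or `NA`.
#' @param source One of `"usda"`, `"off"`, `"expanded"`.
#' @return One-row data frame with columns `surface`, `n_words`,
#'   `ed_kcal_per_g`, `bnf_class`, `ed_class`, `source`.
#' @export
food_term <- function(surface, ed_kcal_per_g = NA_real_, source = "usda") {
  stopifnot(is.character(surface), length(surface) == 1L)
  if (!grepl("^[a-z0-9]+(_[a-z0-9]+)*$", surface)) {
    stop("invalid surface: ", sQuote(surface),
         " (need lowercase/digit tokens joined by single underscores)", call. = FALSE)
  }
  source <- match.arg(source, c("usda", "off", "expanded"))
  ed <- as.numeric(ed_kcal_per_g)
  if (!is.na(ed) && ed < 0) stop("energy density must be nonnegative", call. = FALSE)
  data.frame(
    surface = surface,
    n_words = length(strsplit(surface, "_", fixed = TRUE)[[1L]]),
    ed_kcal_per_g = ed,
    bnf_class = if (is.na(ed)) NA_character_ else classify_bnf(ed),
    ed_class = if (is.na(ed)) NA_character_ else classify_ed(ed),
    source = source,
    stringsAsFactors = FALSE
  )
}

#' Construct a lexicon from food-term rows
#'
#' @param terms Data frame with the columns produced by [food_term()]
#'   (missing derived columns are recomputed).
#' @return Object of class `food_lexicon`: a data frame of unique terms.
#' @export
lexicon <- function(terms) {
  stopifnot(is.data.frame(terms))
  if (nrow(terms) == 0L) {
    terms <- food_term("placeholder")[0L, ]
  } else {
    stopifnot("surface" %in% names(terms))
    if (anyDuplicated(terms$surface)) {
      stop("duplicate surfaces in lexicon: ",
           paste(unique(terms$surface[duplicated(terms$surface)]), collapse = ", "),
           call. = FALSE)
    }
    terms$n_words <- lengths(strsplit(terms$surface, "_", fixed = TRUE))
    if (is.null(terms$ed_kcal_per_g)) terms$ed_kcal_per_g <- NA_real_
    terms$ed_kcal_per_g <- as.numeric(terms$ed_kcal_per_g)
    has_ed <- !is.na(terms$ed_kcal_per_g)
    # classes are derived from ED where present; a term without an ED value
    # (e.g. an expanded word labelled by the classifier) keeps any supplied
    # class labels
    bnf_keep <- if (is.null(terms$bnf_class)) NA_character_ else terms$bnf_class
    ed_keep <- if (is.null(terms$ed_class)) NA_character_ else terms$ed_class
    terms$bnf_class <- ifelse(has_ed, NA_character_, bnf_keep)
    terms$ed_class <- ifelse(has_ed, NA_character_, ed_keep)
    terms$bnf_class[has_ed] <- classify_bnf(terms$ed_kcal_per_g[has_ed])
    terms$ed_class[has_ed] <- classify_ed(terms$ed_kcal_per_g[has_ed])
    if (is.null(terms$source)) terms$source <- "usda"
    terms <- terms[, c("surface", "n_words", "ed_kcal_per_g", "bnf_class",
                       "ed_class", "source")]
  }
  rownames(terms) <- NULL
  class(terms) <- c("food_lexicon", "data.frame")
  terms
}

#' @export
print.food_lexicon <- function(x, ...) {
  cat("Food lexicon:", nrow(x), "terms\n")
  if (nrow(x) > 0L) {
    cat("  by word count:",
        paste(sprintf("%d-word: %d", sort(unique(x$n_words)),
                      tabulate(x$n_words)[sort(unique(x$n_words))]),
              collapse = ", "), "\n")
    if (any(!is.na(x$ed_class))) {
      tab <- table(x$ed_class)
      cat("  by ED class:", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
    }
    cat("  by source:", paste(names(table(x$source)), table(x$source),
                              sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Aggregate synonymous composition rows into one food term
#'
#' Mirrors the merge used when many database variants of an item (brands,
#' preparations) are collapsed into a single representative word: the term
#' gets the arithmetic mean of the contributing energy densities, and its
#' class labels are derived from that mean.
#'
#' @param items Data frame with columns `name` (raw names, unused beyond
#'   bookkeeping) and `ed` (kcal/g), or a numeric vector of EDs.
#' @param representative Normalized surface for the merged term.
#' @param source Source tag for the merged term.
#' @return One-row food-term data frame (see [food_term()]).
#' @export
aggregate_synonyms <- function(items, representative, source = "usda") {
  ed <- if (is.data.frame(items)) items$ed else items
  if (length(ed) == 0L) stop("`items` is empty", call. = FALSE)
  if (any(is.na(ed)) || any(ed < 0)) {
    stop("all energy densities must be nonnegative and non-missing", call. = FALSE)
  }
  food_term(representative, mean(ed), source = source)
}

# kJ -> kcal conversion factor
.kj_per_kcal <- 4.184

#' Build the seed lexicon from a food-composition table
#'
#' Normalizes item names, converts energies to kcal/g, drops rows without an
#' energy value, merges rows that normalize to the same surface by averaging
#' their energy densities, and keeps only surfaces present in the embedding
#' vocabulary (words without a vector cannot take part in clustering or
#' classification).
#'
#' @param composition Data frame with columns `name`, `energy`, `unit`
#'   (one of `"kcal_per_100g"`, `"kcal_per_g"`, `"kJ_per_100g"`), and
#'   optionally `source`.
#' @param vocab Character vector: the embedding vocabulary to intersect with.
#' @param source Default source tag used when `composition$source` is absent.
#' @return A `food_lexicon`. Empty (with a warning) if nothing survives.
#' @export
build_seed_lexicon <- function(composition, vocab, source = "usda") {
  stopifnot(is.data.frame(composition),
            all(c("name", "energy", "unit") %in% names(composition)))
  known_units <- c("kcal_per_100g", "kcal_per_g", "kJ_per_100g")
  if (!all(composition$unit %in% known_units)) {
    stop("unknown energy unit(s): ",
         paste(setdiff(unique(composition$unit), known_units), collapse = ", "),
         call. = FALSE)
  }
  src <- if ("source" %in% names(composition)) composition$source else rep(source, nrow(composition))

  # energy -> kcal/g
  ed <- composition$energy
  ed[composition$unit == "kcal_per_100g"] <- ed[composition$unit == "kcal_per_100g"] / 100
  ed[composition$unit == "kJ_per_100g"] <-
    ed[composition$unit == "kJ_per_100g"] / .kj_per_kcal / 100

  keep <- !is.na(ed)
  if (!all(keep)) message("dropping ", sum(!keep), " row(s) without an energy value")
  composition <- composition[keep, , drop = FALSE]
  ed <- ed[keep]
  src <- src[keep]

  if (nrow(composition) == 0L) {
    warning("no usable composition rows; returning empty lexicon", call. = FALSE)
    return(lexicon(data.frame()))
  }

  surf <- suppressWarnings(normalize_term(composition$name))
  usable <- !is.na(surf)
  if (!all(usable)) message("dropping ", sum(!usable), " unusable item name(s)")
  surf <- surf[usable]; ed <- ed[usable]; src <- src[usable]

  rows <- lapply(split(seq_along(surf), surf), function(idx) {
    term <- aggregate_synonyms(ed[idx], surf[idx[1L]],
                               source = src[idx[1L]])
    term
  })
  lex <- do.call(rbind, rows)

  in_vocab <- lex$surface %in% vocab
  if (!all(in_vocab)) {
    message("dropping ", sum(!in_vocab), " term(s) absent from the embedding vocabulary")
  }
  lex <- lex[in_vocab, , drop = FALSE]
  if (nrow(lex) == 0L) warning("empty seed lexicon: no term found in the vocabulary",
                               call. = FALSE)
  lexicon(lex)
}

#' Read / write a lexicon as TSV
#'
#' Columns: surface, n_words, ed_kcal_per_g, bnf_class, ed_class, source.
#'
#' @param x A `food_lexicon`.
#' @param path File path.
#' @return `write_lexicon` returns `path` invisibly; `read_lexicon` a
#'   `food_lexicon`.
#' @export
write_lexicon <- function(x, path) {
  stopifnot(inherits(x, "food_lexicon"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lexicon(df)
}
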