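# Dictionary matching over review corpora and the district-level case-study
# statistics: token counts of matched food terms (1-4 words), the
# difference-over-sum percent-increase statistic, and Welch two-sample
# t-tests on per-outlet counts.

#' Tokenize review text
#'
#' Applies the same character rules as [normalize_term()] — lowercase,
#' diacritics folded, anything other than letters/digits treated as a
#' separator — so corpus tokens and lexicon surfaces agree. Hyphens
#' separate tokens.
#'
#' @param text Character vector.
#' @return List of character vectors (one per input element); empty input
#'   gives an empty vector.
#' @export
tokenize <- function(text) {
  if (!is.character(text)) stop("`text` must be character", call. = FALSE)
  x <- stringi::stri_trans_general(text, "Latin-ASCII")
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  x <- trimws(x)
  out <- strsplit(x, " +")
  lapply(out, function(t) t[nzchar(t)])
}

#' Match lexicon terms in a token stream
#'
#' Greedy longest-match-first, left to right, non-overlapping: at each
#' position the longest window (up to `max_n` tokens, joined by `_`) that
#' is a lexicon surface is emitted and the scan jumps past it, so sub-terms
#' of a matched dish name are not double-counted. Token occurrences are
#' counted, not distinct types. `overlapping = TRUE` instead counts every
#' window match at every position (sensitivity analysis).
#'
#' @param tokens Character vector of tokens (one document).
#' @param lex A `food_lexicon`, or a character vector of surfaces.
#' @param max_n Longest term length, in words, to try.
#' @param overlapping Count all window matches instead of greedy
#'   non-overlapping ones?
#' @return Data frame with columns `surface`, `start` (token position),
#'   `n_words`.
#' @export
match_terms <- function(tokens, lex, max_n = 4L, overlapping = FALSE) {
  stopifnot(max_n >= 1L)
  surfaces <- if (inherits(lex, "food_lexicon") || is.data.frame(lex)) {
    lex$surface
  } else as.character(lex)
  out_surface <- character(0L); out_start <- integer(0L)
  L <- length(tokens)
  if (L == 0L || length(surfaces) == 0L) {
    return(data.frame(surface = character(0L), start = integer(0L),
                      n_words = integer(0L), stringsAsFactors = FALSE))
  }
  sset <- new.env(parent = emptyenv(), size = length(surfaces))
  for (s in surfaces) assign(s, TRUE, envir = sset)
  has <- function(s) !is.null(sset[[s]])

  if (overlapping) {
    for (i in seq_len(L)) {
      for (n in seq_len(min(max_n, L - i + 1L))) {
        cand <- paste(tokens[i:(i + n - 1L)], collapse = "_")
        if (has(cand)) {
          out_surface <- c(out_surface, cand)
          out_start <- c(out_start, i)
        }
      }
    }
  } else {
    i <- 1L
    while (i <= L) {
      matched <- FALSE
      for (n in rev(seq_len(min(max_n, L - i + 1L)))) {
        cand <- paste(tokens[i:(i + n - 1L)], collapse = "_")
        if (has(cand)) {
          out_surface <- c(out_surface, cand)
          out_start <- c(out_start, i)
          i <- i + n
          matched <- TRUE
          break
        }
      }
      if (!matched) i <- i + 1L
    }
  }
  data.frame(surface = out_surface, start = out_start,
             n_words = lengths(strsplit(out_surface, "_", fixed = TRUE)),
             stringsAsFactors = FALSE)
}

#' Percent increase between word counts under two dictionaries
#'
#' The headline statistic is the difference over the sum,
#' `100 * (E - O) / (O + E)` — the form that reproduces the printed
#' district percentages from their count pairs. The conventional relative
#' change `100 * (E - O) / O` is available as
#' [percent_increase_conventional()].
#'
#' @param original,expanded Nonnegative counts (vectorized).
#' @return Percentages.
#' @export
percent_increase <- function(original, expanded) {
  stopifnot(length(original) == length(expanded))
  if (any(original + expanded <= 0)) {
    stop("percent increase undefined when both counts are zero", call. = FALSE)
  }
  100 * (expanded - original) / (original + expanded)
}

#' @rdname percent_increase
#' @export
percent_increase_conventional <- function(original, expanded) {
  stopifnot(length(original) == length(expanded))
  if (any(original <= 0)) {
    stop("conventional percent increase undefined for a zero baseline",
         call. = FALSE)
  }
  100 * (expanded - original) / original
}

#' Welch two-sample t-test on per-outlet counts
#'
#' Unequal-variance two-sample t with Welch-Satterthwaite fractional
#' degrees of freedom and a two-sided p-value. Thin wrapper over
#' [stats::t.test()] returning just the triple the case-study tables print.
#'
#' @param a,b Numeric vectors (each of length >= 2; at least one with
#'   nonzero variance).
#' @return Object of class `welch_test`: list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("both samples have zero variance; t-test undefined", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value), class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t = %.3f, df = %.2f, p = %.4g\n", x$t, x$df, x$p))
  invisible(x)
}

#' Read review records from CSV or JSONL
#'
#' Expected fields: `outlet_id`, `district`, `text`, and optionally
#' `lon`, `lat`. Format chosen by file extension (`.jsonl`/`.ndjson` vs
#' anything else as CSV).
#'
#' @param path File path.
#' @return Data frame of review records.
#' @export
read_reviews <- function(path) {
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  req <- c("outlet_id", "district", "text")
  if (!all(req %in% names(df))) {
    stop("reviews must have fields: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(as.character(df$outlet_id)))) {
    stop("empty outlet_id in reviews", call. = FALSE)
  }
  df$text[is.na(df$text)] <- ""
  df
}

# per-outlet match counts for one lexicon: data frame
#   outlet_id, district, total, nw1..nw4, L_ED, H_ED
.outlet_counts <- function(reviews, lex, max_n = 4L) {
  ed_map <- NULL
  if (inherits(lex, "food_lexicon")) {
    ed_map <- stats::setNames(lex$ed_class, lex$surface)
  }
  toks <- tokenize(as.character(reviews$text))
  key <- paste(reviews$outlet_id, reviews$district, sep = "\r")
  groups <- split(seq_len(nrow(reviews)), key)
  rows <- lapply(groups, function(idx) {
    m <- do.call(rbind, lapply(idx, function(i) match_terms(toks[[i]], lex, max_n)))
    nw <- tabulate(m$n_words, nbins = max_n)
    ed <- if (!is.null(ed_map) && nrow(m) > 0L) ed_map[m$surface] else character(0L)
    data.frame(outlet_id = reviews$outlet_id[idx[1L]],
               district = reviews$district[idx[1L]],
               total = nrow(m),
               t(stats::setNames(nw, paste0("nw", seq_len(max_n)))),
               L_ED = sum(ed == "L_ED", na.rm = TRUE),
               H_ED = sum(ed == "H_ED", na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' District-level comparison of two lexicons over a review corpus
#'
#' For every district (and per term length, plus the `"all"` total):
#' matched-token counts under the original and expanded lexicons, the
#' percent-increase statistic, and a Welch t-test comparing the per-outlet
#' counts under the two lexicons. Districts with fewer than two outlets get
#' no test (noted).
#'
#' @param reviews Data frame with `outlet_id`, `district`, `text` (see
#'   [read_reviews()]); every review must carry a district label.
#' @param lexicon_old,lexicon_new The original and expanded lexicons.
#' @param max_n Longest term length matched.
#' @return Object of class `district_report`: data frame with columns
#'   `district`, `n_words` (`"all"` or `"1"`..`"4"`), `n_outlets`,
#'   `count_old`, `count_new`, `pct_increase`, `t`, `df`, `p`, `note`.
#'   Attribute `outlet_counts` holds the per-outlet tables.
#' @export
district_report <- function(reviews, lexicon_old, lexicon_new, max_n = 4L) {
  stopifnot(is.data.frame(reviews),
            all(c("outlet_id", "district", "text") %in% names(reviews)))
  if (any(is.na(reviews$district) | !nzchar(as.character(reviews$district)))) {
    stop("every review must carry a district label", call. = FALSE)
  }
  old <- .outlet_counts(reviews, lexicon_old, max_n)
  new <- .outlet_counts(reviews, lexicon_new, max_n)
  stopifnot(identical(old$outlet_id, new$outlet_id))

  count_cols <- stats::setNames(c("all", as.character(seq_len(max_n))),
                                c("total", paste0("nw", seq_len(max_n))))
  rows <- list()
  for (dist in sort(unique(old$district))) {
    sel <- old$district == dist
    for (col in names(count_cols)) {
      o <- old[[col]][sel]; e <- new[[col]][sel]
      O <- sum(o); E <- sum(e)
      pct <- if (O + E > 0) percent_increase(O, E) else NA_real_
      tt <- NULL; note <- ""
      if (sum(sel) < 2L) {
        note <- "fewer than 2 outlets; test omitted"
      } else if (stats::var(o) == 0 && stats::var(e) == 0) {
        if (identical(o, e)) {
          tt <- list(t = 0, df = NA_real_, p = 1)
          note <- "identical counts"
        } else note <- "zero variance in both samples; test omitted"
      } else {
        tt <- welch_t_test(o, e)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        district = dist, n_words = count_cols[[col]], n_outlets = sum(sel),
        count_old = O, count_new = E, pct_increase = pct,
        t = if (is.null(tt)) NA_real_ else tt$t,
        df = if (is.null(tt)) NA_real_ else tt$df,
        p = if (is.null(tt)) NA_real_ else tt$p,
        note = note, stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  structure(rep, outlet_counts = list(old = old, new = new),
            class = c("district_report", "data.frame"))
}
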