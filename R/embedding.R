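# Word-embedding spaces in word2vec format with exact cosine-similarity
# search (full scan; no approximate index, so brute-force equivalence holds).

#' Construct an embedding space
#'
#' @param vectors Numeric matrix, one row per word, with unique rownames.
#' @return Object of class `embedding_space`: list with `vocab`, `vectors`
#'   (|vocab| x d) and `d`.
#' @export
embedding_space <- function(vectors) {
  stopifnot(is.matrix(vectors), is.numeric(vectors), nrow(vectors) >= 1L)
  words <- rownames(vectors)
  if (is.null(words) || any(!nzchar(words))) {
    stop("`vectors` must have non-empty rownames (the vocabulary)", call. = FALSE)
  }
  if (anyDuplicated(words)) {
    stop("duplicate word in vocabulary: ",
         words[duplicated(words)][1L], call. = FALSE)
  }
  structure(list(vocab = words, vectors = vectors, d = ncol(vectors)),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat("Embedding space:", length(x$vocab), "words, dimension", x$d, "\n")
  invisible(x)
}

#' Look up word vectors
#'
#' @param space An `embedding_space`.
#' @param words Character vector; all must be in the vocabulary unless
#'   `strict = FALSE`, in which case out-of-vocabulary words are dropped with
#'   a message (their count is reported).
#' @param strict Error on out-of-vocabulary words?
#' @return Matrix of vectors (one row per retained word).
#' @export
word_vectors <- function(space, words, strict = TRUE) {
  stopifnot(inherits(space, "embedding_space"))
  hit <- words %in% space$vocab
  if (!all(hit)) {
    if (strict) stop(sum(!hit), " word(s) not in vocabulary, e.g. ",
                     sQuote(words[!hit][1L]), call. = FALSE)
    message("skipping ", sum(!hit), " out-of-vocabulary word(s)")
  }
  space$vectors[words[hit], , drop = FALSE]
}

#' Load word2vec-format embeddings
#'
#' Supports the standard text format (header line `"<n> <d>"`, then one word
#' and d numbers per line) and the binary format (same header, then each word
#' as bytes terminated by a space followed by d little-endian float32
#' values). Lookup is case-sensitive.
#'
#' @param path File path.
#' @param format `"word2vec_text"` or `"word2vec_binary"`.
#' @return An `embedding_space`.
#' @export
load_embeddings <- function(path, format = c("word2vec_text", "word2vec_binary")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "word2vec_text") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    header <- as.integer(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]])
    if (length(header) != 2L || any(is.na(header))) {
      stop("malformed word2vec header: ", sQuote(lines[1L]), call. = FALSE)
    }
    n <- header[1L]; d <- header[2L]
    body <- lines[-1L]
    if (length(body) != n) {
      stop("header declares ", n, " words but file has ", length(body), call. = FALSE)
    }
    parts <- strsplit(body, "[ \t]+")
    words <- vapply(parts, `[[`, character(1L), 1L)
    vals <- lapply(parts, function(p) as.numeric(p[-1L]))
    if (any(lengths(vals) != d)) {
      stop("row with wrong dimension (expected ", d, ")", call. = FALSE)
    }
    m <- do.call(rbind, vals)
    rownames(m) <- words
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    header_chars <- character(0L)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("unexpected end of file in header", call. = FALSE)
      if (ch == "\n") break
      header_chars <- c(header_chars, ch)
    }
    header <- as.integer(strsplit(trimws(paste(header_chars, collapse = "")),
                                  " +")[[1L]])
    if (length(header) != 2L || any(is.na(header))) {
      stop("malformed word2vec binary header", call. = FALSE)
    }
    n <- header[1L]; d <- header[2L]
    m <- matrix(0, n, d)
    words <- character(n)
    for (i in seq_len(n)) {
      wchars <- raw(0L)
      repeat {
        b <- readBin(con, "raw", 1L)
        if (length(b) == 0L) {
          stop("header declares ", n, " words but file ends after ", i - 1L,
               call. = FALSE)
        }
        if (b == as.raw(0x20)) break
        if (b == as.raw(0x0a) && length(wchars) == 0L) next  # leading newline
        wchars <- c(wchars, b)
      }
      words[i] <- rawToChar(wchars)
      vec <- readBin(con, "numeric", d, size = 4L, endian = "little")
      if (length(vec) != d) stop("truncated vector for word ", sQuote(words[i]),
                                 call. = FALSE)
      m[i, ] <- vec
    }
    rownames(m) <- words
  }
  if (anyDuplicated(rownames(m))) {
    stop("duplicate word in embedding file: ",
         rownames(m)[duplicated(rownames(m))][1L], call. = FALSE)
  }
  embedding_space(m)
}

#' Write embeddings in word2vec format
#'
#' Text output uses full double precision (`format(..., digits = 17)`); the
#' binary format is float32 by definition, so a text round-trip is bit-exact
#' while a binary round-trip is exact at float32 resolution.
#'
#' @param space An `embedding_space`.
#' @inheritParams load_embeddings
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(space, path,
                             format = c("word2vec_text", "word2vec_binary")) {
  stopifnot(inherits(space, "embedding_space"))
  format <- match.arg(format)
  n <- length(space$vocab); d <- space$d
  if (format == "word2vec_text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(n, d), con)
    for (i in seq_len(n)) {
      writeLines(paste(space$vocab[i],
                       paste(format(space$vectors[i, ], digits = 17,
                                    scientific = FALSE, trim = TRUE),
                             collapse = " ")), con)
    }
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(n, " ", d, "\n"), con, eos = NULL)
    for (i in seq_len(n)) {
      writeChar(paste0(space$vocab[i], " "), con, eos = NULL)
      writeBin(as.numeric(space$vectors[i, ]), con, size = 4L, endian = "little")
      writeChar("\n", con, eos = NULL)
    }
  }
  invisible(path)
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal dimension; neither all-zero.
#' @return `u . v / (|u| |v|)`, in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch", call. = FALSE)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector",
                               call. = FALSE)
  sum(u * v) / (nu * nv)
}

# unit-normalized copy of the vocabulary matrix (rows with zero norm get NaN
# similarities and can never pass a threshold in [0, 1])
.unit_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  m / nrm
}

#' All vocabulary words within a similarity level of a query
#'
#' Full scan against a unit-normalized copy of the vocabulary matrix:
#' exactly the words with cosine similarity >= `s` to the query, sorted by
#' similarity descending, ties broken lexicographically.
#'
#' @param space An `embedding_space`.
#' @param query Numeric vector of dimension `space$d` (non-zero).
#' @param s Similarity level in \[0, 1\].
#' @return Data frame with columns `word`, `similarity`.
#' @export
neighbors_within <- function(space, query, s) {
  stopifnot(inherits(space, "embedding_space"))
  if (length(query) != space$d) stop("query dimension mismatch", call. = FALSE)
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s > 1) {
    stop("`s` must be a single value in [0, 1]", call. = FALSE)
  }
  qn <- sqrt(sum(query^2))
  if (qn == 0) stop("cosine similarity undefined for a zero query", call. = FALSE)
  sims <- as.vector(.unit_rows(space$vectors) %*% (query / qn))
  # tiny slack so an exact duplicate of the query passes s = 1 despite
  # floating-point rounding in the normalized product
  keep <- which(!is.na(sims) & sims >= s - 1e-12)
  ord <- keep[order(-sims[keep], space$vocab[keep])]
  data.frame(word = space$vocab[ord], similarity = sims[ord],
             stringsAsFactors = FALSE)
}
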