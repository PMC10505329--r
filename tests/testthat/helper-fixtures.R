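# Shared fixtures: small synthetic constructions used across test files.

# modest planted space: fast enough for per-module tests
small_spec <- function(seed, n_food_clusters = 4L, words_per_cluster = 25L,
                       n_background_words = 200L, d = 25L, ...) {
  synthetic_spec(n_food_clusters = n_food_clusters,
                 words_per_cluster = words_per_cluster,
                 n_background_words = n_background_words, d = d,
                 seed = seed, ...)
}

# random embedding space with given words
random_space <- function(n, d, seed) {
  set.seed(seed)
  m <- matrix(rnorm(n * d), n, d)
  rownames(m) <- sprintf("word%03d", seq_len(n))
  embedding_space(m)
}

# two well-separated gaussian blobs with ED labels: list(X, y)
separable_xy <- function(n_per_class, d, margin = 8, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * d), n_per_class, d),
             matrix(rnorm(n_per_class * d), n_per_class, d))
  X[seq_len(n_per_class), 1] <- X[seq_len(n_per_class), 1] + margin
  y <- rep(c("L_ED", "H_ED"), each = n_per_class)
  perm <- sample(2 * n_per_class)
  list(X = X[perm, , drop = FALSE], y = y[perm])
}

# independent log-likelihood oracle: direct density evaluation with base
# linear algebra (no shared code with the package internals)
gmm_loglik_oracle <- function(weights, means, cov_list, X) {
  n <- nrow(X); K <- length(weights); d <- ncol(X)
  dens <- matrix(0, n, K)
  for (k in seq_len(K)) {
    S <- cov_list[[k]]
    Sinv <- solve(S)
    logdet <- determinant(S, logarithm = TRUE)$modulus
    for (i in seq_len(n)) {
      xc <- X[i, ] - means[k, ]
      dens[i, k] <- log(weights[k]) - 0.5 * (d * log(2 * pi) + logdet +
                                               drop(t(xc) %*% Sinv %*% xc))
    }
  }
  sum(log(rowSums(exp(dens))))
}

# independent Welch oracle: textbook formula
welch_oracle <- function(a, b) {
  m1 <- mean(a); m2 <- mean(b)
  v1 <- var(a) / length(a); v2 <- var(b) / length(b)
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
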