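test_that("count_params follows the covariance-family formulas", {
  expect_equal(count_params(1, 1, "spherical"), 2L)
  expect_equal(count_params(2, 3, "full"), 19L)
  expect_equal(count_params(3, 2, "tied"), 11L)
  expect_equal(count_params(2, 4, "diag"), 17L)  # 1 + 8 + 8
  expect_error(count_params(2, 3, "banana"))
})

test_that("K = 1 recovers the maximum-likelihood Gaussian", {
  set.seed(21)
  X <- matrix(rnorm(200 * 4, mean = 2), 200, 4)
  for (ct in c("full", "tied", "diag", "spherical")) {
    m <- fit_gmm(X, 1, ct, seed = 3)
    expect_equal(m$weights, 1)
    expect_equal(unname(m$means[1, ]), unname(colMeans(X)), tolerance = 1e-8)
  }
  # spherical K = 1: AIC against the closed-form Gaussian log-likelihood
  m <- fit_gmm(X, 1, "spherical", seed = 3, reg = 1e-6)
  n <- nrow(X); d <- ncol(X)
  Xc <- sweep(X, 2, colMeans(X))
  s2 <- mean(colSums(Xc^2) / n) + 1e-6
  ll <- sum(-0.5 * d * log(2 * pi * s2) - rowSums(Xc^2) / (2 * s2))
  expect_equal(m$log_likelihood, ll, tolerance = 1e-6)
  expect_equal(m$aic, 2 * count_params(1, d, "spherical") - 2 * ll,
               tolerance = 1e-6)
})

test_that("reported log-likelihood equals direct density evaluation", {
  set.seed(22)
  X <- rbind(matrix(rnorm(60 * 3), 60, 3),
             matrix(rnorm(60 * 3, mean = 6), 60, 3))
  for (ct in c("full", "tied", "diag", "spherical")) {
    m <- fit_gmm(X, 2, ct, seed = 4)
    covs <- lapply(seq_len(m$K), function(k) component_covariance(m, k))
    oracle <- gmm_loglik_oracle(m$weights, m$means, covs, X)
    expect_equal(m$log_likelihood, oracle, tolerance = 1e-6)
    expect_equal(m$aic, 2 * m$n_params - 2 * m$log_likelihood)
  }
})

test_that("planted two-cluster structure is recovered", {
  set.seed(23)
  d <- 5
  X <- rbind(matrix(rnorm(80 * d), 80, d),
             matrix(rnorm(80 * d, mean = 10), 80, d))  # 10 within-SD apart
  labels <- rep(1:2, each = 80)
  m <- fit_gmm(X, 2, "full", seed = 5)
  hard <- max.col(responsibilities(m, X))
  agreement <- max(mean(hard == labels), mean(hard == 3 - labels))
  expect_equal(agreement, 1.0)
  expect_true(m$converged)
})

test_that("EM log-likelihood is non-decreasing along the trace", {
  set.seed(24)
  X <- rbind(matrix(rnorm(100 * 4), 100, 4),
             matrix(rnorm(100 * 4, mean = 3), 100, 4))
  for (ct in c("full", "diag")) {
    m <- fit_gmm(X, 3, ct, seed = 6)
    expect_true(all(diff(m$loglik_trace) > -1e-6))
  }
})

test_that("fit_gmm is deterministic and validates inputs", {
  set.seed(25)
  X <- matrix(rnorm(50 * 3), 50, 3)
  m1 <- fit_gmm(X, 2, "diag", seed = 7)
  m2 <- fit_gmm(X, 2, "diag", seed = 7)
  expect_identical(m1$log_likelihood, m2$log_likelihood)
  expect_identical(m1$means, m2$means)
  expect_error(fit_gmm(X[1:2, ], 2, "diag", seed = 1), "n > K")
})

test_that("calibrate selects the planted component count", {
  spec <- small_spec(seed = 31, n_food_clusters = 3, words_per_cluster = 40,
                     n_background_words = 0, d = 10)
  emb <- generate_embedding_space(spec)
  X <- emb$space$vectors
  cal <- calibrate(X, 1:5, cov_types = c("diag", "spherical"), seed = 8)
  expect_equal(cal$best$K, 3L)
  expect_equal(nrow(cal$table), 10L)
  # single blob
  set.seed(32)
  X1 <- matrix(rnorm(300 * 6), 300, 6)
  cal1 <- calibrate(X1, 1:4, cov_types = "spherical", seed = 8)
  expect_equal(cal1$best$K, 1L)
  # determinism
  cal2 <- calibrate(X, 1:5, cov_types = c("diag", "spherical"), seed = 8)
  expect_identical(cal$table, cal2$table)
  # selected K invariant to row shuffling
  set.seed(33)
  calr <- calibrate(X[sample(nrow(X)), ], 1:5,
                    cov_types = c("diag", "spherical"), seed = 8)
  expect_equal(calr$best$K, cal$best$K)
})

test_that("two-stage refinement searches around the coarse optimum", {
  spec <- small_spec(seed = 34, n_food_clusters = 4, words_per_cluster = 80,
                     n_background_words = 0, d = 10)
  emb <- generate_embedding_space(spec)
  cal <- calibrate(emb$space$vectors, c(1, 3, 5, 7), cov_types = "spherical",
                   seed = 9, refine_radius = 2)
  fine <- cal$table[cal$table$stage == "fine", ]
  expect_gt(nrow(fine), 0)
  # the fine pass fills in the unvisited K around the coarse optimum
  coarse_best <- with(cal$table[cal$table$stage == "coarse", ],
                      K[which.min(aic)])
  expect_setequal(fine$K, setdiff(seq(coarse_best - 2, coarse_best + 2),
                                  c(1, 3, 5, 7)))
  expect_equal(cal$best$K, 4L)
})

test_that("membership accepts centroids and normalizes responsibilities", {
  set.seed(26)
  X <- rbind(matrix(rnorm(100 * 4), 100, 4),
             matrix(rnorm(100 * 4, mean = 8), 100, 4))
  m <- fit_gmm(X, 2, "full", seed = 10)
  for (p in c(0.05, 0.5, 0.95)) {
    mem <- membership(m, m$means[1, ], p, mode = "quantile")
    expect_true(mem$accepted[1])
    expect_true(mem$inside)
  }
  set.seed(27)
  pts <- matrix(rnorm(20 * 4, sd = 5), 20, 4)
  resp <- responsibilities(m, pts)
  expect_equal(rowSums(resp), rep(1, 20))
  mem <- membership(m, pts, 0.7, mode = "posterior")
  expect_equal(dim(mem$accepted), c(20L, 2L))
})

test_that("quantile-mode ellipsoids hold the nominal probability mass", {
  set.seed(28)
  X <- matrix(rnorm(5000 * 5, mean = 1, sd = 2), 5000, 5)
  m <- fit_gmm(X, 1, "spherical", seed = 11)
  # draw from the fitted component and measure empirical coverage
  set.seed(29)
  n_mc <- 10000
  draws <- matrix(rnorm(n_mc * 5, sd = sqrt(m$covariances[1])), n_mc, 5)
  draws <- sweep(draws, 2, m$means[1, ], "+")
  for (p in c(0.5, 0.75, 0.9)) {
    cover <- mean(membership(m, draws, p, mode = "quantile")$accepted[, 1])
    se <- sqrt(p * (1 - p) / n_mc)
    expect_lt(abs(cover - p), 3 * se)
  }
})

test_that("mixture serialization round-trips through JSON", {
  set.seed(30)
  X <- rbind(matrix(rnorm(60 * 3), 60, 3),
             matrix(rnorm(60 * 3, mean = 5), 60, 3))
  for (ct in c("full", "tied", "diag", "spherical")) {
    m <- fit_gmm(X, 2, ct, seed = 12)
    path <- withr::local_tempfile(fileext = ".json")
    write_gmm(m, path)
    back <- read_gmm(path)
    expect_equal(back$means, m$means, ignore_attr = TRUE)
    expect_equal(back$aic, m$aic)
    expect_equal(responsibilities(back, X), responsibilities(m, X),
                 tolerance = 1e-12)
  }
})

test_that("mixture density agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(35)
  X <- rbind(matrix(rnorm(100 * 3), 100, 3),
             matrix(rnorm(100 * 3, mean = 6), 100, 3))
  m <- fit_gmm(X, 2, "full", seed = 13, reg = 0, tol = 1e-8, max_iter = 500)
  mc <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  # both EMs should land on the same well-separated optimum
  expect_equal(m$log_likelihood, mc$loglik, tolerance = 1e-3)
})
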