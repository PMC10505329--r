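# Benchmark of ten classifiers predicting the binary energy-density class
# of a word from its embedding vector: ANN, SVM, GP, AdaBoost, naive Bayes,
# QDA, gradient boosting, k-NN, random forest, decision tree.
#
# Stratified fivefold cross-validation with fold splits shared across
# models; defaults first, then grid-search tuning of the top performers on
# the same folds. Features are used unscaled by default (defaults-first
# benchmarking); pass scale = TRUE to standardize.

.ed_levels <- c("L_ED", "H_ED")
.model_names <- c("ANN", "SVM", "GP", "AB", "NB", "QDA", "GB", "KNN", "RF", "DT")

.as_feature_df <- function(X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df
}

# ---- AdaBoost.M1 on depth-1 rpart stumps ------------------------------
# (no boosted-stump package is available; the algorithm is small enough to
# carry here: exponential reweighting with alpha = log((1 - err) / err) / 2)
.fit_adaboost <- function(X, y, n_rounds = 50L) {
  df <- .as_feature_df(X)
  df$.y <- y
  n <- nrow(df)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0L)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w, method = "class",
                        control = rpart::rpart.control(maxdepth = 1L,
                                                       xval = 0L, cp = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w[pred != y]) / sum(w)
    if (err >= 0.5) break                     # stump no better than chance
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(alpha * ifelse(pred != y, 1, -1))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (length(stumps) == 0L) {                 # degenerate: majority class
    stumps <- list(NULL)
    alphas <- 1
  }
  list(stumps = stumps, alphas = alphas, levels = levels(y),
       majority = names(which.max(table(y))))
}

.predict_adaboost <- function(fit, X) {
  df <- .as_feature_df(X)
  if (is.null(fit$stumps[[1L]])) {
    return(factor(rep(fit$majority, nrow(df)), levels = fit$levels))
  }
  score <- rep(0, nrow(df))
  for (m in seq_along(fit$stumps)) {
    pred <- predict(fit$stumps[[m]], df, type = "class")
    score <- score + fit$alphas[m] * ifelse(pred == fit$levels[2L], 1, -1)
  }
  factor(ifelse(score >= 0, fit$levels[2L], fit$levels[1L]),
         levels = fit$levels)
}

# ---- model registry ----------------------------------------------------
# each entry: fit(X, y, params) and predict(fit, X) -> factor on levels(y)

.model_registry <- function() {
  list(
    ANN = list(
      fit = function(X, y, p) {
        size <- p$size %||% 100L
        fit <- nnet::nnet(x = X, y = as.numeric(y == levels(y)[2L]),
                          size = size, decay = p$decay %||% 1e-4,
                          maxit = 200L, MaxNWts = 100000L,
                          entropy = TRUE, trace = FALSE)
        list(fit = fit, levels = levels(y))
      },
      predict = function(f, X) {
        pr <- as.vector(predict(f$fit, X))
        factor(ifelse(pr >= 0.5, f$levels[2L], f$levels[1L]), levels = f$levels)
      }),
    SVM = list(
      fit = function(X, y, p) {
        gamma <- p$gamma
        if (is.null(gamma) || is.na(gamma)) gamma <- 1 / ncol(X)
        e1071::svm(X, y, kernel = "radial", cost = p$cost %||% 1,
                   gamma = gamma)
      },
      predict = function(f, X) predict(f, X)),
    GP = list(
      fit = function(X, y, p) {
        scale <- p$scale %||% 1
        if (is.na(scale)) scale <- 1
        sigma <- stats::median(kernlab::sigest(X, scaled = FALSE)) * scale
        kernlab::gausspr(X, y, kernel = "rbfdot",
                         kpar = list(sigma = sigma), scaled = FALSE)
      },
      predict = function(f, X) kernlab::predict(f, X)),
    AB = list(
      fit = function(X, y, p) .fit_adaboost(X, y, p$n_rounds %||% 50L),
      predict = .predict_adaboost),
    NB = list(
      fit = function(X, y, p) {
        list(fit = e1071::naiveBayes(.as_feature_df(X), y), levels = levels(y))
      },
      predict = function(f, X) predict(f$fit, .as_feature_df(X))),
    QDA = list(
      fit = function(X, y, p) MASS::qda(X, grouping = y),
      predict = function(f, X) predict(f, X)$class),
    GB = list(
      fit = function(X, y, p) {
        fit <- xgboost::xgboost(X, y, nrounds = p$nrounds %||% 100L,
                                max_depth = 3L, learning_rate = 0.1,
                                nthreads = 1L, verbosity = 0L)
        # predict() returns the probability of the second factor level
        list(fit = fit, levels = levels(y))
      },
      predict = function(f, X) {
        pr <- predict(f$fit, X)
        factor(ifelse(pr >= 0.5, f$levels[2L], f$levels[1L]), levels = f$levels)
      }),
    KNN = list(
      fit = function(X, y, p) list(X = X, y = y, k = p$k %||% 5L),
      predict = function(f, X) class::knn(f$X, X, f$y, k = f$k)),
    RF = list(
      fit = function(X, y, p) {
        depth <- p$depth %||% Inf
        maxnodes <- if (is.finite(depth)) min(2^depth, nrow(X)) else NULL
        randomForest::randomForest(X, y, ntree = p$ntree %||% 100L,
                                   maxnodes = maxnodes)
      },
      predict = function(f, X) predict(f, X)),
    DT = list(
      fit = function(X, y, p) {
        df <- .as_feature_df(X)
        df$.y <- y
        rpart::rpart(.y ~ ., data = df, method = "class")
      },
      predict = function(f, X) predict(f, .as_feature_df(X), type = "class"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.coerce_labels <- function(y) {
  y <- factor(as.character(y), levels = intersect(.ed_levels, unique(as.character(y))))
  if (nlevels(y) == 1L) stop("both ED classes must be present in `y`", call. = FALSE)
  if (nlevels(y) != 2L) stop("`y` must contain the two classes L_ED / H_ED",
                             call. = FALSE)
  factor(y, levels = .ed_levels)
}

#' Stratified cross-validation fold assignment
#'
#' Depends only on (`y`, `k`, `seed`): within each class, observations are
#' shuffled under the seed and dealt round-robin to folds.
#'
#' @param y Class labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  y <- as.factor(y)
  set.seed(seed)
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- which(y == lev)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

.cv_accuracy <- function(X, y, fold, model_name, params, seed, scale_features) {
  registry <- .model_registry()[[model_name]]
  k <- max(fold)
  accs <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (scale_features) {
      mu <- colMeans(Xtr); sdv <- apply(Xtr, 2L, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/")
      Xte <- sweep(sweep(Xte, 2L, mu), 2L, sdv, "/")
    }
    set.seed(seed + f)
    fit <- registry$fit(Xtr, y[tr], params)
    pred <- registry$predict(fit, Xte)
    accs[f] <- mean(pred == y[te])
  }
  accs
}

#' Cross-validate the ten-model classifier benchmark
#'
#' Runs stratified fivefold cross-validation with identical fold splits for
#' every model, each at its default hyperparameters, and reports mean
#' accuracy and the standard deviation of the fold accuracies (both in %),
#' sorted by mean accuracy descending.
#'
#' @param X Numeric matrix of word vectors (n x d), n >= 10.
#' @param y ED class labels (`"L_ED"` / `"H_ED"`); both classes required.
#' @param seed Integer seed (fold splits and stochastic fits).
#' @param folds Number of folds.
#' @param models Subset of model names to run (default: all ten).
#' @param scale Standardize features inside each training fold?
#' @return Object of class `cv_report`: data frame with columns `model`,
#'   `mean_accuracy`, `sd_accuracy`, `folds`; attributes `fold_assignment`,
#'   `seed`, `scale`.
#' @export
cross_validate_models <- function(X, y, seed = 1L, folds = 5L,
                                  models = .model_names, scale = FALSE) {
  stopifnot(is.matrix(X), nrow(X) >= 10L)
  y <- .coerce_labels(y)
  stopifnot(length(y) == nrow(X))
  models <- match.arg(models, .model_names, several.ok = TRUE)
  fold <- stratified_folds(y, folds, seed)
  rows <- lapply(models, function(m) {
    accs <- .cv_accuracy(X, y, fold, m, list(), seed, scale)
    data.frame(model = m, mean_accuracy = 100 * mean(accs),
               sd_accuracy = 100 * stats::sd(accs), folds = folds,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep <- rep[order(-rep$mean_accuracy, rep$sd_accuracy), ]
  rownames(rep) <- NULL
  structure(rep, fold_assignment = fold, seed = seed, scale = scale,
            class = c("cv_report", "data.frame"))
}

#' Default hyperparameter grids for the tuned benchmark
#'
#' SVM: cost x RBF gamma (NA = 1/d); KNN: neighbor count; RF: tree count x
#' depth cap; ANN: hidden size x weight decay; GP: kernel length-scale
#' multiplier. Models without a grid are kept at defaults with a note.
#'
#' @return Named list of parameter data frames.
#' @export
default_tuning_grids <- function() {
  list(
    SVM = expand.grid(cost = c(0.1, 1, 10, 100), gamma = c(NA, 1e-3, 1e-2)),
    KNN = data.frame(k = c(3L, 5L, 11L, 21L)),
    RF = expand.grid(ntree = c(100L, 300L, 600L), depth = c(Inf, 10, 20)),
    ANN = expand.grid(size = c(50L, 100L), decay = c(1e-4, 1e-3)),
    GP = data.frame(scale = c(0.5, 1, 2))
  )
}

#' Tune the top-k models from a cross-validation report
#'
#' Takes the `k` highest mean-accuracy models, grid-searches each over its
#' hyperparameter grid using the identical fold splits of the untuned
#' report, and reports before/after accuracies. The final model is the one
#' with the highest tuned mean accuracy (ties broken by lower standard
#' deviation), refit on all data with its best parameters.
#'
#' @inheritParams cross_validate_models
#' @param report A `cv_report` from [cross_validate_models()] on the same
#'   data.
#' @param k How many top models to tune.
#' @param grids Named list of parameter grids (see
#'   [default_tuning_grids()]); a model with no grid keeps its defaults.
#' @return Object of class `ed_tuning`: list with `table` (model,
#'   accuracy_before, accuracy_after, sd_after, params, note), `best_name`,
#'   `best_params` and `best_model` (an `ed_model` refit on all data).
#' @export
tune_top_models <- function(X, y, report, k = 5L,
                            grids = default_tuning_grids(),
                            seed = attr(report, "seed")) {
  stopifnot(inherits(report, "cv_report"), nrow(report) >= k)
  y <- .coerce_labels(y)
  fold <- attr(report, "fold_assignment")
  scale <- isTRUE(attr(report, "scale"))
  top <- utils::head(report[order(-report$mean_accuracy), ], k)

  rows <- list()
  params_by_model <- list()
  for (i in seq_len(nrow(top))) {
    m <- top$model[i]
    grid <- grids[[m]]
    if (is.null(grid) || nrow(grid) == 0L) {
      rows[[i]] <- data.frame(model = m, accuracy_before = top$mean_accuracy[i],
                              accuracy_after = top$mean_accuracy[i],
                              sd_after = top$sd_accuracy[i],
                              params = "", note = "no grid; defaults kept",
                              stringsAsFactors = FALSE)
      next
    }
    best_acc <- -Inf; best_sd <- Inf; best_params <- list()
    for (g in seq_len(nrow(grid))) {
      params <- as.list(grid[g, , drop = FALSE])
      accs <- .cv_accuracy(X, y, fold, m, params, seed, scale)
      acc <- 100 * mean(accs); sdv <- 100 * stats::sd(accs)
      if (acc > best_acc || (acc == best_acc && sdv < best_sd)) {
        best_acc <- acc; best_sd <- sdv; best_params <- params
      }
    }
    params_by_model[[m]] <- best_params
    rows[[i]] <- data.frame(
      model = m, accuracy_before = top$mean_accuracy[i],
      accuracy_after = best_acc, sd_after = best_sd,
      params = paste(names(best_params),
                     vapply(best_params, format, character(1L)),
                     sep = "=", collapse = ", "),
      note = "", stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  sel <- order(-tab$accuracy_after, tab$sd_after)[1L]
  best_name <- tab$model[sel]
  best_params <- params_by_model[[best_name]] %||% list()
  best_model <- fit_ed_model(X, y, best_name, best_params, seed = seed,
                             scale = scale)
  structure(list(table = tab, best_name = best_name,
                 best_params = best_params, best_model = best_model),
            class = "ed_tuning")
}

#' @export
print.ed_tuning <- function(x, ...) {
  cat("Hyperparameter tuning of top", nrow(x$table), "models\n")
  print.data.frame(x$table)
  cat("Selected:", x$best_name, "\n")
  invisible(x)
}

#' Fit a single ED classifier on all data
#'
#' @inheritParams cross_validate_models
#' @param model One of the ten benchmark model names.
#' @param params Named list of hyperparameters (defaults used where absent).
#' @param scale Standardize features (training statistics stored for
#'   prediction)?
#' @return Object of class `ed_model`.
#' @export
fit_ed_model <- function(X, y, model = "SVM", params = list(), seed = 1L,
                         scale = FALSE) {
  model <- match.arg(model, .model_names)
  y <- .coerce_labels(y)
  centers <- NULL; scales <- NULL
  if (scale) {
    centers <- colMeans(X); scales <- apply(X, 2L, stats::sd)
    scales[scales == 0] <- 1
    X <- sweep(sweep(X, 2L, centers), 2L, scales, "/")
  }
  set.seed(seed)
  fit <- .model_registry()[[model]]$fit(X, y, params)
  structure(list(name = model, params = params, fit = fit, d = ncol(X),
                 levels = levels(y), centers = centers, scales = scales,
                 seed = seed),
            class = "ed_model")
}

#' @export
print.ed_model <- function(x, ...) {
  cat("ED classifier:", x$name,
      if (length(x$params)) paste0("(",
        paste(names(x$params), unlist(lapply(x$params, format)),
              sep = "=", collapse = ", "), ")") else "(defaults)", "\n")
  invisible(x)
}

#' Predict ED classes for words from their embedding vectors
#'
#' Out-of-vocabulary words are skipped with a message. The numeric code
#' follows the 1 = L_ED, 2 = H_ED serialization.
#'
#' @param model An `ed_model` from [fit_ed_model()] or
#'   [tune_top_models()]`$best_model`.
#' @param words Character vector of words to label.
#' @param space An `embedding_space` holding their vectors.
#' @return Data frame with columns `word`, `ed_class`, `ed_code`.
#' @export
predict_ed <- function(model, words, space) {
  stopifnot(inherits(model, "ed_model"), inherits(space, "embedding_space"))
  X <- word_vectors(space, words, strict = FALSE)
  if (ncol(X) != model$d) stop("embedding dimension mismatch", call. = FALSE)
  if (nrow(X) == 0L) {
    return(data.frame(word = character(0L), ed_class = character(0L),
                      ed_code = integer(0L), stringsAsFactors = FALSE))
  }
  if (!is.null(model$centers)) {
    X <- sweep(sweep(X, 2L, model$centers), 2L, model$scales, "/")
  }
  pred <- .model_registry()[[model$name]]$predict(model$fit, X)
  pred <- factor(as.character(pred), levels = model$levels)
  data.frame(word = rownames(X), ed_class = as.character(pred),
             ed_code = as.integer(pred), stringsAsFactors = FALSE)
}
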