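# Gaussian mixture models over word vectors.
#
# EM with the four classic covariance families (full, tied, diag, spherical),
# AIC-based model selection over a (K, covariance) grid, and point-membership
# tests against the fitted components: either by posterior responsibility or
# by the chi-square p-mass ellipsoid (the "hyperellipse" view).
#
# Covariance matrices get a small ridge on the diagonal (`reg`); with
# hundreds of dimensions and a few thousand points a full covariance is
# singular without it.

.cov_types <- c("full", "tied", "diag", "spherical")

#' Free-parameter count of a Gaussian mixture
#'
#' `(K - 1)` mixing weights + `K * d` means + the covariance parameters:
#' `K * d * (d + 1) / 2` (full), `d * (d + 1) / 2` (tied), `K * d` (diag),
#' `K` (spherical).
#'
#' @param K Number of components (>= 1).
#' @param d Dimension (>= 1).
#' @param cov_type Covariance family.
#' @return Integer parameter count, as used in the AIC.
#' @export
count_params <- function(K, d, cov_type = .cov_types) {
  cov_type <- match.arg(cov_type)
  stopifnot(K >= 1L, d >= 1L)
  cov_terms <- switch(cov_type,
    full = K * d * (d + 1) / 2,
    tied = d * (d + 1) / 2,
    diag = K * d,
    spherical = K
  )
  as.integer((K - 1) + K * d + cov_terms)
}

# per-component log densities: n x K matrix of log N(x_i; mu_k, Sigma_k)
.log_component_density <- function(X, means, covs, cov_type) {
  n <- nrow(X); d <- ncol(X); K <- nrow(means)
  out <- matrix(0, n, K)
  cst <- -0.5 * d * log(2 * pi)
  if (cov_type %in% c("full", "tied")) {
    for (k in seq_len(K)) {
      S <- if (cov_type == "tied") covs else covs[[k]]
      R <- chol(S)                         # S = R'R
      logdet <- 2 * sum(log(diag(R)))
      Xc <- t(X) - means[k, ]
      z <- backsolve(R, Xc, transpose = TRUE)
      out[, k] <- cst - 0.5 * logdet - 0.5 * colSums(z^2)
    }
  } else if (cov_type == "diag") {
    for (k in seq_len(K)) {
      v <- covs[k, ]
      Xc <- sweep(X, 2L, means[k, ])
      out[, k] <- cst - 0.5 * sum(log(v)) -
        0.5 * rowSums(sweep(Xc^2, 2L, v, "/"))
    }
  } else {  # spherical
    for (k in seq_len(K)) {
      v <- covs[k]
      Xc <- sweep(X, 2L, means[k, ])
      out[, k] <- cst - 0.5 * d * log(v) - 0.5 * rowSums(Xc^2) / v
    }
  }
  out
}

.logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

# M-step covariance update for one family
.mstep_cov <- function(X, resp, means, Nk, cov_type, reg) {
  n <- nrow(X); d <- ncol(X); K <- ncol(resp)
  if (cov_type == "full") {
    lapply(seq_len(K), function(k) {
      Xc <- sweep(X, 2L, means[k, ])
      S <- crossprod(Xc * resp[, k], Xc) / Nk[k]
      S + diag(reg, d)
    })
  } else if (cov_type == "tied") {
    S <- matrix(0, d, d)
    for (k in seq_len(K)) {
      Xc <- sweep(X, 2L, means[k, ])
      S <- S + crossprod(Xc * resp[, k], Xc)
    }
    S / n + diag(reg, d)
  } else if (cov_type == "diag") {
    do.call(rbind, lapply(seq_len(K), function(k) {
      Xc <- sweep(X, 2L, means[k, ])
      colSums(Xc^2 * resp[, k]) / Nk[k] + reg
    }))
  } else {  # spherical
    vapply(seq_len(K), function(k) {
      Xc <- sweep(X, 2L, means[k, ])
      mean(colSums(Xc^2 * resp[, k]) / Nk[k]) + reg
    }, numeric(1L))
  }
}

#' Fit a Gaussian mixture model by EM
#'
#' K-means initialization (deterministic given `seed`), then EM until the
#' per-observation log-likelihood change drops below `tol` or `max_iter`
#' iterations. The reported `log_likelihood` is the observed-data
#' log-likelihood sum over rows of `log sum_k pi_k N(x; mu_k, Sigma_k)`.
#'
#' @param X Numeric matrix, n x d, with n > K.
#' @param K Number of components.
#' @param cov_type Covariance family: `"full"`, `"tied"`, `"diag"` or
#'   `"spherical"`.
#' @param seed Integer seed controlling initialization.
#' @param max_iter,tol EM stopping rule (`tol` is on the change in mean
#'   log-likelihood per observation).
#' @param reg Ridge added to covariance diagonals.
#' @return Object of class `food_gmm`: weights, means (K x d), covariances
#'   (representation depends on family), `log_likelihood`, `n_params`,
#'   `aic`, `converged`, `loglik_trace`, `seed`.
#' @export
fit_gmm <- function(X, K, cov_type = .cov_types, seed = 1L,
                    max_iter = 100L, tol = 1e-3, reg = 1e-6) {
  cov_type <- match.arg(cov_type)
  stopifnot(is.matrix(X), is.numeric(X))
  n <- nrow(X); d <- ncol(X)
  if (!(n > K && K >= 1L)) stop("need n > K >= 1 (n = ", n, ", K = ", K, ")",
                                call. = FALSE)

  set.seed(seed)
  if (K == 1L) {
    resp <- matrix(1, n, 1L)
  } else {
    km <- tryCatch(stats::kmeans(X, centers = K, nstart = 10L, iter.max = 50L),
                   error = function(e) NULL)
    assign <- if (is.null(km)) sample(rep_len(seq_len(K), n)) else km$cluster
    resp <- matrix(0, n, K)
    resp[cbind(seq_len(n), assign)] <- 1
  }

  ll_prev <- -Inf
  trace <- numeric(0L)
  converged <- FALSE
  weights <- means <- covs <- NULL
  for (iter in seq_len(max_iter)) {
    # M-step (tiny floor on Nk keeps an emptied component well-defined;
    # the covariance ridge keeps its matrix positive-definite)
    Nk <- colSums(resp) + 10 * .Machine$double.eps
    weights <- Nk / n
    means <- crossprod(resp, X) / Nk
    covs <- .mstep_cov(X, resp, means, Nk, cov_type, reg)

    # E-step
    logdens <- .log_component_density(X, means, covs, cov_type)
    logw <- sweep(logdens, 2L, log(weights), "+")
    lse <- .logsumexp_rows(logw)
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(logw - lse)

    if (is.finite(ll_prev) && abs(ll - ll_prev) / n < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
  }

  n_params <- count_params(K, d, cov_type)
  ll <- trace[length(trace)]
  structure(list(
    K = K, d = d, weights = as.vector(weights), means = means,
    covariances = covs, cov_type = cov_type,
    log_likelihood = ll, n_params = n_params,
    aic = 2 * n_params - 2 * ll,
    converged = converged, loglik_trace = trace,
    n_obs = n, seed = seed, reg = reg
  ), class = "food_gmm")
}

#' @export
print.food_gmm <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d, d = %d, covariance = %s\n",
              x$K, x$d, x$cov_type))
  cat(sprintf("  log-likelihood %.3f, %d parameters, AIC %.3f%s\n",
              x$log_likelihood, x$n_params, x$aic,
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' @export
logLik.food_gmm <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_params, class = "logLik")
}

#' Full covariance matrix of one component
#'
#' Expands the internal per-family representation to a d x d matrix.
#'
#' @param model A `food_gmm`.
#' @param k Component index.
#' @return d x d covariance matrix.
#' @export
component_covariance <- function(model, k) {
  stopifnot(inherits(model, "food_gmm"), k >= 1L, k <= model$K)
  switch(model$cov_type,
    full = model$covariances[[k]],
    tied = model$covariances,
    diag = diag(model$covariances[k, ], model$d),
    spherical = diag(model$covariances[k], model$d)
  )
}

#' Posterior responsibilities of the mixture components
#'
#' @param model A `food_gmm`.
#' @param X Numeric matrix (n x d) or a single vector of length d.
#' @return n x K matrix of responsibilities (rows sum to 1).
#' @export
responsibilities <- function(model, X) {
  stopifnot(inherits(model, "food_gmm"))
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$d) stop("dimension mismatch", call. = FALSE)
  logdens <- .log_component_density(X, model$means, model$covariances,
                                    model$cov_type)
  logw <- sweep(logdens, 2L, log(model$weights), "+")
  exp(logw - .logsumexp_rows(logw))
}

# squared Mahalanobis distances to every component: n x K
.mahalanobis_sq <- function(model, X) {
  n <- nrow(X); K <- model$K
  out <- matrix(0, n, K)
  for (k in seq_len(K)) {
    if (model$cov_type %in% c("full", "tied")) {
      S <- component_covariance(model, k)
      R <- chol(S)
      z <- backsolve(R, t(X) - model$means[k, ], transpose = TRUE)
      out[, k] <- colSums(z^2)
    } else {
      v <- if (model$cov_type == "diag") model$covariances[k, ]
           else rep(model$covariances[k], model$d)
      Xc <- sweep(X, 2L, model$means[k, ])
      out[, k] <- rowSums(sweep(Xc^2, 2L, v, "/"))
    }
  }
  out
}

#' Component membership at a probability level
#'
#' Two interpretations of a point lying "inside" a component's
#' hyperellipse at probability level `p`:
#' \describe{
#'   \item{posterior}{component k accepts x iff its responsibility
#'     `gamma_k(x) >= p`;}
#'   \item{quantile}{component k accepts x iff the squared Mahalanobis
#'     distance to its centroid is at most the chi-square `p`-quantile with
#'     d degrees of freedom — the ellipsoid holding probability mass `p`.}
#' }
#' A point is inside the mixture iff at least one component accepts it.
#'
#' @param model A `food_gmm`.
#' @param x Vector of length d, or an n x d matrix.
#' @param p Probability level in (0, 1).
#' @param mode `"posterior"` or `"quantile"`.
#' @return List with `accepted` (logical, n x K), `value` (the governing
#'   per-component value: responsibility or squared Mahalanobis distance)
#'   and `inside` (logical, length n). For vector input the matrices drop
#'   to vectors.
#' @export
membership <- function(model, x, p, mode = c("posterior", "quantile")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "food_gmm"))
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1) {
    stop("`p` must be a single value in (0, 1)", call. = FALSE)
  }
  single <- is.vector(x)
  if (single) x <- matrix(x, nrow = 1L)
  if (ncol(x) != model$d) stop("dimension mismatch", call. = FALSE)
  if (mode == "posterior") {
    value <- responsibilities(model, x)
    accepted <- value >= p
  } else {
    value <- .mahalanobis_sq(model, x)
    accepted <- value <= stats::qchisq(p, df = model$d)
  }
  inside <- rowSums(accepted) > 0
  if (single) {
    list(accepted = accepted[1L, ], value = value[1L, ], inside = inside[1L])
  } else {
    list(accepted = accepted, value = value, inside = inside)
  }
}

#' Grid-search mixtures over K and covariance family by AIC
#'
#' Fits every (K, covariance) pair and returns the minimum-AIC model
#' together with the full AIC table. An optional fine pass re-searches
#' `best K +/- refine_radius` in steps of 1 (the two-stage coarse-then-fine
#' protocol used for large K ranges).
#'
#' @param X Numeric matrix n x d.
#' @param K_grid Integer vector of component counts.
#' @param cov_types Covariance families to try.
#' @param seed Seed passed to every fit.
#' @param refine_radius Integer; 0 disables the fine pass.
#' @param ... Passed to [fit_gmm()].
#' @return Object of class `gmm_calibration`: list with `best` (a
#'   `food_gmm`) and `table` (K, cov_type, stage, log_likelihood, n_params,
#'   aic, converged).
#' @export
calibrate <- function(X, K_grid, cov_types = .cov_types, seed = 1L,
                      refine_radius = 0L, ...) {
  stopifnot(length(K_grid) >= 1L, length(cov_types) >= 1L)
  cov_types <- match.arg(cov_types, .cov_types, several.ok = TRUE)

  fit_grid <- function(Ks, stage) {
    rows <- list(); fits <- list()
    for (K in Ks) for (ct in cov_types) {
      fit <- tryCatch(fit_gmm(X, K, ct, seed = seed, ...),
                      error = function(e) e)
      if (inherits(fit, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          K = K, cov_type = ct, stage = stage, log_likelihood = NA_real_,
          n_params = count_params(K, ncol(X), ct), aic = NA_real_,
          converged = NA, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          K = K, cov_type = ct, stage = stage,
          log_likelihood = fit$log_likelihood, n_params = fit$n_params,
          aic = fit$aic, converged = fit$converged, stringsAsFactors = FALSE)
        fits[[paste(K, ct)]] <- fit
      }
    }
    list(table = do.call(rbind, rows), fits = fits)
  }

  coarse <- fit_grid(unique(as.integer(K_grid)), "coarse")
  tab <- coarse$table
  fits <- coarse$fits
  if (all(is.na(tab$aic))) stop("all mixture fits failed", call. = FALSE)

  if (refine_radius > 0L) {
    bestK <- tab$K[which.min(tab$aic)]
    fine_Ks <- setdiff(
      seq(max(1L, bestK - refine_radius), bestK + refine_radius),
      tab$K[!is.na(tab$aic)])
    fine_Ks <- fine_Ks[fine_Ks < nrow(X)]
    if (length(fine_Ks)) {
      fine <- fit_grid(fine_Ks, "fine")
      tab <- rbind(tab, fine$table)
      fits <- c(fits, fine$fits)
    }
  }

  best_row <- tab[which.min(tab$aic), ]
  best <- fits[[paste(best_row$K, best_row$cov_type)]]
  structure(list(best = best, table = tab), class = "gmm_calibration")
}

#' @export
print.gmm_calibration <- function(x, ...) {
  cat("GMM calibration over", nrow(x$table), "fits\n")
  cat("Selected:\n")
  print(x$best)
  invisible(x)
}

#' Serialize / deserialize a fitted mixture as JSON
#'
#' A portable plain-text archive of weights, means, covariances, covariance
#' family, seed and fit statistics.
#'
#' @param model A `food_gmm`.
#' @param path File path.
#' @return `write_gmm` returns `path` invisibly; `read_gmm` a `food_gmm`.
#' @export
write_gmm <- function(model, path) {
  stopifnot(inherits(model, "food_gmm"))
  # covariances flattened column-major for an unambiguous round-trip
  payload <- list(
    K = model$K, d = model$d, weights = model$weights,
    means = as.vector(model$means), cov_type = model$cov_type,
    covariances = switch(model$cov_type,
      full = lapply(model$covariances, as.vector),
      tied = as.vector(model$covariances),
      diag = as.vector(model$covariances),
      spherical = model$covariances),
    log_likelihood = model$log_likelihood, n_params = model$n_params,
    aic = model$aic, converged = model$converged, n_obs = model$n_obs,
    seed = model$seed, reg = model$reg
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gmm
#' @export
read_gmm <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  covs <- switch(p$cov_type,
    full = {
      cv <- p$covariances   # list of K vectors, or a K x d^2 matrix if
      if (is.matrix(cv)) {  # jsonlite simplified uniform-length rows
        lapply(seq_len(p$K), function(k) matrix(cv[k, ], p$d, p$d))
      } else {
        lapply(seq_len(p$K), function(k)
          matrix(as.numeric(unlist(cv[[k]])), p$d, p$d))
      }
    },
    tied = matrix(as.numeric(unlist(p$covariances)), p$d, p$d),
    diag = matrix(as.numeric(unlist(p$covariances)), p$K, p$d),
    spherical = as.numeric(unlist(p$covariances))
  )
  structure(list(
    K = p$K, d = p$d, weights = as.numeric(p$weights),
    means = matrix(as.numeric(unlist(p$means)), p$K, p$d),
    covariances = covs, cov_type = p$cov_type,
    log_likelihood = p$log_likelihood, n_params = p$n_params,
    aic = p$aic, converged = p$converged,
    loglik_trace = numeric(0L), n_obs = p$n_obs, seed = p$seed, reg = p$reg
  ), class = "food_gmm")
}
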