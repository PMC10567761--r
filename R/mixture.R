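# Gaussian mixture fitting (EM and variational Bayes) in d dimensions.
# The principal (largest-weight) component is interpreted as the healthy
# subpopulation; the complement weight is the pathological/outlier fraction.

#' Construct a Gaussian mixture component
#'
#' @param weight mixing weight in `[0, 1]`.
#' @param mean numeric mean vector (length d).
#' @param cov d x d symmetric positive-definite covariance matrix. A scalar
#'   is accepted for d = 1.
#' @return An object of class `gaussian_component`.
#' @export
gaussian_component <- function(weight, mean, cov) {
  mean <- as.numeric(mean)
  d <- length(mean)
  cov <- as.matrix(cov)
  if (!is.numeric(weight) || length(weight) != 1L || weight < 0 || weight > 1)
    stop("'weight' must be a single number in [0, 1]")
  if (!all(dim(cov) == c(d, d)))
    stop("'cov' must be a ", d, "x", d, " matrix")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("'cov' must be symmetric")
  cov <- (cov + t(cov)) / 2
  if (any(eigen(cov, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("'cov' must be positive definite")
  structure(list(weight = weight, mean = mean, cov = cov, d = d),
            class = "gaussian_component")
}

#' @export
print.gaussian_component <- function(x, ...) {
  cat(sprintf("Gaussian component (d = %d), weight = %.4f\n", x$d, x$weight))
  cat("  mean:", paste(signif(x$mean, 6), collapse = ", "), "\n")
  cat("  cov :", paste(signif(x$cov, 6), collapse = ", "), "\n")
  invisible(x)
}

# log N(x | mu, Sigma) for each row of x (n x d), via Cholesky
.log_dmvnorm <- function(x, mu, sigma) {
  d <- ncol(x)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) { # fall back: symmetrize + jitter
    sigma <- (sigma + t(sigma)) / 2 + diag(1e-10 * mean(diag(sigma)), d)
    ch <- chol(sigma)
  }
  logdet <- 2 * sum(log(diag(ch)))
  z <- backsolve(ch, t(x) - mu, transpose = TRUE) # d x n
  maha <- colSums(z^2)
  -0.5 * (d * log(2 * pi) + logdet + maha)
}

.as_value_matrix <- function(values) {
  x <- if (is.matrix(values)) values else matrix(as.numeric(values), ncol = 1)
  storage.mode(x) <- "double"
  x
}

# Initialization schedule. 1D, K = 2: the first restarts are deterministic
# quantile splits at the median, the 90th and the 97.5th percentile — the
# tail-oriented splits matter because on segments with little contamination
# (outlier weight of a few percent) a median split converges to a local
# optimum that halves the healthy bulk instead of isolating the tail.
# Other cases: equal-count quantile split (1D) / k-means++ centers (d >= 2)
# first, then random restarts.
.init_assign <- function(x, K, restart, seed) {
  n <- nrow(x)
  if (K == 1L) return(rep(1L, n))
  if (ncol(x) == 1L && K == 2L && restart <= 3L) {
    split_q <- c(0.5, 0.9, 0.975)[restart]
    return(ifelse(rank(x[, 1], ties.method = "first") <= split_q * n, 1L, 2L))
  }
  if (restart == 1L) {
    if (ncol(x) == 1L) {
      # equal-count quantile split; rank-based so ties cannot empty a bin
      return(as.integer(cut(rank(x[, 1], ties.method = "first"), K,
                            labels = FALSE)))
    }
    centers <- .kmeanspp_centers(x, K)
  } else {
    centers <- x[sample.int(n, K), , drop = FALSE]
  }
  d2 <- sapply(seq_len(K), function(k) rowSums((x - rep(centers[k, ], each = n))^2))
  max.col(-d2, ties.method = "first")
}

.kmeanspp_centers <- function(x, K) {
  n <- nrow(x)
  centers <- matrix(NA_real_, K, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  if (K > 1) {
    d2 <- rowSums((x - rep(centers[1, ], each = n))^2)
    for (k in 2:K) {
      p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[k, ] <- x[sample.int(n, 1, prob = p), ]
      d2 <- pmin(d2, rowSums((x - rep(centers[k, ], each = n))^2))
    }
  }
  centers
}

.row_max <- function(m) {
  out <- m[, 1]
  for (k in seq_len(ncol(m))[-1]) out <- pmax(out, m[, k])
  out
}

# One EM run from a hard assignment; returns NULL if the starting partition
# is degenerate. If a component empties out mid-run (the data do not support
# K components), the last valid iterate is returned as a non-converged fit.
.em_run <- function(x, K, z0, tol, max_iter, reg) {
  n <- nrow(x); d <- ncol(x)
  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), z0)] <- 1
  ll_old <- -Inf
  trace <- numeric(0)
  weights <- numeric(K); means <- matrix(0, K, d)
  covs <- vector("list", K)
  prev <- NULL
  for (iter in seq_len(max_iter)) {
    # M-step
    nk <- colSums(resp)
    if (any(nk < d + 1e-8)) { # emptied component
      if (is.null(prev)) return(NULL)
      return(c(prev, list(loglik = ll_old * n, loglik_trace = trace,
                          n_iter = iter - 1L, converged = FALSE)))
    }
    weights <- nk / n
    means <- crossprod(resp, x) / nk
    for (k in seq_len(K)) {
      xc <- x - rep(means[k, ], each = n)
      covs[[k]] <- crossprod(xc * resp[, k], xc) / nk[k] + diag(reg, d)
      covs[[k]] <- (covs[[k]] + t(covs[[k]])) / 2
    }
    # E-step
    logp <- matrix(0, n, K)
    for (k in seq_len(K))
      logp[, k] <- log(weights[k]) + .log_dmvnorm(x, means[k, ], covs[[k]])
    m <- .row_max(logp)
    lse <- m + log(rowSums(exp(logp - m)))
    ll <- mean(lse)
    trace <- c(trace, ll)
    resp <- exp(logp - lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      return(list(weights = weights, means = means, covs = covs,
                  loglik = ll * n, loglik_trace = trace, n_iter = iter,
                  converged = TRUE))
    }
    ll_old <- ll
    prev <- list(weights = weights, means = means, covs = covs)
  }
  list(weights = weights, means = means, covs = covs, loglik = ll_old * n,
       loglik_trace = trace, n_iter = max_iter, converged = FALSE)
}

#' Fit a Gaussian mixture model
#'
#' Fits a K-component Gaussian mixture to 1D or multivariate data, either by
#' maximum-likelihood expectation-maximization (`method = "em"`) or by
#' variational Bayes with a Dirichlet weight-concentration prior
#' (`method = "variational"`). The best of `n_init` restarts (by final
#' log-likelihood) is returned. Covariances are regularized by adding `reg`
#' to every diagonal element at each M-step, which keeps them positive
#' definite even on near-degenerate segments.
#'
#' @param values numeric vector (d = 1) or n x d numeric matrix.
#' @param K number of components (default 2: one healthy, one pathological).
#' @param method `"em"` (canonical) or `"variational"`.
#' @param seed integer seed controlling initialization; restarts use
#'   `seed`, `seed + 1`, ....
#' @param tol convergence tolerance on the change in mean per-point
#'   log-likelihood (EM) or its variational analogue.
#' @param max_iter maximum iterations per restart.
#' @param reg covariance diagonal floor; default `1e-6` times the mean
#'   per-dimension sample variance.
#' @param n_init number of restarts. For 1D K = 2 the first three are
#'   deterministic quantile splits (median, 90th, 97.5th percentile — the
#'   tail splits protect low-contamination segments from bulk-splitting
#'   local optima); otherwise an equal-count quantile split (1D) or
#'   k-means++ seeding (d >= 2) comes first. Remaining restarts are random.
#' @return An object of class `mixture_model` with elements `components`
#'   (list of [gaussian_component()]), `log_likelihood`, `loglik_trace`,
#'   `n_iter`, `converged`, `method`, `seed`, `K`, `d`, `n`.
#' @examples
#' x <- c(rnorm(500, 1, 0.15), rnorm(60, 1.8, 0.5))
#' m <- fit_mixture(x, K = 2, seed = 1)
#' outlier_fraction(m)
#' @export
fit_mixture <- function(values, K = 2L, method = c("em", "variational"),
                        seed = 1L, tol = 1e-6, max_iter = 500L, reg = NULL,
                        n_init = 5L) {
  method <- match.arg(method)
  x <- .as_value_matrix(values)
  if (!all(is.finite(x))) stop("non-finite values in input")
  n <- nrow(x); d <- ncol(x)
  K <- as.integer(K)
  if (n < K * (d + 1)) stop("insufficient data: need at least K*(d+1) points")
  if (is.null(reg)) {
    reg <- 1e-6 * mean(apply(x, 2, stats::var))
    # constant data: fall back to a tiny absolute floor
    if (reg <= 0) reg <- 1e-12 * (1 + mean(x^2))
  }
  if (!is.finite(reg) || reg < 0) stop("'reg' must be a non-negative number")

  best <- NULL
  for (i in seq_len(n_init)) {
    if (!is.null(seed)) set.seed(as.integer(seed) + i - 1L)
    z0 <- .init_assign(x, K, restart = i, seed = seed)
    fit <- if (method == "em") {
      .em_run(x, K, z0, tol, max_iter, reg)
    } else {
      .vb_run(x, K, z0, tol, max_iter, reg)
    }
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best)) stop("all mixture restarts failed (degenerate data?)")

  comps <- lapply(seq_len(K), function(k)
    gaussian_component(best$weights[k], best$means[k, ], best$covs[[k]]))
  structure(list(components = comps,
                 log_likelihood = best$loglik,
                 loglik_trace = best$loglik_trace,
                 n_iter = best$n_iter,
                 converged = best$converged,
                 method = method, seed = seed, K = K, d = d, n = n),
            class = "mixture_model")
}

#' @export
print.mixture_model <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d, d = %d, n = %d, method = %s\n",
              x$K, x$d, x$n, x$method))
  cat(sprintf("  log-likelihood = %.4f (%d iterations, converged = %s)\n",
              x$log_likelihood, x$n_iter, x$converged))
  for (k in seq_len(x$K)) {
    cmp <- x$components[[k]]
    cat(sprintf("  [%d] weight %.4f  mean %s  sd/cov %s\n", k, cmp$weight,
                paste(signif(cmp$mean, 5), collapse = ", "),
                paste(signif(cmp$cov, 5), collapse = ", ")))
  }
  invisible(x)
}

# Variational Bayes GMM (Dirichlet-Normal-Wishart conjugate model).
# Priors: weight concentration alpha0 = 1/K, beta0 = 1, m0 = data mean,
# nu0 = d, E[Lambda] matched to the inverse data covariance.
.vb_run <- function(x, K, z0, tol, max_iter, reg) {
  n <- nrow(x); d <- ncol(x)
  alpha0 <- 1 / K
  beta0 <- 1
  m0 <- colMeans(x)
  S <- stats::cov(x) + diag(reg, d)
  nu0 <- d
  W0inv <- S * nu0            # so E[Lambda] = nu0 * W0 = S^{-1}

  resp <- matrix(0, n, K)
  resp[cbind(seq_len(n), z0)] <- 1
  bound_old <- -Inf
  trace <- numeric(0)
  alpha <- beta <- nu <- numeric(K)
  m <- matrix(0, K, d); Winv <- vector("list", K)

  for (iter in seq_len(max_iter)) {
    nk <- colSums(resp) + 1e-10
    xbar <- crossprod(resp, x) / nk
    alpha <- alpha0 + nk
    beta <- beta0 + nk
    nu <- nu0 + nk
    for (k in seq_len(K)) {
      m[k, ] <- (beta0 * m0 + nk[k] * xbar[k, ]) / beta[k]
      xc <- x - rep(xbar[k, ], each = n)
      Sk <- crossprod(xc * resp[, k], xc) / nk[k]
      dm <- xbar[k, ] - m0
      Winv[[k]] <- W0inv + nk[k] * Sk +
        (beta0 * nk[k] / beta[k]) * tcrossprod(dm) + diag(reg, d)
    }
    # variational E-step
    eln_pi <- digamma(alpha) - digamma(sum(alpha))
    logr <- matrix(0, n, K)
    for (k in seq_len(K)) {
      Wk <- chol2inv(chol(Winv[[k]]))
      eln_lam <- sum(digamma((nu[k] + 1 - seq_len(d)) / 2)) + d * log(2) -
        determinant(Winv[[k]], logarithm = TRUE)$modulus[1]
      xc <- t(x) - m[k, ]
      maha <- colSums((Wk %*% xc) * xc)
      logr[, k] <- eln_pi[k] + 0.5 * eln_lam - d / (2 * beta[k]) -
        0.5 * nu[k] * maha - d / 2 * log(2 * pi)
    }
    mrow <- .row_max(logr)
    lse <- mrow + log(rowSums(exp(logr - mrow)))
    bound <- mean(lse)
    trace <- c(trace, bound)
    resp <- exp(logr - lse)
    if (is.finite(bound_old) && abs(bound - bound_old) < tol) break
    bound_old <- bound
  }

  weights <- alpha / sum(alpha)
  covs <- lapply(seq_len(K), function(k) {
    cv <- Winv[[k]] / nu[k]            # expected-precision point estimate
    (cv + t(cv)) / 2
  })
  # report observed-data log-likelihood at the point estimates
  logp <- sapply(seq_len(K), function(k)
    log(weights[k]) + .log_dmvnorm(x, m[k, ], covs[[k]]))
  logp <- matrix(logp, n, K)
  mm <- .row_max(logp)
  ll <- sum(mm + log(rowSums(exp(logp - mm))))
  list(weights = weights, means = m, covs = covs, loglik = ll,
       loglik_trace = trace, n_iter = length(trace),
       converged = length(trace) < max_iter)
}

#' Select the principal (healthy) component of a mixture
#'
#' The principal Gaussian is interpreted as the healthy subpopulation. The
#' default rule picks the component with the largest weight; exact ties are
#' broken toward the smaller generalized variance (determinant of the
#' covariance). An alternative rule picks the component whose mean is nearest
#' the sample median supplied via `center`.
#'
#' @param model a `mixture_model`.
#' @param rule `"weight"` (default) or `"center"`.
#' @param center numeric vector (required for `rule = "center"`), typically
#'   the coordinate-wise sample median.
#' @return integer index of the principal component.
#' @export
select_principal <- function(model, rule = c("weight", "center"),
                             center = NULL) {
  stopifnot(inherits(model, "mixture_model"), model$K >= 1)
  rule <- match.arg(rule)
  if (rule == "center") {
    if (is.null(center)) stop("'center' required for rule = \"center\"")
    d2 <- vapply(model$components,
                 function(c) sum((c$mean - center)^2), numeric(1))
    return(which.min(d2))
  }
  w <- vapply(model$components, `[[`, numeric(1), "weight")
  top <- which(w >= max(w) - 1e-12)
  if (length(top) == 1L) return(top)
  dets <- vapply(model$components[top], function(c) det(c$cov), numeric(1))
  top[which.min(dets)]
}

#' Pathological (outlier) fraction of a mixture
#'
#' Returns one minus the principal component's weight: the estimated
#' proportion of results not attributable to the healthy subpopulation.
#'
#' @inheritParams select_principal
#' @param principal optional pre-selected principal index.
#' @return fraction in `[0, 1]`.
#' @export
outlier_fraction <- function(model, principal = NULL) {
  stopifnot(inherits(model, "mixture_model"))
  if (is.null(principal)) principal <- select_principal(model)
  1 - model$components[[principal]]$weight
}

#' Serialize a mixture model to JSON
#'
#' Weights, means and covariances (row-major), method, seed and fit
#' diagnostics, suitable for archiving alongside pipeline outputs.
#'
#' @param model a `mixture_model`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
mixture_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "mixture_model"))
  obj <- list(
    K = model$K, d = model$d, n = model$n, method = model$method,
    seed = model$seed, log_likelihood = model$log_likelihood,
    n_iter = model$n_iter, converged = model$converged,
    components = lapply(model$components, function(c) list(
      weight = c$weight, mean = c$mean, cov = as.numeric(t(c$cov)))))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Deserialize a mixture model from JSON
#'
#' @param json JSON string or path to a file written by [mixture_to_json()].
#' @return a `mixture_model`.
#' @export
mixture_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  comps <- lapply(obj$components, function(c)
    gaussian_component(c$weight, unlist(c$mean),
                       matrix(unlist(c$cov), obj$d, obj$d, byrow = TRUE)))
  structure(list(components = comps, log_likelihood = obj$log_likelihood,
                 loglik_trace = NULL, n_iter = obj$n_iter,
                 converged = obj$converged, method = obj$method,
                 seed = obj$seed, K = obj$K, d = obj$d, n = obj$n),
            class = "mixture_model")
}
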