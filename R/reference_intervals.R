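# Reference intervals from the principal Gaussian of per-segment mixtures,
# bootstrap uncertainty, and polynomial age trends of the interval limits.

#' Estimation configuration
#'
#' Bundles the tunable parameters shared by the per-segment estimation
#' pipeline: mixture fitting, principal-component selection, interval
#' coverage, segment reliability and bootstrap settings.
#'
#' @param K mixture components (default 2).
#' @param method `"em"` or `"variational"`.
#' @param n_init mixture restarts.
#' @param tol,max_iter,reg passed to [fit_mixture()].
#' @param coverage central probability mass of the reference interval.
#' @param min_n minimum segment size; smaller segments are flagged, not
#'   estimated.
#' @param bin_width age bin width in years.
#' @param seed base seed for mixture initialization.
#' @param bootstrap logical: attach bootstrap standard errors in [ri_table()].
#' @param B,frac bootstrap replicates and subsample fraction.
#' @return list of class `ri_config`.
#' @export
ri_config <- function(K = 2L, method = "em", n_init = 5L, tol = 1e-6,
                      max_iter = 500L, reg = NULL, coverage = 0.95,
                      min_n = 120L, bin_width = 1L, seed = 1L,
                      bootstrap = FALSE, B = 100L, frac = 0.5) {
  stopifnot(coverage > 0, coverage < 1, min_n >= 1, B >= 2,
            frac > 0, frac <= 1)
  structure(list(K = K, method = method, n_init = n_init, tol = tol,
                 max_iter = max_iter, reg = reg, coverage = coverage,
                 min_n = min_n, bin_width = bin_width, seed = seed,
                 bootstrap = bootstrap, B = B, frac = frac),
            class = "ri_config")
}

#' Reference interval from a 1D Gaussian component
#'
#' The low and high limits are the `(1 - coverage)/2` and `(1 + coverage)/2`
#' quantiles of `N(mu, sigma^2)`, i.e. `mu +/- z * sigma` with `z` the
#' standard-normal quantile. With the default coverage 0.95 these are the
#' 2.5th and 97.5th percentiles of the healthy distribution.
#'
#' @param comp a 1D [gaussian_component()].
#' @param coverage central probability mass in (0, 1).
#' @return named numeric vector `c(low, high)`.
#' @examples
#' ri_from_component(gaussian_component(1, 0.9, 0.15^2))
#' @export
ri_from_component <- function(comp, coverage = 0.95) {
  stopifnot(inherits(comp, "gaussian_component"), comp$d == 1L,
            coverage > 0, coverage < 1)
  z <- stats::qnorm((1 + coverage) / 2)
  s <- sqrt(comp$cov[1, 1])
  c(low = comp$mean - z * s, high = comp$mean + z * s)
}

#' Estimate a reference interval for one segment
#'
#' The per-segment pipeline: fit a K-component mixture, select the principal
#' (healthy) Gaussian, and take its central-coverage quantiles as the
#' interval. Segments with fewer than `min_n` values are flagged unreliable
#' and produce no estimate.
#'
#' @param values numeric vector of (already filtered) readings.
#' @param config an [ri_config()].
#' @return list with `low`, `high`, `n`, `outlier_fraction`, `unreliable`,
#'   `model` (the fitted `mixture_model`, or `NULL` when flagged).
#' @export
estimate_ri_segment <- function(values, config = ri_config()) {
  n <- length(values)
  if (n < config$min_n)
    return(list(low = NA_real_, high = NA_real_, n = n,
                outlier_fraction = NA_real_, unreliable = TRUE, model = NULL))
  model <- fit_mixture(values, K = config$K, method = config$method,
                       seed = config$seed, tol = config$tol,
                       max_iter = config$max_iter, reg = config$reg,
                       n_init = config$n_init)
  p <- select_principal(model)
  ri <- ri_from_component(model$components[[p]], config$coverage)
  list(low = unname(ri["low"]), high = unname(ri["high"]), n = n,
       outlier_fraction = outlier_fraction(model, p), unreliable = FALSE,
       model = model)
}

#' Reference-interval table over all gender/age segments
#'
#' Segments a filtered single- or multi-analyte result table by gender and
#' age and estimates a reference interval in every reliable segment. The
#' result is deterministic for a fixed `config$seed`.
#'
#' @param table filtered result table.
#' @param config an [ri_config()]; with `config$bootstrap = TRUE` the columns
#'   `low_se`/`high_se` carry bootstrap standard errors (see
#'   [bootstrap_ri()]), otherwise they are `NA`.
#' @return data.frame: analyte, gender, age, n, low, high, low_se, high_se,
#'   outlier_fraction, unreliable (one row per analyte x segment).
#' @export
ri_table <- function(table, config = ri_config()) {
  rows <- list()
  for (analyte in sort(unique(table$analyte))) {
    sub <- table[table$analyte == analyte, , drop = FALSE]
    seg <- segment_by_gender_age(sub, bin_width = config$bin_width,
                                 min_n = config$min_n)
    for (i in seq_len(nrow(seg$info))) {
      vals <- seg$segments[[i]]
      est <- estimate_ri_segment(vals, config)
      lse <- hse <- NA_real_
      if (config$bootstrap && !est$unreliable) {
        bs <- bootstrap_ri(vals, B = config$B, frac = config$frac,
                           seed = config$seed, config = config)
        lse <- bs$sd["low"]; hse <- bs$sd["high"]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        analyte = analyte, gender = seg$info$gender[i],
        age = seg$info$age[i], n = est$n, low = est$low, high = est$high,
        low_se = unname(lse), high_se = unname(hse),
        outlier_fraction = est$outlier_fraction,
        unreliable = est$unreliable, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bootstrap uncertainty of the reference-interval limits
#'
#' Draws `B` subsamples of size `floor(frac * n)` with replacement, re-runs
#' the full per-segment estimate on each, and summarizes each limit by the
#' mean and standard deviation across replicates. Defaults follow the
#' convention of 100 samples of half the dataset size; the reported interval
#' is the replicate mean and its error the replicate standard deviation.
#'
#' @param values numeric vector of readings.
#' @param B number of bootstrap replicates.
#' @param frac subsample fraction of `length(values)`.
#' @param seed RNG seed for the resampling.
#' @param config an [ri_config()] driving each replicate's fit; `min_n` is
#'   applied to the subsample size.
#' @return list with `mean` and `sd` (each `c(low, high)`), `B_used`, and
#'   `failed` (replicates dropped). More than 20% failed replicates is an
#'   error.
#' @export
bootstrap_ri <- function(values, B = 100L, frac = 0.5, seed = 1L,
                         config = ri_config()) {
  stopifnot(B >= 2, frac > 0, frac <= 1)
  n <- length(values)
  m <- max(1L, floor(frac * n))
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(n, m * B, replace = TRUE), nrow = m)
  lows <- highs <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    est <- tryCatch(estimate_ri_segment(values[idx[, b]], config),
                    error = function(e) NULL)
    if (!is.null(est) && !est$unreliable) {
      lows[b] <- est$low; highs[b] <- est$high
    }
  }
  ok <- is.finite(lows) & is.finite(highs)
  if (sum(!ok) > 0.2 * B)
    stop("more than 20% of bootstrap replicates failed (",
         sum(!ok), " of ", B, ")")
  list(mean = c(low = mean(lows[ok]), high = mean(highs[ok])),
       sd = c(low = stats::sd(lows[ok]), high = stats::sd(highs[ok])),
       B_used = sum(ok), failed = sum(!ok))
}

.fit_poly_trend <- function(series, degree, age_range, analyte = NA_character_,
                            gender = NA_character_, limit = NA_character_) {
  stopifnot(is.data.frame(series), all(c("age", "limit") %in% names(series)))
  s <- series[is.finite(series$limit), , drop = FALSE]
  if (!is.null(age_range))
    s <- s[s$age >= age_range[1] & s$age <= age_range[2], , drop = FALSE]
  min_pts <- degree + 2L
  if (nrow(s) < min_pts)
    stop("need at least ", min_pts, " points within the age range")
  if (stats::var(s$limit) == 0) {
    warning("constant series: trend is flat, R-squared reported as 0")
    coefs <- c(s$limit[1], rep(0, degree))
    return(structure(list(analyte = analyte, gender = gender, limit = limit,
                          degree = degree, coefficients = coefs,
                          r_squared = 0, p_values = rep(NA_real_, degree + 1),
                          age_range = range(s$age)), class = "age_trend"))
  }
  fit <- stats::lm(limit ~ stats::poly(age, degree, raw = TRUE), data = s)
  # noiseless series are a legitimate input (coefficient recovery); silence
  # only summary.lm's perfect-fit caveat about its (unused-here) inference
  sm <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
  structure(list(analyte = analyte, gender = gender, limit = limit,
                 degree = degree,
                 coefficients = unname(stats::coef(fit)),
                 r_squared = sm$r.squared,
                 p_values = unname(sm$coefficients[, 4]),
                 age_range = range(s$age), fit = fit),
            class = "age_trend")
}

#' Linear age trend of a reference-interval limit
#'
#' Ordinary least squares of a limit-versus-age series restricted to
#' `age_range`. Over adult ages the high limits of creatinine (20-60) and
#' urea (20-50) are close to linear; the slope quantifies the average annual
#' widening of the interval.
#'
#' @param series data.frame with columns `age` and `limit` (mg/dl).
#' @param age_range numeric `c(min, max)` in years, or `NULL` for all ages.
#' @param analyte,gender,limit optional labels stored in the result.
#' @return object of class `age_trend`: `coefficients` in ascending order
#'   (intercept, slope, ...), `r_squared`, per-coefficient `p_values`,
#'   `degree`, `age_range`.
#' @export
fit_linear_trend <- function(series, age_range = NULL,
                             analyte = NA_character_, gender = NA_character_,
                             limit = NA_character_) {
  .fit_poly_trend(series, 1L, age_range, analyte, gender, limit)
}

#' Cubic age trend of a reference-interval limit
#'
#' Degree-3 least squares, capturing the accelerating widening of the
#' interval in the elderly (> 60 years) that a linear trend misses.
#'
#' @inheritParams fit_linear_trend
#' @export
fit_cubic_trend <- function(series, age_range = NULL,
                            analyte = NA_character_, gender = NA_character_,
                            limit = NA_character_) {
  .fit_poly_trend(series, 3L, age_range, analyte, gender, limit)
}

#' @export
print.age_trend <- function(x, ...) {
  cat(sprintf("Age trend (degree %d) %s %s %s limit, ages %s-%s\n",
              x$degree, x$analyte, x$gender, x$limit,
              x$age_range[1], x$age_range[2]))
  cat("  coefficients (ascending):",
      paste(signif(x$coefficients, 6), collapse = ", "), "\n")
  cat(sprintf("  R-squared = %.4f\n", x$r_squared))
  invisible(x)
}

#' Evaluate an age trend at given ages
#' @param trend an `age_trend`.
#' @param age numeric vector of ages (years).
#' @return predicted limit values (mg/dl).
#' @export
predict_trend <- function(trend, age) {
  stopifnot(inherits(trend, "age_trend"))
  drop(outer(age, seq_along(trend$coefficients) - 1, `^`) %*%
         trend$coefficients)
}

#' Annual deterioration rate implied by a linear limit trend
#'
#' Converts the slope of a linear high-limit trend into a relative annual
#' change, anchored at the predicted limit at `ref_age`:
#' `100 * slope / (intercept + ref_age * slope)` percent per year. With the
#' default anchor at age 20 this reads as the fraction of young-adult organ
#' capacity lost per year.
#'
#' @param trend a degree-1 `age_trend`.
#' @param ref_age anchor age in years (default 20).
#' @return percent per year (numeric scalar).
#' @export
annual_deterioration_rate <- function(trend, ref_age = 20) {
  stopifnot(inherits(trend, "age_trend"))
  if (trend$degree != 1L) stop("trend must be linear (degree 1)")
  intercept <- trend$coefficients[1]
  slope <- trend$coefficients[2]
  anchor <- intercept + ref_age * slope
  if (anchor <= 0) stop("predicted limit at ref_age is non-positive")
  100 * slope / anchor
}

#' Serialize age trends to a JSON report
#'
#' @param trends list of `age_trend` objects.
#' @param path optional output path.
#' @return JSON string (invisibly if written).
#' @export
trends_to_json <- function(trends, path = NULL) {
  obj <- lapply(trends, function(t) list(
    analyte = t$analyte, gender = t$gender, limit = t$limit,
    degree = t$degree, coefficients = t$coefficients,
    r_squared = t$r_squared, p_values = t$p_values,
    age_range = t$age_range))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
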