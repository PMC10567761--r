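# Continuous abnormal flags: the highest-density-region percentile of a
# reading under the segment's principal Gaussian, backed by a persisted
# population model keyed by (analyte set, gender, age).

#' Highest-density-region percentile of a reading
#'
#' The continuous generalization of the binary abnormal flag: the probability
#' mass of the region where the density exceeds the density at `x`,
#' `P(f(X) >= f(x))` for `X ~ N(mu, Sigma)`. It is 0 at the distribution
#' center and approaches 1 far out. In closed form this is the chi-square(d)
#' CDF of the squared Mahalanobis distance; for d = 1 it reduces to
#' `2 * pnorm(|x - mu| / sigma) - 1`, so a reading exactly at a 95% reference
#' limit scores 0.95.
#'
#' @param comp a [gaussian_component()].
#' @param x numeric vector of length `comp$d` (a single reading).
#' @return percentile in `[0, 1)`.
#' @examples
#' cmp <- gaussian_component(1, 1.0, 0.15^2)
#' hdr_percentile(cmp, 1.0)                    # 0 at the mean
#' hdr_percentile(cmp, 1.0 + 1.959964 * 0.15)  # 0.95 at the RI limit
#' @export
hdr_percentile <- function(comp, x) {
  stopifnot(inherits(comp, "gaussian_component"))
  x <- as.numeric(x)
  if (length(x) != comp$d)
    stop("reading has dimension ", length(x), ", component has ", comp$d)
  maha <- stats::mahalanobis(matrix(x, nrow = 1), comp$mean, comp$cov)
  unname(stats::pchisq(maha, df = comp$d))
}

.pm_key <- function(analytes, gender, age) {
  paste(paste(sort(analytes), collapse = "+"), gender, age, sep = "|")
}

#' Build a population model from routine results
#'
#' Fits, for every gender/age segment, a per-analyte 1D mixture and (when the
#' table carries two or more analytes) a joint multivariate mixture on the
#' readings paired by person and date. The principal component, outlier
#' fraction and sample size of each reliable segment are stored; unreliable
#' segments (n below `config$min_n`) are explicit gaps. Together with
#' [predict.population_model()] this is the "augmented model": a reading is
#' scored against the healthy distribution of its own gender/age segment.
#'
#' @param table filtered long-format result table (one or more analytes).
#' @param config an [ri_config()].
#' @return object of class `population_model`: `entries` (named list keyed
#'   `"analyteset|gender|age"`), `analytes`, `meta`.
#' @export
build_population_model <- function(table, config = ri_config()) {
  analytes <- sort(unique(table$analyte))
  entries <- list()
  add_entry <- function(anset, gender, age, values) {
    x <- .as_value_matrix(values)
    key <- .pm_key(anset, gender, age)
    if (nrow(x) < config$min_n) {
      entries[[key]] <<- list(analytes = anset, gender = gender, age = age,
                              n = nrow(x), unreliable = TRUE)
      return(invisible())
    }
    model <- fit_mixture(x, K = config$K, method = config$method,
                         seed = config$seed, tol = config$tol,
                         max_iter = config$max_iter, reg = config$reg,
                         n_init = config$n_init)
    p <- select_principal(model)
    entries[[key]] <<- list(analytes = anset, gender = gender, age = age,
                            n = nrow(x), unreliable = FALSE,
                            component = model$components[[p]],
                            outlier_fraction = outlier_fraction(model, p))
  }
  # 1D entries per analyte
  for (a in analytes) {
    sub <- table[table$analyte == a, , drop = FALSE]
    seg <- segment_by_gender_age(sub, bin_width = config$bin_width,
                                 min_n = config$min_n)
    for (i in seq_len(nrow(seg$info)))
      add_entry(a, seg$info$gender[i], seg$info$age[i], seg$segments[[i]])
  }
  # joint entry for the full panel (readings paired by person and date)
  if (length(analytes) >= 2) {
    tabs <- lapply(analytes, function(a)
      table[table$analyte == a, , drop = FALSE])
    joint <- join_analytes(tabs[[1]], tabs[[2]])
    if (length(analytes) > 2) {
      for (a in analytes[-(1:2)]) {
        t3 <- tabs[[match(a, analytes)]]
        t3 <- t3[!duplicated(paste(t3$person_id, t3$date, sep = "\r")), ]
        t3 <- t3[c("person_id", "date", "value")]
        names(t3)[3] <- paste0("value_", a)
        joint <- merge(joint, t3, by = c("person_id", "date"))
      }
    }
    vcols <- paste0("value_", analytes)
    key <- paste(joint$gender, joint$age, sep = "|")
    for (k in unique(key)) {
      rows <- joint[key == k, vcols, drop = FALSE]
      parts <- strsplit(k, "|", fixed = TRUE)[[1]]
      add_entry(analytes, parts[1], as.integer(parts[2]), as.matrix(rows))
    }
  }
  structure(list(entries = entries, analytes = analytes,
                 meta = list(coverage = config$coverage, seed = config$seed,
                             min_n = config$min_n, K = config$K,
                             method = config$method,
                             created = format(Sys.time(), "%Y-%m-%d"),
                             schema_version = 1L)),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  n_gap <- sum(vapply(x$entries, `[[`, logical(1), "unreliable"))
  cat(sprintf("Population model: %d entries (%d unreliable gaps), analytes %s\n",
              length(x$entries), n_gap, paste(x$analytes, collapse = ", ")))
  invisible(x)
}

.pm_lookup <- function(model, analytes, gender, age) {
  key <- .pm_key(analytes, gender, age)
  e <- model$entries[[key]]
  if (is.null(e))
    stop("no model for segment: ", key)
  if (isTRUE(e$unreliable))
    stop("segment ", key, " is an explicit gap (n = ", e$n, " below minimum)")
  e
}

#' Score readings against a population model
#'
#' Returns the continuous abnormal flag for each analyte reading (its HDR
#' percentile under the 1D principal Gaussian of the matching gender/age
#' segment) and, when the model holds a joint entry covering all supplied
#' analytes, the joint percentile of the readings taken together. A reading
#' can be abnormal on its own yet normal jointly (or vice versa) because the
#' joint percentile accounts for the correlation between analytes. Ages are
#' exact-match keys: an absent segment is an error, never an extrapolation.
#'
#' @param object a `population_model`.
#' @param gender `"male"` or `"female"`.
#' @param age integer age in years.
#' @param readings named numeric vector, names = analyte codes.
#' @param threshold flag threshold on the percentile (default 0.95, the
#'   conventional reference-interval mass).
#' @param ... unused.
#' @return list of class `flag_result`: `per_analyte` (data.frame analyte,
#'   value, percentile, flag), `joint` (list percentile/flag, or `NULL` for
#'   a single reading), `threshold`.
#' @export
predict.population_model <- function(object, gender, age, readings,
                                     threshold = 0.95, ...) {
  stopifnot(is.numeric(readings), length(readings) >= 1,
            !is.null(names(readings)))
  analytes <- names(readings)
  per <- data.frame(analyte = analytes, value = unname(readings),
                    percentile = NA_real_, flag = NA,
                    stringsAsFactors = FALSE)
  for (i in seq_along(analytes)) {
    e <- .pm_lookup(object, analytes[i], gender, age)
    per$percentile[i] <- hdr_percentile(e$component, readings[i])
  }
  per$flag <- per$percentile > threshold
  joint <- NULL
  if (length(analytes) >= 2) {
    e <- .pm_lookup(object, analytes, gender, age)
    x <- unname(readings[sort(analytes)])
    p <- hdr_percentile(e$component, x)
    joint <- list(percentile = p, flag = p > threshold)
  }
  structure(list(per_analyte = per, joint = joint, threshold = threshold,
                 gender = gender, age = age),
            class = "flag_result")
}

#' @export
print.flag_result <- function(x, ...) {
  cat(sprintf("Abnormal flags (%s, age %d, threshold %.2f):\n",
              x$gender, x$age, x$threshold))
  for (i in seq_len(nrow(x$per_analyte))) {
    r <- x$per_analyte[i, ]
    cat(sprintf("  %s = %g: %.1f%% range (%s)\n", r$analyte, r$value,
                100 * r$percentile, if (r$flag) "abnormal" else "normal"))
  }
  if (!is.null(x$joint))
    cat(sprintf("  joint: %.1f%% range (%s)\n", 100 * x$joint$percentile,
                if (x$joint$flag) "abnormal" else "normal"))
  invisible(x)
}

#' Save a population model to JSON
#' @param model a `population_model`.
#' @param path output path.
#' @export
save_population_model <- function(model, path) {
  entries <- lapply(model$entries, function(e) {
    out <- list(analytes = as.list(e$analytes), gender = e$gender,
                age = e$age, n = e$n, unreliable = e$unreliable)
    if (!e$unreliable) {
      out$weight <- e$component$weight
      out$mean <- e$component$mean
      out$cov <- as.numeric(t(e$component$cov))
      out$outlier_fraction <- e$outlier_fraction
    }
    out
  })
  obj <- list(meta = model$meta, analytes = as.list(model$analytes),
              entries = entries)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17)), path)
  invisible(path)
}

#' Load a population model from JSON
#' @param path path written by [save_population_model()].
#' @return a `population_model`.
#' @export
load_population_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  entries <- lapply(obj$entries, function(e) {
    out <- list(analytes = unlist(e$analytes), gender = e$gender,
                age = as.integer(e$age), n = as.integer(e$n),
                unreliable = isTRUE(e$unreliable))
    if (!out$unreliable) {
      d <- length(out$analytes)
      out$component <- gaussian_component(
        e$weight, unlist(e$mean), matrix(unlist(e$cov), d, d, byrow = TRUE))
      out$outlier_fraction <- e$outlier_fraction
    }
    out
  })
  structure(list(entries = entries, analytes = unlist(obj$analytes),
                 meta = obj$meta),
            class = "population_model")
}
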