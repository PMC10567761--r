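# Bivariate generalization of the reference interval: the highest-density
# ellipse of the principal binormal distribution and conditional ("chord")
# intervals for one analyte at a fixed value of the other.

#' Highest-density ellipse of a bivariate Gaussian
#'
#' The 2D analogue of a central reference interval: the contour around the
#' mean enclosing a given probability mass. For a Gaussian this is the set of
#' points whose squared Mahalanobis distance is below the chi-square(2)
#' quantile at `mass`, i.e. `r^2 = -2 * log(1 - mass)` — identical to
#' integrating the density outward from the mean, but in closed form.
#'
#' @param comp a 2D [gaussian_component()].
#' @param mass enclosed probability mass in (0, 1), default 0.95.
#' @return object of class `density_ellipse` with `mean`, `cov`, `mass`,
#'   `mahalanobis_sq`.
#' @examples
#' e <- hdr_ellipse(gaussian_component(1, c(0, 0), diag(2)))
#' e$mahalanobis_sq  # 5.99146 = -2 log(0.05)
#' @export
hdr_ellipse <- function(comp, mass = 0.95) {
  stopifnot(inherits(comp, "gaussian_component"), comp$d == 2L,
            mass > 0, mass < 1)
  ev <- eigen(comp$cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("covariance is not positive definite")
  rho <- comp$cov[1, 2] / sqrt(comp$cov[1, 1] * comp$cov[2, 2])
  if (abs(rho) > 0.999)
    stop("covariance is numerically singular (|correlation| > 0.999)")
  structure(list(mean = comp$mean, cov = comp$cov, mass = mass,
                 mahalanobis_sq = stats::qchisq(mass, df = 2)),
            class = "density_ellipse")
}

#' @export
print.density_ellipse <- function(x, ...) {
  cat(sprintf("Density ellipse: mass %.3f, Mahalanobis^2 threshold %.5f\n",
              x$mass, x$mahalanobis_sq))
  cat("  mean:", paste(signif(x$mean, 6), collapse = ", "), "\n")
  invisible(x)
}

#' Conditional (chord) interval at a fixed analyte value
#'
#' Slices the joint highest-density ellipse at a fixed value of one analyte,
#' returning the acceptable range for the other: the two real roots of the
#' boundary quadratic in the free coordinate. When the fixed value lies
#' outside the ellipse's projection the interval is empty — the fixed reading
#' alone already places the result outside the joint region.
#'
#' @param ellipse a [hdr_ellipse()] result.
#' @param fixed_index which coordinate is fixed (1 or 2).
#' @param fixed_value the fixed reading (mg/dl).
#' @return object of class `chord_interval`: `fixed_index`, `fixed_value`,
#'   `interval` (`c(low, high)` or `NULL`), `empty`.
#' @examples
#' e <- hdr_ellipse(gaussian_component(1, c(0, 0), diag(2)))
#' chord_interval(e, 2, 0)$interval   # +/- 2.44775
#' chord_interval(e, 2, 3)$empty      # TRUE
#' @export
chord_interval <- function(ellipse, fixed_index, fixed_value) {
  stopifnot(inherits(ellipse, "density_ellipse"), fixed_index %in% c(1, 2))
  i <- fixed_index; j <- 3L - as.integer(fixed_index)
  Q <- solve(ellipse$cov)
  dxi <- fixed_value - ellipse$mean[i]
  # Q_jj t^2 + 2 Q_ij dxi t + (Q_ii dxi^2 - r^2) = 0, t = x_j - mu_j
  a <- Q[j, j]; b <- 2 * Q[i, j] * dxi
  cc <- Q[i, i] * dxi^2 - ellipse$mahalanobis_sq
  disc <- b^2 - 4 * a * cc
  if (disc < 0)
    return(structure(list(fixed_index = i, fixed_value = fixed_value,
                          interval = NULL, empty = TRUE),
                     class = "chord_interval"))
  t1 <- (-b - sqrt(disc)) / (2 * a)
  t2 <- (-b + sqrt(disc)) / (2 * a)
  structure(list(fixed_index = i, fixed_value = fixed_value,
                 interval = sort(ellipse$mean[j] + c(t1, t2)),
                 empty = FALSE),
            class = "chord_interval")
}

#' @export
print.chord_interval <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("Chord interval at coordinate %d = %g: empty (outside joint region)\n",
                x$fixed_index, x$fixed_value))
  } else {
    cat(sprintf("Chord interval at coordinate %d = %g: (%.5f, %.5f)\n",
                x$fixed_index, x$fixed_value, x$interval[1], x$interval[2]))
  }
  invisible(x)
}

#' Boundary polyline of a density ellipse
#'
#' Points on the ellipse boundary, parameterized by angle through the
#' covariance's spectral decomposition; suitable for plotting or CSV export.
#'
#' @param ellipse a [hdr_ellipse()] result.
#' @param n_points number of points (>= 8); the polyline is closed (the last
#'   point repeats the first).
#' @return `n_points + 1` x 2 matrix of (x, y) boundary coordinates.
#' @export
contour_polyline <- function(ellipse, n_points = 360L) {
  stopifnot(inherits(ellipse, "density_ellipse"), n_points >= 8)
  es <- eigen(ellipse$cov, symmetric = TRUE)
  r <- sqrt(ellipse$mahalanobis_sq)
  theta <- seq(0, 2 * pi, length.out = n_points + 1L)
  circ <- rbind(cos(theta), sin(theta))
  pts <- t(ellipse$mean + es$vectors %*% (sqrt(es$values) * r * circ))
  colnames(pts) <- c("x", "y")
  pts
}

#' Conditional-distribution interval (alternative semantic)
#'
#' Central `coverage` interval of the exact conditional distribution of the
#' free analyte given the fixed one, `N(mu_j + rho-adjusted shift,
#' conditional variance)`. Unlike [chord_interval()] this never vanishes, no
#' matter how extreme the fixed reading; it answers a different question
#' ("given this urea, what creatinine is typical?") and is provided for
#' comparison.
#'
#' @param comp a 2D [gaussian_component()].
#' @param fixed_index,fixed_value the conditioning coordinate and value.
#' @param coverage central mass of the conditional interval.
#' @return named numeric `c(low, high)`.
#' @export
conditional_interval <- function(comp, fixed_index, fixed_value,
                                 coverage = 0.95) {
  stopifnot(inherits(comp, "gaussian_component"), comp$d == 2L,
            fixed_index %in% c(1, 2))
  i <- fixed_index; j <- 3L - as.integer(fixed_index)
  mu_c <- comp$mean[j] + comp$cov[j, i] / comp$cov[i, i] *
    (fixed_value - comp$mean[i])
  var_c <- comp$cov[j, j] - comp$cov[j, i]^2 / comp$cov[i, i]
  z <- stats::qnorm((1 + coverage) / 2)
  c(low = mu_c - z * sqrt(var_c), high = mu_c + z * sqrt(var_c))
}

#' Serialize an ellipse (and optional chords) to JSON
#' @param ellipse a `density_ellipse`.
#' @param chords optional list of `chord_interval` objects.
#' @param path optional output path.
#' @return JSON string (invisibly if written).
#' @export
ellipse_to_json <- function(ellipse, chords = NULL, path = NULL) {
  obj <- list(mean = ellipse$mean, cov = as.numeric(t(ellipse$cov)),
              mass = ellipse$mass, mahalanobis_sq = ellipse$mahalanobis_sq)
  if (!is.null(chords))
    obj$chords <- lapply(chords, function(ch) list(
      fixed_index = ch$fixed_index, fixed_value = ch$fixed_value,
      empty = ch$empty,
      interval = if (ch$empty) NULL else ch$interval))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
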