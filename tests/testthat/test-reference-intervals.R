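# Reference intervals from principal Gaussians, bootstrap errors, and
# age-trend regressions.

test_that("ri_from_component gives the central normal quantiles", {
  std <- gaussian_component(1, 0, 1)
  ri <- ri_from_component(std, coverage = 0.95)
  expect_equal(unname(ri), c(-1.959964, 1.959964), tolerance = 1e-6)

  cmp <- gaussian_component(1, 0.9, 0.15^2)
  ri2 <- ri_from_component(cmp)
  expect_equal(unname(ri2), c(0.60601, 1.19399), tolerance = 1e-5)

  # width is monotone in coverage
  widths <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99),
                   function(cv) diff(ri_from_component(std, cv)), numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("analytic limits match empirical quantiles of fresh draws", {
  mu <- 0.9; s <- 0.15
  ri <- ri_from_component(gaussian_component(1, mu, s^2))
  set.seed(99)
  draws <- rnorm(1e6, mu, s)
  emp_low <- quantile(draws, 0.025, names = FALSE)
  # MC se of the 2.5% quantile: sqrt(p(1-p)/n) / f(q)
  se <- sqrt(0.025 * 0.975 / 1e6) / dnorm(qnorm(0.025)) * s
  expect_lt(abs(emp_low - ri["low"]), 3 * se)
})

test_that("estimate_ri_segment recovers the healthy interval, pure and contaminated", {
  cfg <- ri_config(seed = 5)
  set.seed(5)
  pure <- rnorm(20000, 1.0, 0.15)
  est <- estimate_ri_segment(pure, cfg)
  expect_false(est$unreliable)
  expect_equal(est$low, 0.706, tolerance = 0.01)
  expect_equal(est$high, 1.294, tolerance = 0.01)

  # the method's central claim: contamination does not drag the limits
  cont <- contaminated_sample(20000, w_out = 0.1, seed = 5)
  est2 <- estimate_ri_segment(cont, cfg)
  expect_lt(abs(est2$low - 0.706), 0.02)
  expect_lt(abs(est2$high - 1.294), 0.02)
  expect_lt(abs(est2$outlier_fraction - 0.1), 0.02)

  # segments below min_n are flagged, not estimated
  small <- estimate_ri_segment(rnorm(50), ri_config(min_n = 120))
  expect_true(small$unreliable)
  expect_true(is.na(small$low))
})

test_that("RI limits shift little under moderate, well-separated contamination", {
  # contamination <= 10% with mean >= 3 sd away moves limits < 5% of sigma.
  # Paired design: replace 10% of the same healthy sample, so the comparison
  # isolates the contamination-induced shift; the uncontaminated baseline is
  # the single-Gaussian ML estimate (a K = 2 fit on pure data trims its own
  # spurious tail, confounding the effect being measured)
  for (seed in 1:3) {
    set.seed(seed)
    healthy <- rnorm(15000, 1, 0.15)
    repl <- runif(15000) < 0.1
    dirty_x <- ifelse(repl, rnorm(15000, 1 + 3.5 * 0.15, 0.15), healthy)
    clean <- estimate_ri_segment(healthy, ri_config(seed = seed, K = 1))
    dirty <- estimate_ri_segment(dirty_x, ri_config(seed = seed))
    expect_lt(abs(dirty$low - clean$low), 0.05 * 0.15)
    expect_lt(abs(dirty$high - clean$high), 0.05 * 0.15)
  }
})

test_that("RI estimation is affine equivariant", {
  x <- contaminated_sample(8000, seed = 17)
  cfg <- ri_config(seed = 17)
  e1 <- estimate_ri_segment(x, cfg)
  e10 <- estimate_ri_segment(10 * x, cfg)
  expect_equal(e10$low, 10 * e1$low, tolerance = 1e-3)
  expect_equal(e10$high, 10 * e1$high, tolerance = 1e-3)
})

test_that("ri_table covers every segment once and is reproducible", {
  sp <- small_spec(n_per_segment = 300L, ages = c(25L, 45L, 80L))
  coh <- generate_cohort(sp, seed = 31)
  tab <- filter_plausible(coh$results)$table
  cfg <- fast_config(seed = 31)
  rit <- ri_table(tab, cfg)
  # 2 analytes x 2 genders x 3 ages
  expect_equal(nrow(rit), 12L)
  expect_true(all(!rit$unreliable))
  expect_true(all(rit$low < rit$high))
  # male high limits exceed female at every age (generator encodes the gap)
  for (a in unique(rit$analyte)) {
    m <- rit[rit$analyte == a & rit$gender == "male", ]
    f <- rit[rit$analyte == a & rit$gender == "female", ]
    expect_true(all(m$high[order(m$age)] > f$high[order(f$age)]))
  }
  # determinism
  rit2 <- ri_table(tab, cfg)
  expect_identical(rit, rit2)
})

test_that("bootstrap_ri summarizes replicate variability", {
  # degenerate data: nearly constant values -> zero spread across replicates
  cfg <- ri_config(min_n = 10, K = 1)
  bs0 <- bootstrap_ri(rep(1, 300), B = 10, frac = 0.5, seed = 1, config = cfg)
  expect_equal(unname(bs0$sd), c(0, 0))

  # defaults follow the 100-samples-of-half convention
  expect_equal(formals(bootstrap_ri)$B, 100L)
  expect_equal(formals(bootstrap_ri)$frac, 0.5)

  # bootstrap mean approaches the point estimate
  x <- contaminated_sample(4000, seed = 23)
  cfg2 <- ri_config(seed = 23, n_init = 2)
  bs <- bootstrap_ri(x, B = 40, frac = 0.5, seed = 23, config = cfg2)
  est <- estimate_ri_segment(x, cfg2)
  expect_lt(abs(bs$mean["high"] - est$high), 3 * unname(bs$sd["high"]) + 0.01)
  expect_equal(bs$B_used + bs$failed, 40)
})

test_that("bootstrap spread shrinks roughly as 1/sqrt(2) when n quadruples", {
  cfg <- ri_config(seed = 3, n_init = 2, min_n = 50)
  x_small <- contaminated_sample(2000, seed = 3)
  x_big <- contaminated_sample(8000, seed = 4)
  bs_s <- bootstrap_ri(x_small, B = 100, frac = 0.5, seed = 3, config = cfg)
  bs_b <- bootstrap_ri(x_big, B = 100, frac = 0.5, seed = 3, config = cfg)
  ratio <- unname(bs_b$sd["high"] / bs_s$sd["high"])
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.3) # within 30% relative
})

test_that("fit_linear_trend recovers constructed coefficients exactly", {
  ages <- 20:60
  series <- data.frame(age = ages, limit = 0.00387 * ages + 1.108239)
  tr <- fit_linear_trend(series, age_range = c(20, 60))
  expect_equal(tr$coefficients[1], 1.108239, tolerance = 1e-10)
  expect_equal(tr$coefficients[2], 0.00387, tolerance = 1e-12)
  expect_equal(tr$r_squared, 1.0)

  series2 <- data.frame(age = 20:50, limit = 0.13385 * (20:50) + 17.18661)
  tr2 <- fit_linear_trend(series2, age_range = c(20, 50))
  expect_equal(tr2$coefficients, c(17.18661, 0.13385), tolerance = 1e-10)

  # constant series: flat trend, R^2 reported 0 with a warning
  expect_warning(trc <- fit_linear_trend(
    data.frame(age = 20:40, limit = rep(1, 21))), "constant")
  expect_equal(trc$coefficients[2], 0)
  expect_equal(trc$r_squared, 0)

  expect_error(fit_linear_trend(data.frame(age = c(20, 30), limit = c(1, 2))),
               "at least 3 points")
})

test_that("noisy linear trend matches the normal-equations oracle", {
  set.seed(77)
  ages <- 20:60
  y <- 0.004 * ages + 1.1 + rnorm(length(ages), 0, 0.01)
  tr <- fit_linear_trend(data.frame(age = ages, limit = y))
  X <- cbind(1, ages)
  beta <- solve(t(X) %*% X, t(X) %*% y) # independent least-squares oracle
  expect_equal(tr$coefficients, as.numeric(beta), tolerance = 1e-10)
  # p-values from standard OLS t-tests
  expect_true(all(tr$p_values < 1e-10))
})

test_that("fit_cubic_trend interpolates cubics and dominates the linear fit", {
  ages <- seq(20, 90, by = 5)
  coefs <- c(1.0, 0.01, -2e-4, 3e-6)
  y <- coefs[1] + coefs[2] * ages + coefs[3] * ages^2 + coefs[4] * ages^3
  tr <- fit_cubic_trend(data.frame(age = ages, limit = y))
  expect_equal(tr$coefficients, coefs, tolerance = 1e-8)
  expect_equal(tr$r_squared, 1.0)

  # accelerating old-age series: cubic beats linear in residual RMS
  sp <- default_spec()
  ages2 <- 20:90
  high <- vapply(ages2, function(a)
    segment_truth(sp, "2160-0", "male", a)$high, numeric(1))
  series <- data.frame(age = ages2, limit = high)
  lin <- fit_linear_trend(series)
  cub <- fit_cubic_trend(series)
  rms <- function(tr) sqrt(mean((predict_trend(tr, ages2) - high)^2))
  expect_lt(rms(cub), rms(lin))
  expect_gte(cub$r_squared, lin$r_squared) # nested models
})

test_that("annual_deterioration_rate follows the ref-age-20 convention", {
  tr_urea <- fit_linear_trend(
    data.frame(age = 20:50, limit = 0.13385 * (20:50) + 17.18661))
  expect_equal(annual_deterioration_rate(tr_urea, ref_age = 20), 0.674,
               tolerance = 1e-3)
  tr_crea <- fit_linear_trend(
    data.frame(age = 20:60, limit = 0.00387 * (20:60) + 1.108239))
  expect_equal(annual_deterioration_rate(tr_crea, ref_age = 20), 0.3264,
               tolerance = 1e-3)
  # zero slope -> zero rate
  suppressWarnings(tr0 <- fit_linear_trend(
    data.frame(age = 20:40, limit = rep(2, 21))))
  expect_equal(annual_deterioration_rate(tr0), 0)
  expect_error(annual_deterioration_rate(
    fit_cubic_trend(data.frame(age = 20:40, limit = (20:40)^3 / 1e4))),
    "degree 1")
})
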