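# Continuous HDR percentiles and the population model behind predict().

test_that("hdr_percentile has the right closed forms", {
  cmp <- gaussian_component(1, 1.0, 0.15^2)
  expect_equal(hdr_percentile(cmp, 1.0), 0)           # densest point
  # a reading at the 95% RI limit sits exactly at the 0.95 flag threshold
  lim <- ri_from_component(cmp, 0.95)
  expect_equal(hdr_percentile(cmp, lim["high"]), 0.95, tolerance = 1e-9)
  expect_equal(hdr_percentile(cmp, lim["low"]), 0.95, tolerance = 1e-9)
  # d = 1 closed form: 2 Phi(|z|) - 1
  expect_equal(hdr_percentile(cmp, 1.3), 2 * pnorm(2) - 1, tolerance = 1e-12)

  # d = 2: chi-square(2) CDF of Mahalanobis^2
  cmp2 <- gaussian_component(1, c(0, 0), diag(2))
  x <- c(sqrt(5.99146), 0)
  expect_equal(hdr_percentile(cmp2, x), 0.95, tolerance = 1e-5)
  expect_error(hdr_percentile(cmp2, 1), "dimension")
})

test_that("hdr_percentile matches the density-ranking MC oracle in d = 1, 2, 3", {
  set.seed(202)
  n <- 2e5
  for (d in 1:3) {
    A <- matrix(rnorm(d * d), d)
    S <- crossprod(A) + diag(d) * 0.5
    mu <- rnorm(d)
    cmp <- gaussian_component(1, mu, S)
    ch <- chol(S)
    draws <- sweep(matrix(rnorm(n * d), n, d) %*% ch, 2, mu, `+`)
    x <- mu + ch[1, ] * 0.8 # an arbitrary off-center reading
    # oracle: fraction of draws whose density exceeds the density at x,
    # i.e. whose Mahalanobis^2 is smaller
    m_x <- stats::mahalanobis(matrix(x, 1), mu, S)
    m_draws <- stats::mahalanobis(draws, mu, S)
    frac <- mean(m_draws < m_x)
    p <- hdr_percentile(cmp, x)
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(p - frac), 3 * se)
  }
})

test_that("percentile increases with distance from the center", {
  cmp <- gaussian_component(1, 1.0, 0.15^2)
  xs <- 1.0 + seq(0, 1, by = 0.05)
  ps <- vapply(xs, function(x) hdr_percentile(cmp, x), numeric(1))
  expect_true(all(diff(ps) > 0))
  S <- matrix(c(1, 0.6, 0.6, 1), 2)
  cmp2 <- gaussian_component(1, c(0, 0), S)
  dirs <- seq(0.1, 3, by = 0.1)
  ps2 <- vapply(dirs, function(t) hdr_percentile(cmp2, c(t, 0.5 * t)),
                numeric(1))
  expect_true(all(diff(ps2) > 0))
})

test_that("population model counts entries and stores generator truth", {
  sp <- small_spec(n_per_segment = 400L, ages = c(30L, 60L))
  coh <- generate_cohort(sp, seed = 41)
  tab <- filter_plausible(coh$results)$table
  cfg <- fast_config(seed = 41)
  pm <- build_population_model(tab, cfg)
  # 2 analyte singletons + 1 pair, x 2 genders x 2 ages
  expect_equal(length(pm$entries), 3L * 2L * 2L)
  expect_false(any(vapply(pm$entries, `[[`, logical(1), "unreliable")))

  # stored 1D means track the generating healthy means within 3 SE
  for (a in c("2160-0", "3094-0")) for (g in c("male", "female"))
    for (age in c(30L, 60L)) {
      tr <- segment_truth(sp, a, g, age)
      e <- pm$entries[[paste(a, g, age, sep = "|")]]
      se <- tr$healthy_sd / sqrt(0.9 * e$n)
      expect_lt(abs(e$component$mean - tr$healthy_mean), 3 * se + 0.05 * tr$healthy_sd)
    }
})

test_that("small segments become explicit gaps, not silent defaults", {
  sp <- small_spec(n_per_segment = 60L, ages = 40L, genders = "male")
  coh <- generate_cohort(sp, seed = 43)
  pm <- build_population_model(coh$results, ri_config(min_n = 120))
  expect_true(all(vapply(pm$entries, `[[`, logical(1), "unreliable")))
  expect_error(predict(pm, "male", 40, c("2160-0" = 1.0)), "gap")
  expect_error(predict(pm, "male", 77, c("2160-0" = 1.0)), "no model")
})

test_that("predict reproduces closed-form percentiles and flags", {
  # hand-built model entry: mu = (1, 14), diagonal covariance, rho = 0
  pm <- structure(list(
    entries = list(), analytes = c("2160-0", "3094-0"),
    meta = list(coverage = 0.95)), class = "population_model")
  add <- function(key, comp) pm$entries[[key]] <<- list(
    analytes = strsplit(strsplit(key, "|", fixed = TRUE)[[1]][1], "+",
                        fixed = TRUE)[[1]],
    gender = "male", age = 30L, n = 1000L, unreliable = FALSE,
    component = comp, outlier_fraction = 0.05)
  add("2160-0|male|30", gaussian_component(0.95, 1.0, 0.0225))
  add("3094-0|male|30", gaussian_component(0.95, 14.0, 9.0))
  add("2160-0+3094-0|male|30",
      gaussian_component(0.95, c(1.0, 14.0), diag(c(0.0225, 9.0))))

  fr <- predict(pm, "male", 30, c("2160-0" = 1.3, "3094-0" = 10.0))
  crea <- fr$per_analyte[fr$per_analyte$analyte == "2160-0", ]
  urea <- fr$per_analyte[fr$per_analyte$analyte == "3094-0", ]
  expect_equal(crea$percentile, 2 * pnorm(2.0) - 1, tolerance = 1e-9) # 0.9545
  expect_true(crea$flag)                                  # abnormal alone
  expect_equal(urea$percentile, 2 * pnorm(4 / 3) - 1, tolerance = 1e-9) # 0.8175
  expect_false(urea$flag)
  # joint percentile: chi-square(2) CDF of 4 + 16/9
  expect_equal(fr$joint$percentile, 1 - exp(-(4 + 16 / 9) / 2),
               tolerance = 1e-9)                          # 0.9444
  expect_false(fr$joint$flag) # abnormal alone, normal jointly

  # readings at the segment means: all percentiles 0, nothing flagged
  fr0 <- predict(pm, "male", 30, c("2160-0" = 1.0, "3094-0" = 14.0))
  expect_equal(fr0$per_analyte$percentile, c(0, 0))
  expect_equal(fr0$joint$percentile, 0)
  expect_false(any(fr0$per_analyte$flag))
})

test_that("binary flags agree with RI / ellipse membership", {
  cmp1 <- gaussian_component(0.9, 1.0, 0.0225)
  lim <- ri_from_component(cmp1, 0.95)
  for (x in seq(0.5, 1.7, by = 0.06)) {
    inside <- x >= lim["low"] && x <= lim["high"]
    expect_equal(hdr_percentile(cmp1, x) > 0.95, !inside)
  }
  S <- matrix(c(0.0225, 0.225, 0.225, 9), 2)
  cmp2 <- gaussian_component(0.9, c(1, 14), S)
  ell <- hdr_ellipse(cmp2, 0.95)
  set.seed(7)
  pts <- cbind(runif(200, 0.4, 1.8), runif(200, 5, 30))
  maha <- stats::mahalanobis(pts, cmp2$mean, cmp2$cov)
  for (i in seq_len(200)) {
    expect_equal(hdr_percentile(cmp2, pts[i, ]) > 0.95,
                 maha[i] > ell$mahalanobis_sq)
  }
})

test_that("joint percentile uses the correlation, not the marginals alone", {
  rho <- 0.6
  S <- matrix(c(1, rho, rho, 1), 2)
  cmp <- gaussian_component(1, c(0, 0), S)
  # equal marginal percentiles, different joint percentiles
  concordant <- c(1, 1)
  discordant <- c(1, -1)
  m1 <- gaussian_component(1, 0, 1)
  expect_equal(hdr_percentile(m1, concordant[1]),
               hdr_percentile(m1, discordant[1]))
  expect_gt(hdr_percentile(cmp, discordant), hdr_percentile(cmp, concordant))
})

test_that("a saved model reloads to byte-identical predictions", {
  sp <- small_spec(n_per_segment = 300L, ages = 50L)
  coh <- generate_cohort(sp, seed = 47)
  pm <- build_population_model(filter_plausible(coh$results)$table,
                               fast_config(seed = 47))
  f <- withr::local_tempfile(fileext = ".json")
  save_population_model(pm, f)
  pm2 <- load_population_model(f)
  r <- c("2160-0" = 1.2, "3094-0" = 18)
  fr1 <- predict(pm, "female", 50, r)
  fr2 <- predict(pm2, "female", 50, r)
  expect_identical(fr1$per_analyte$percentile, fr2$per_analyte$percentile)
  expect_identical(fr1$joint$percentile, fr2$joint$percentile)
})
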