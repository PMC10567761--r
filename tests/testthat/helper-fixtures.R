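# Shared fixtures: tiny in-code tables and seeded contaminated samples.

make_table <- function(person_id, gender, age, analyte, value,
                       date = as.Date("2021-03-01")) {
  data.frame(person_id = person_id, gender = gender, age = age,
             analyte = analyte, value = value,
             date = rep(as.Date(date), length.out = length(value)),
             stringsAsFactors = FALSE)
}

# contaminated 1D segment: healthy N(1.0, 0.15^2) with a pathological
# N(1.8, 0.5^2) admixture
contaminated_sample <- function(n, w_out = 0.1, seed = 1,
                                mu = 1.0, sd = 0.15,
                                mu_out = 1.8, sd_out = 0.5) {
  set.seed(seed)
  out <- runif(n) < w_out
  ifelse(out, rnorm(n, mu_out, sd_out), rnorm(n, mu, sd))
}

# contaminated bivariate segment with correlated healthy component
contaminated_sample_2d <- function(n, w_out = 0.1, seed = 3,
                                   mu = c(1.0, 14.0), sds = c(0.15, 3.0),
                                   rho = 0.5) {
  set.seed(seed)
  out <- runif(n) < w_out
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  m1 <- ifelse(out, mu[1] + 3 * sds[1], mu[1])
  m2 <- ifelse(out, mu[2] + 3 * sds[2], mu[2])
  s1 <- ifelse(out, 2 * sds[1], sds[1])
  s2 <- ifelse(out, 2 * sds[2], sds[2])
  cbind(m1 + s1 * z1, m2 + s2 * z2)
}

# small fast config for pipeline tests
fast_config <- function(...) {
  ri_config(n_init = 2L, min_n = 50L, ...)
}

# tiny cohort spec (few ages, small segments) for pipeline tests
small_spec <- function(n_per_segment = 400L, ages = c(30L, 60L, 90L),
                       genders = c("male", "female"),
                       implausible_rate = 0.002) {
  sp <- default_spec()
  sp$ages <- ages
  sp$genders <- genders
  sp$n_per_segment <- n_per_segment
  sp$implausible_rate <- implausible_rate
  sp
}
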