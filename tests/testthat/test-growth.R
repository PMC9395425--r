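test_that("local cubic reproduces a global cubic and its derivative exactly", {
  f <- function(x) 2 + 3 * x - x^2 + 0.5 * x^3
  fp <- function(x) 3 - 2 * x + 1.5 * x^2
  ages <- seq(9, 13, by = 1 / 12)
  vals <- f(ages)
  for (bw in c(0.4, 0.75, 2)) {
    for (x0 in c(9.7, 11, 12.3)) {
      fit <- fit_local_cubic(ages, vals, x0, bw)
      expect_equal(fit$fitted, f(x0), tolerance = 1e-9)
      expect_equal(fit$velocity, fp(x0), tolerance = 1e-8)
    }
  }
  # constant series: fitted constant, zero velocity
  fitc <- fit_local_cubic(ages, rep(140, length(ages)), 11, 0.75)
  expect_equal(fitc$fitted, 140, tolerance = 1e-10)
  expect_equal(fitc$velocity, 0, tolerance = 1e-8)
})

test_that("local fit agrees with an independent normal-equations WLS oracle", {
  set.seed(21)
  ages <- seq(10, 12, length.out = 15)
  vals <- 130 + 4 * (ages - 10) + rnorm(15, 0, 0.3)
  rw <- runif(15, 0.5, 1)
  x0 <- 11.1
  fit <- fit_local_cubic(ages, vals, x0, bandwidth = 1.2, robust_weights = rw)
  w <- tricube((ages - x0) / 1.2) * rw
  oracle <- wls_poly_oracle(ages[w > 0], vals[w > 0], w[w > 0], x0)
  expect_equal(fit$fitted, oracle[1], tolerance = 1e-8)
  expect_equal(fit$velocity, oracle[2], tolerance = 1e-8)
})

test_that("degenerate designs fall back or error informatively", {
  ages <- c(10, 10.1, 10.2, 10.3)
  vals <- c(140, 140.2, 140.4, 140.6)
  # only two points carry kernel weight -> degree drops to linear
  expect_warning(fit <- fit_local_cubic(ages, vals, 10.15, bandwidth = 0.15),
                 "falling back")
  expect_lt(fit$degree, 3)
  expect_equal(fit$fitted, 140.3, tolerance = 1e-6)
  expect_error(fit_local_cubic(ages, vals, 20, bandwidth = 0.5), "positive weight")
})

test_that("smoothing reproduces a noiseless cubic with zero residuals", {
  ages <- seq(10, 11.2, by = 1 / 12)
  vals <- 120 + 5 * (ages - 10) + 2 * (ages - 10)^2 - 0.8 * (ages - 10)^3
  m <- smooth_series(tibble::tibble(age_years = ages, value = vals),
                     robust_iterations = 0L)
  at_obs <- approx(m$curve$age_years, m$curve$fitted, ages)$y
  expect_equal(at_obs, vals, tolerance = 1e-6)
})

test_that("smoothing is equivariant under vertical shifts", {
  set.seed(4)
  ages <- seq(10, 12, by = 1 / 12)
  vals <- 135 + 3 * (ages - 10) + rnorm(length(ages), 0, 0.3)
  m0 <- smooth_series(tibble::tibble(age_years = ages, value = vals))
  m1 <- smooth_series(tibble::tibble(age_years = ages, value = vals + 50))
  expect_equal(m1$curve$fitted, m0$curve$fitted + 50, tolerance = 1e-8)
  expect_equal(m1$curve$velocity, m0$curve$velocity, tolerance = 1e-8)
})

test_that("bisquare reweighting suppresses a gross outlier", {
  ages <- seq(10, 12, by = 1 / 12)
  vals <- 130 + 4 * (ages - 10)
  dirty <- vals
  k <- 13
  dirty[k] <- dirty[k] + 8  # 8 cm spike
  m_dirty <- smooth_series(tibble::tibble(age_years = ages, value = dirty),
                           robust_iterations = 2L)
  m_clean <- smooth_series(tibble::tibble(age_years = ages[-k], value = vals[-k]),
                           robust_iterations = 0L)
  expect_lt(m_dirty$robust_weights[k], 0.05)
  clean_at <- approx(m_clean$curve$age_years, m_clean$curve$fitted,
                     m_dirty$curve$age_years, rule = 2)$y
  expect_lt(max(abs(m_dirty$curve$fitted - clean_at)), 0.2)
})

test_that("short series are flagged unmodellable", {
  s <- tibble::tibble(age_years = seq(10, 10.4, by = 0.1), value = 140:144)
  expect_warning(m <- smooth_series(s), "unmodellable")
  expect_null(m)
  st <- assign_maturity_stage(NULL)
  expect_true(is.na(st$stage))
  expect_equal(st$reason, "unmodellable")
})

test_that("velocity argmax tracks the analytic peak on simulated growth", {
  set.seed(11)
  p <- pb_typical_female
  phv <- pb1_phv_age(p$h1, p$h_theta, p$s0, p$s1, p$theta)
  ages <- seq(phv - 2, phv + 2, by = 1 / 12)
  h <- pb_h(ages, p) + rnorm(length(ages), 0, 0.3)
  m <- smooth_series(tibble::tibble(age_years = ages, value = h))
  keep <- staging_support(m)
  est <- m$curve$age_years[keep][which.max(m$curve$velocity[keep])]
  expect_lt(abs(est - phv), 0.25)
})

test_that("staging follows the documented cascade on canonical shapes", {
  cfg <- staging_config()
  ages <- seq(10, 12, by = 1 / 12)
  # strictly decelerating childhood curve -> stage 1, short-for-age recorded
  s1 <- stage_from_velocity(ages, 5.5 - 0.3 * (ages - 10), height_z = -0.5, config = cfg)
  expect_equal(s1$stage, 1L)
  expect_true(s1$short_for_age)
  # window astride the analytic PHV -> stage 3 with a detected peak
  p <- pb_typical_female
  phv <- pb1_phv_age(p$h1, p$h_theta, p$s0, p$s1, p$theta)
  ga <- seq(phv - 1.2, phv + 0.9, by = 1 / 12)
  s3 <- stage_from_velocity(ga, pb_v(ga, p), config = cfg)
  expect_equal(s3$stage, 3L)
  expect_lt(abs(s3$phv_age - phv), 0.2)
  # window entirely well past PHV with end velocity ~30% of its start -> stage 4
  ga4 <- seq(phv + 1.6, phv + 3.6, by = 1 / 12)
  s4 <- stage_from_velocity(ga4, pb_v(ga4, p), config = cfg)
  expect_equal(s4$stage, 4L)
  # early-spurt window: past the minimum, still accelerating -> stage 2
  pm <- pb_typical_male
  ga2 <- seq(pm$theta - 2.6, pm$theta - 0.9, by = 1 / 12)
  s2 <- stage_from_velocity(ga2, pb_v(ga2, pm), config = cfg)
  expect_equal(s2$stage, 2L)
})

test_that("later developmental windows never yield a lower stage", {
  p <- pb_typical_female
  phv <- pb1_phv_age(p$h1, p$h_theta, p$s0, p$s1, p$theta)
  starts <- seq(phv - 4, phv + 1.5, by = 0.25)
  stages <- vapply(starts, function(s0) {
    ga <- seq(s0, s0 + 2, by = 1 / 12)
    stage_from_velocity(ga, pb_v(ga, p))$stage
  }, integer(1))
  expect_true(all(diff(stages) >= 0))
})
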