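# Small-sample brute-force oracles, evaluated directly from the defining
# formulas, pinned against the implementation.

test_that("log transforms behave and round-trip", {
  expect_equal(transform_log(c(1, 10, 100))$transformed, c(0, 1, 2))
  expect_error(transform_log(c(1, -2, 3)), "indices: 2")
  r <- transform_log(c(0.2, 1.0, 1.8), "reflect_then_log10")
  expect_equal(r$K, 1.8)
  expect_equal(r$transformed, log10(c(2.6, 1.8, 1.0)))
  # order-reversing
  expect_true(all(diff(r$transformed) < 0))
  # recorded inverse reproduces inputs
  expect_equal(invert_transform_log(r), c(0.2, 1.0, 1.8), tolerance = 1e-12)
  set.seed(2)
  x <- rnorm(50)
  expect_equal(invert_transform_log(transform_log(x, "reflect_then_log10")), x,
               tolerance = 1e-12)
})

test_that("Pearson correlation matches the direct sum formula", {
  x <- c(1.2, 3.1, 2.2, 5.0, 4.4, 6.1, 0.7, 2.9)
  y <- c(2.0, 4.5, 2.9, 6.2, 6.8, 7.7, 1.1, 3.3)
  n <- length(x)
  r_direct <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  t_direct <- r_direct * sqrt((n - 2) / (1 - r_direct^2))
  p_direct <- 2 * pt(-abs(t_direct), n - 2)
  got <- correlation(x, y)
  expect_equal(got$r, r_direct, tolerance = 1e-10)
  expect_equal(got$p, p_direct, tolerance = 1e-10)
  # exact linear relation
  expect_equal(correlation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
})

test_that("partial correlation matches the first-order closed form", {
  # construct data whose sample correlations are exactly 0.5 pairwise
  set.seed(9)
  n <- 40
  Z <- scale(qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, 2:4])
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  X <- Z %*% chol(R)
  expect_equal(cor(X)[lower.tri(cor(X))], rep(0.5, 3), tolerance = 1e-12)
  got <- correlation(X[, 1], X[, 2], controls = list(X[, 3]))
  closed <- (0.5 - 0.5 * 0.5) / sqrt((1 - 0.25) * (1 - 0.25))
  expect_equal(got$r, closed, tolerance = 1e-10)   # 1/3
  expect_equal(got$df, n - 3L)
  # independent control at large n changes nothing materially
  set.seed(10)
  x <- rnorm(4000); y <- x + rnorm(4000); z <- rnorm(4000)
  expect_equal(correlation(x, y, list(z))$r, correlation(x, y)$r, tolerance = 0.02)
})

test_that("pooled t-test matches hand arithmetic and is antisymmetric", {
  got <- t_test_two_tailed(c(1, 2), c(3, 4))
  expect_equal(got$t, -2 / sqrt(0.5 * (1 / 2 + 1 / 2)), tolerance = 1e-10)  # -2.828
  expect_equal(got$df, 2)
  swapped <- t_test_two_tailed(c(3, 4), c(1, 2))
  expect_equal(swapped$t, -got$t, tolerance = 1e-12)
  expect_equal(swapped$p, got$p, tolerance = 1e-12)
  same <- t_test_two_tailed(c(5, 5, 5), c(5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(t_test_two_tailed(c(1, 1), c(2, 2)), "degenerate")
})

test_that("quadratic fit interpolates exact quadratics and reports the vertex", {
  x <- 1:6
  y <- 1 + 2 * x - 0.5 * x^2
  fit <- suppressWarnings(quadratic_fit(x, y))
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
  expect_equal(fit$b1, 2, tolerance = 1e-8)
  expect_equal(fit$b2, -0.5, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_equal(fit$vertex_x, 2, tolerance = 1e-8)
  expect_error(quadratic_fit(rep(2, 6), y), "collinear")
})

test_that("quadratic OLS matches the normal-equations oracle on a small instance", {
  set.seed(31)
  x <- c(5, 6, 6, 7, 7, 8, 8, 9, 9, 10)
  y <- 2 + 0.8 * x - 0.05 * x^2 + rnorm(10, 0, 0.3)
  X <- cbind(1, x, x^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fit <- quadratic_fit(x, y)
  expect_equal(c(fit$intercept, fit$b1, fit$b2), as.numeric(beta), tolerance = 1e-10)
  rss <- sum((y - X %*% beta)^2)
  tss <- sum((y - mean(y))^2)
  expect_equal(fit$r2, 1 - rss / tss, tolerance = 1e-10)
  Fstat <- ((tss - rss) / 2) / (rss / (10 - 3))
  expect_equal(fit$p, pf(Fstat, 2, 7, lower.tail = FALSE), tolerance = 1e-10)
})

test_that("quadratic coefficient estimates are unbiased at the study size", {
  set.seed(77)
  truth <- c(1, 2, -0.5)
  reps <- 500
  est <- matrix(NA_real_, reps, 3)
  for (i in seq_len(reps)) {
    x <- runif(58, 0.7, 1)      # the log10 RP range
    y <- truth[1] + truth[2] * x + truth[3] * x^2 + rnorm(58, 0, 0.3)
    f <- quadratic_fit(x, y)
    est[i, ] <- c(f$intercept, f$b1, f$b2)
  }
  for (j in 1:3) {
    mc_se <- sd(est[, j]) / sqrt(reps)
    expect_lt(abs(mean(est[, j]) - truth[j]), 2 * mc_se)
  }
})

test_that("Bonferroni thresholds reproduce the printed criteria", {
  b6 <- bonferroni_adjust(c(0.001, 0.012, 0.007, 0.002, 0.000, 0.005), m = 6)
  expect_equal(b6$threshold, 0.05 / 6, tolerance = 1e-15)
  expect_equal(sprintf("%.3f", b6$threshold), "0.008")
  expect_equal(b6$significant, c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(bonferroni_adjust(0.01, m = 4)$threshold, 0.0125)
  expect_equal(bonferroni_adjust(0.03, m = 1)$threshold, 0.05)
  expect_equal(bonferroni_adjust(c(0.3, 0.004), m = 6)$adjusted_p, c(1, 0.024))
})

test_that("Kruskal-Wallis H matches the rank-sum formula and rank invariance", {
  vals <- c(1, 2, 3, 4, 5, 6)
  grp <- rep(c("a", "b"), each = 3)
  got <- kruskal_wallis_mc(vals, grp)
  # no ties: H = 12/(n(n+1)) * sum(R_i^2/n_i) - 3(n+1)
  H_direct <- 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7
  expect_equal(got$summary$H, H_direct, tolerance = 1e-10)   # 3.857...
  expect_equal(got$summary$df, 1L)
  # invariant under strictly monotone transforms
  got2 <- kruskal_wallis_mc(exp(vals), grp)
  expect_equal(got2$summary$H, got$summary$H, tolerance = 1e-12)
  # identical observations everywhere -> H 0, pairwise p 1
  flat <- kruskal_wallis_mc(rep(7, 9), rep(c("a", "b", "c"), 3))
  expect_equal(flat$summary$H, 0)
  expect_equal(flat$pairwise$p_adjusted, rep(1, 3))
})

test_that("Dunn pairwise z matches the direct mean-rank formula", {
  set.seed(5)
  vals <- c(3.1, 4.2, 2.8, 7.7, 8.1, 6.9, 5.5, 5.0, 6.2, 4.9, 8.8, 3.3)
  grp <- rep(c("g1", "g2", "g3"), each = 4)
  got <- kruskal_wallis_mc(vals, grp)
  n <- length(vals)
  rk <- rank(vals)
  m1 <- mean(rk[grp == "g1"]); m2 <- mean(rk[grp == "g2"])
  se <- sqrt((n * (n + 1) / 12) * (1 / 4 + 1 / 4))  # no ties here
  z_direct <- (m1 - m2) / se
  row <- got$pairwise[got$pairwise$group_1 == "g1" & got$pairwise$group_2 == "g2", ]
  expect_equal(row$z, z_direct, tolerance = 1e-10)
  expect_equal(row$p_adjusted, min(1, 3 * 2 * pnorm(-abs(z_direct))), tolerance = 1e-10)
})

test_that("Kruskal-Wallis test size is nominal under the null", {
  set.seed(123)
  reps <- 2000
  rej <- logical(reps)
  for (i in seq_len(reps)) {
    vals <- rnorm(30)
    grp <- rep(c("a", "b", "c"), each = 10)
    rej[i] <- kruskal.test(vals, factor(grp))$p.value < 0.05
  }
  bounds <- qbinom(c(0.005, 0.995), reps, 0.05) / reps
  expect_gte(mean(rej), bounds[1])
  expect_lte(mean(rej), bounds[2])
})

test_that("2x2 chi-square, RR and OR match hand computation", {
  tab <- rbind(c(9, 18), c(1, 19))  # slower-biorhythm row first
  got <- chi_square_rr(tab)
  # direct sum((O-E)^2/E)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$chi_sq, sum((tab - E)^2 / E), tolerance = 1e-10)  # 5.51
  expect_equal(got$relative_risk, (9 / 27) / (1 / 20), tolerance = 1e-12)  # 6.67
  expect_equal(got$odds_ratio, 9 * 19 / (18 * 1), tolerance = 1e-12)
  expect_false(got$or_corrected)
  # equal proportions -> null everything
  flat <- chi_square_rr(rbind(c(5, 5), c(5, 5)))
  expect_equal(flat$chi_sq, 0)
  expect_equal(flat$relative_risk, 1)
  expect_equal(flat$odds_ratio, 1)
  # zero cell -> Haldane-corrected OR, flagged
  z <- chi_square_rr(rbind(c(4, 0), c(2, 6)))
  expect_true(z$or_corrected)
  expect_equal(z$odds_ratio, (4.5 * 6.5) / (0.5 * 2.5), tolerance = 1e-12)
  expect_error(chi_square_rr(rbind(c(4, 3), c(0, 0))), "margins")
})

test_that("standardised betas reduce to correlations in canonical designs", {
  set.seed(14)
  x <- rnorm(30); y <- 2 * x + rnorm(30)
  sb <- standardized_betas(y, list(x = x))
  expect_equal(sb$beta, correlation(x, y)$r, tolerance = 1e-10)
  # orthogonal standardized predictors: beta_j equals r(response, x_j)
  n <- 25
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * 2), n, 2))))[, 2:3]
  X <- scale(Q)
  resp <- 0.7 * X[, 1] - 0.3 * X[, 2] + rnorm(n, 0, 0.5)
  sb2 <- standardized_betas(resp, list(a = X[, 1], b = X[, 2]))
  expect_equal(sb2$beta[1], cor(resp, X[, 1]), tolerance = 1e-10)
  expect_equal(sb2$beta[2], cor(resp, X[, 2]), tolerance = 1e-10)
  # scale invariance
  sb3 <- standardized_betas(resp, list(a = 10 * X[, 1], b = X[, 2]))
  expect_equal(sb3$beta, sb2$beta, tolerance = 1e-10)
  expect_error(standardized_betas(resp, list(a = X[, 1], b = 2 * X[, 1])),
               "collinearity")
})

test_that("Tukey fences flag outliers under both policies", {
  expect_true(all(!flag_outliers(1:9)))
  with_out <- flag_outliers(c(1:9, 100))
  expect_equal(which(with_out), 10)
  expect_equal(which(flag_outliers(c(1:9, 100), "extreme_3_0")), 10)
  # hinge arithmetic: fivenum hinges of {1..9, 100} are 3 and 8
  fn <- fivenum(c(1:9, 100))
  expect_equal(fn[c(2, 4)], c(3, 8))
  # translation invariance
  expect_equal(flag_outliers(c(1:9, 100) + 55), with_out)
  expect_error(flag_outliers(c(1, 2, 3)), "n >= 4")
})

test_that("pooled means recombine group means with their sizes", {
  expect_equal(round(pooled_mean(c(7.50, 6.96), c(34, 27)), 2), 7.26)
  expect_equal(round(pooled_mean(c(10.30, 10.36), c(34, 27)), 2), 10.33)
  expect_equal(pooled_mean(c(4.5, 4.5), c(10, 3)), 4.5)
})
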