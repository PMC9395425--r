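test_that("simulation is deterministic and per-participant streams are stable", {
  cfg <- sim_config(seed = 17, n_female = 5L, n_male = 4L)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$records, s2$cohort$records)
  expect_identical(s1$truth, s2$truth)
  # byte-identical files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulated_study(s1, d1); write_simulated_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # enlarging the cohort leaves earlier participants' draws untouched
  bigger <- simulate_cohort(sim_config(seed = 17, n_female = 6L, n_male = 4L))
  first5 <- bigger$cohort$records[bigger$cohort$records$participant_id %in%
                                   sprintf("P%03d", 1:5), ]
  expect_equal(first5$height_cm,
               s1$cohort$records$height_cm[s1$cohort$records$participant_id %in%
                                             sprintf("P%03d", 1:5)])
})

test_that("degenerate generator: no noise, flat gain model -> exact sex baselines", {
  cfg <- sim_config(seed = 3, n_female = 4L, n_male = 4L,
                    gain_curvature = 0, gain_sd_log10 = 0,
                    seasonal_amplitude = 0, lockdown_bump = 0,
                    noise_height_cm = 0, noise_weight_kg = 0, noise_leg_cm = 0)
  sim <- simulate_cohort(cfg)
  gains <- vapply(sim$truth$participant_id, function(id) {
    interval_gain(participant_series(sim$cohort, id, "weight"))$gain
  }, numeric(1))
  expected <- ifelse(sim$truth$sex == "female",
                     cfg$gain_peak_female, cfg$gain_peak_male)
  expect_equal(unname(gains), expected, tolerance = 1e-9)
  expect_equal(sim$truth$expected_gain, expected, tolerance = 1e-9)
})

test_that("expected weight gain is ordered RP6 < RP7 and RP6 < RP8 by construction", {
  cfg <- sim_config()
  for (sex in c("female", "male")) {
    g <- vapply(6:8, function(rp) rpgrowth:::expected_gain(rp, sex, cfg), numeric(1))
    expect_lt(g[1], g[2])
    expect_lt(g[1], g[3])
  }
  # and the empirical group means across replicated cohorts respect the order
  gains <- list(`6` = c(), `7` = c(), `8` = c())
  for (seed in 1:20) {
    sim <- simulate_cohort(sim_config(seed = seed, n_female = 17L, n_male = 14L))
    gg <- vapply(sim$truth$participant_id, function(id) {
      interval_gain(participant_series(sim$cohort, id, "weight"))$gain
    }, numeric(1))
    for (rp in 6:8) {
      gains[[as.character(rp)]] <- c(gains[[as.character(rp)]],
                                     gg[sim$truth$rp_days == rp])
    }
  }
  expect_lt(mean(gains[["6"]]), mean(gains[["7"]]))
  expect_lt(mean(gains[["6"]]), mean(gains[["8"]]))
})

test_that("simulated heights rise monotonically in the noiseless case", {
  cfg <- sim_config(seed = 8, n_female = 3L, n_male = 3L,
                    noise_height_cm = 0, noise_weight_kg = 0, noise_leg_cm = 0)
  sim <- simulate_cohort(cfg)
  for (id in sim$truth$participant_id) {
    s <- participant_series(sim$cohort, id, "height")
    expect_true(all(diff(s$value) > 0))
  }
})

test_that("noiseless histology recovers every RP; matching rule fails under miscounts", {
  for (p in c(5, 8, 10)) {
    h <- simulate_histology(p, dsr = 4.2, n_fields = 2, noise_cv = 0,
                            miscount_rate = 0, seed = p)
    r <- apply_inclusion_rule(estimate_rp(h))
    expect_true(r$included)
    expect_equal(r$rp_days, p)
  }
  # heavy miscounting drives exclusion roughly as often as matching predicts
  set.seed(99)
  excluded <- vapply(1:200, function(i) {
    h <- simulate_histology(7, n_fields = 2, noise_cv = 0, miscount_rate = 0.5,
                            seed = i)
    !apply_inclusion_rule(estimate_rp(h))$included
  }, logical(1))
  expect_gt(mean(excluded), 0.2)
  expect_lt(mean(excluded), 0.9)
})

test_that("DSR-ratio estimator tolerates realistic measurement noise", {
  set.seed(42)
  hits <- 0; total <- 0
  for (p in c(6, 7, 8)) {
    h <- simulate_histology(p, dsr = 4, n_fields = 100, noise_cv = 0.03,
                            p_count_visible = 0, seed = 1000 + p)
    est <- estimate_rp(h)
    expect_true(all(est$method == "dsr_ratio"))
    hits <- hits + sum(est$rp_days == p); total <- total + nrow(est)
  }
  expect_gt(hits / total, 0.97)
})
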