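test_that("BMI is weight over squared height in metres", {
  expect_equal(bmi(50, 100), 50)
  expect_equal(bmi(46, 152), 46 / 1.52^2)   # 19.909...
  expect_equal(bmi(2 * 46, 152), 2 * bmi(46, 152))
  expect_error(bmi(-1, 150), "positive")
})

test_that("LMS percentile matches the closed form and is monotone in BMI", {
  ref <- as_lms_reference(tibble::tibble(
    sex = rep("F", 2), age_years = c(10, 11),
    L = c(-1.6, -1.6), M = c(17, 17.4), S = c(0.12, 0.125)))
  # bmi equal to the median -> z 0, percentile 50
  at_m <- bmi_percentile(17, "female", 10, ref)
  expect_equal(at_m$z, 0, tolerance = 1e-12)
  expect_equal(at_m$percentile, 50, tolerance = 1e-10)
  # direct one-line evaluation of the Box-Cox form at L = -1.6
  z_direct <- ((22 / 17)^(-1.6) - 1) / (-1.6 * 0.12)
  got <- bmi_percentile(22, "female", 10, ref)
  expect_equal(got$z, z_direct, tolerance = 1e-12)
  expect_equal(got$percentile, pnorm(z_direct) * 100, tolerance = 1e-10)
  # L = 1 reduces to (x/M - 1)/S
  ref1 <- as_lms_reference(tibble::tibble(sex = "F", age_years = 10,
                                          L = 1, M = 17, S = 0.12))
  expect_equal(lms_zscore(18, "female", 10, ref1), (18 / 17 - 1) / 0.12,
               tolerance = 1e-12)
  # strictly increasing in bmi; interpolation stays inside the grid
  bmis <- seq(14, 30, by = 0.5)
  pct <- bmi_percentile(bmis, "female", 10.5, ref)$percentile
  expect_true(all(diff(pct) > 0))
  expect_error(bmi_percentile(20, "female", 30, ref), "outside")
})

test_that("obesity classification uses at-or-above the 95th percentile", {
  expect_true(classify_obesity(95))
  expect_false(classify_obesity(94.99))
  expect_true(classify_obesity(100))
})

test_that("interval gain normalises by elapsed months of 30.4375 days", {
  s <- tibble::tibble(
    visit_date = as.Date("2019-09-01") + c(0, 426),
    value = c(42, 48))
  g <- interval_gain(s)
  expect_equal(g$gain, 6)
  expect_equal(g$adjusted_gain_14mo, 6 / (426 / 30.4375) * 14, tolerance = 1e-12)
  expect_equal(g$adjusted_gain_14mo, 6, tolerance = 0.01)  # 426 d is ~14 mo
  # 12-month span scales to 7 kg over 14 months
  s2 <- tibble::tibble(visit_date = as.Date("2019-09-01") + c(0, round(12 * 30.4375)),
                       value = c(42, 48))
  expect_equal(interval_gain(s2)$adjusted_gain_14mo, 7, tolerance = 0.01)
  # single in-window value -> absent with reason
  g1 <- interval_gain(s, window = as.Date(c("2019-09-01", "2019-09-02")))
  expect_true(is.na(g1$gain))
  expect_equal(g1$reason, "insufficient observations")
  # translation invariance
  s3 <- s; s3$value <- s3$value + 100
  expect_equal(interval_gain(s3)$gain, g$gain)
})

test_that("average weight handles overall and monthly granularity", {
  s <- tibble::tibble(
    visit_date = as.Date(c("2019-09-10", "2019-09-24", "2019-11-05")),
    value = c(40, 42, 44))
  expect_equal(average_weight(s), 42)
  monthly <- average_weight(s, granularity = "monthly")
  expect_equal(nrow(monthly), 2)  # no October visit -> absent, not zero
  expect_equal(monthly$mean_value[monthly$month == as.Date("2019-09-01")], 41)
  expect_true(is.na(average_weight(s, window = as.Date(c("2021-01-01", "2021-02-01")))))
})

test_that("period labels follow Southern-Hemisphere seasons and the lockdown window", {
  lab <- label_period(as.Date(c("2020-01-15", "2020-04-15", "2019-09-20", "2020-07-01")))
  expect_equal(as.character(lab$season), c("summer", "autumn", "spring", "winter"))
  expect_equal(lab$lockdown, c(FALSE, TRUE, FALSE, FALSE))
  edges <- label_period(as.Date(c("2020-03-24", "2020-03-25", "2020-06-08", "2020-06-09")))
  expect_equal(edges$lockdown, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("per-season gains telescope to the full-window gain on gap-free data", {
  dates <- seq(as.Date("2019-09-01"), as.Date("2020-10-31"), by = "1 day")
  s <- tibble::tibble(visit_date = dates,
                      value = 40 + 0.01 * seq_along(dates))
  cuts <- as.Date(c("2019-09-01", "2019-12-01", "2020-03-01",
                    "2020-07-01", "2020-10-31"))
  partial <- sum(vapply(seq_len(length(cuts) - 1), function(i) {
    interval_gain(s, window = c(cuts[i], cuts[i + 1]))$gain
  }, numeric(1)))
  total <- interval_gain(s, window = range(dates))$gain
  # consecutive windows share their boundary visit, so the sums telescope
  expect_equal(partial, total, tolerance = 1e-9)
})

test_that("synthetic LMS references are valid and file round-trip safely", {
  for (measure in c("bmi", "height")) {
    ref <- synthetic_lms_reference(measure)
    expect_s3_class(ref, "lms_reference")
    expect_true(all(ref$M > 0) && all(ref$S > 0))
    dir <- withr::local_tempdir()
    path <- file.path(dir, paste0("lms_", measure, "_synthetic.csv"))
    write_lms(ref, path)
    back <- read_lms(path)
    expect_equal(back$M, ref$M, tolerance = 1e-9)
    expect_equal(back$sex, ref$sex)
  }
})
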