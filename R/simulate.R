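# Synthetic study generator. Emulates the structure of the real cohort: 61
# adolescents (34 F / 27 M) starting near age 10.33 y, measured roughly
# monthly from September 2019 to October 2020 with a January school-holiday
# gap and an April-May 2020 lockdown gap; integer Retzius periodicities on
# 5-10 days with sex-specific distributions (female mode 8, male mode 6);
# and an expected 14-month weight gain that is quadratic in log10(RP) with
# its optimum between 7 and 8 days, plus a seasonal oscillation and a
# lockdown bump confined to slower (RP >= 7) biorhythms.
#
# Heights follow per-participant Preece-Baines model 1 curves, which have an
# analytic velocity and hence an analytic peak-height-velocity age — the
# oracle used to validate the smoother and the maturity staging.

#' Preece-Baines model 1 height
#'
#' `h(t) = h1 - 2 (h1 - h_theta) / (exp(s0 (t - theta)) + exp(s1 (t - theta)))`.
#'
#' @param t Age(s) in years.
#' @param h1 Adult height (cm).
#' @param h_theta Height at age `theta` (cm).
#' @param s0,s1 Rate constants (1/yr), `s0 < s1`.
#' @param theta Timing parameter (yr), near the age at peak velocity.
#' @return Height in cm.
#' @export
pb1_height <- function(t, h1, h_theta, s0, s1, theta) {
  tau <- t - theta
  h1 - 2 * (h1 - h_theta) / (exp(s0 * tau) + exp(s1 * tau))
}

#' Analytic Preece-Baines model 1 velocity
#'
#' Closed-form derivative of [pb1_height()], in cm/yr.
#'
#' @inheritParams pb1_height
#' @return Velocity in cm/yr.
#' @export
pb1_velocity <- function(t, h1, h_theta, s0, s1, theta) {
  tau <- t - theta
  e0 <- exp(s0 * tau); e1 <- exp(s1 * tau)
  2 * (h1 - h_theta) * (s0 * e0 + s1 * e1) / (e0 + e1)^2
}

#' Analytic age at peak height velocity
#'
#' Maximises [pb1_velocity()] over `[theta - 4, theta + 2]`.
#'
#' @inheritParams pb1_height
#' @return Age in years at the velocity maximum.
#' @export
pb1_phv_age <- function(h1, h_theta, s0, s1, theta) {
  stats::optimize(function(t) pb1_velocity(t, h1, h_theta, s0, s1, theta),
                  interval = c(theta - 4, theta + 2), maximum = TRUE)$maximum
}

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions; see the methods vignette
#' for the reasoning behind each value.
#'
#' @param seed Base RNG seed.
#' @param n_female,n_male Cohort sizes.
#' @param start_age_mean,start_age_sd Starting-age distribution (years).
#' @param visit_months First-of-month dates of the visit schedule.
#' @param visit_day_jitter_sd SD (days) of each participant's visit-day offset.
#' @param rp_support Integer RP support (days).
#' @param rp_probs_female,rp_probs_male Probability vectors over `rp_support`.
#' @param gain_peak_female,gain_peak_male Expected 14-month weight gain (kg)
#'   at the optimum RP, by sex.
#' @param gain_opt_rp RP (days) at which expected gain peaks.
#' @param gain_curvature Quadratic coefficient of log10(expected gain) in
#'   log10(RP); negative opens the curve downwards, 0 removes the RP effect.
#' @param gain_sd_log10 Between-participant SD of log10 gain.
#' @param seasonal_amplitude Amplitude (kg) of the seasonal weight
#'   oscillation (summer trough, winter crest; Southern Hemisphere).
#' @param lockdown_bump Extra weight (kg) accrued across the lockdown window
#'   by participants with RP >= `lockdown_rp_min`.
#' @param lockdown_rp_min Minimum RP receiving the lockdown bump.
#' @param lockdown_window Length-2 `Date` vector of the lockdown.
#' @param noise_height_cm,noise_weight_kg,noise_leg_cm Measurement noise SDs.
#' @param leg_fraction Lower-leg length as a fraction of height.
#' @param start_bmi_mean,start_bmi_sd Starting BMI distribution (kg/m^2).
#' @param pb_female,pb_male Named lists of Preece-Baines parameter means and
#'   SDs: `h1_mean, h1_sd, drop_mean, drop_sd` (`drop = h1 - h_theta`),
#'   `s0_mean, s0_sd, s1_mean, s1_sd, theta_mean, theta_sd`.
#' @param miscount_rate Per-count probability of a one-day miscount in
#'   simulated cross-striation counts.
#' @param histology_noise_cv Coefficient of variation of simulated enamel
#'   length measurements.
#' @param dsr_mean,dsr_sd Daily secretion rate distribution (um/day).
#' @param p_count_visible Probability that a simulated field has countable
#'   cross striations (otherwise only the DSR-ratio route is available).
#' @return A `sim_config` list.
#' @export
sim_config <- function(
    seed = 1L,
    n_female = 34L, n_male = 27L,
    start_age_mean = 10.33, start_age_sd = 0.57,
    visit_months = as.Date(c(
      "2019-09-01", "2019-10-01", "2019-11-01", "2019-12-01",
      "2020-02-01", "2020-03-01", "2020-06-01", "2020-07-01",
      "2020-08-01", "2020-09-01", "2020-10-01")),
    visit_day_jitter_sd = 3,
    rp_support = 5:10,
    rp_probs_female = c(0.06, 0.21, 0.18, 0.29, 0.17, 0.09),
    rp_probs_male = c(0.08, 0.36, 0.22, 0.19, 0.11, 0.04),
    gain_peak_female = 7.8, gain_peak_male = 6.8,
    gain_opt_rp = 7.6, gain_curvature = -25.5, gain_sd_log10 = 0.35,
    seasonal_amplitude = 0.4,
    lockdown_bump = 2.0, lockdown_rp_min = 7L,
    lockdown_window = as.Date(c("2020-03-25", "2020-06-08")),
    noise_height_cm = 0.3, noise_weight_kg = 0.25, noise_leg_cm = 0.2,
    leg_fraction = 0.27,
    start_bmi_mean = 18.5, start_bmi_sd = 2.2,
    pb_female = list(h1_mean = 166, h1_sd = 5.5, drop_mean = 13.5, drop_sd = 1.5,
                     s0_mean = 0.11, s0_sd = 0.012, s1_mean = 1.25, s1_sd = 0.12,
                     theta_mean = 11.4, theta_sd = 0.6),
    pb_male = list(h1_mean = 177, h1_sd = 6.0, drop_mean = 14.0, drop_sd = 1.6,
                   s0_mean = 0.105, s0_sd = 0.012, s1_mean = 1.20, s1_sd = 0.12,
                   theta_mean = 13.6, theta_sd = 0.8),
    miscount_rate = 0.02,
    histology_noise_cv = 0.03,
    dsr_mean = 4.0, dsr_sd = 0.3,
    p_count_visible = 0.8) {
  cfg <- as.list(environment())
  for (p in list(cfg$rp_probs_female, cfg$rp_probs_male)) {
    if (length(p) != length(cfg$rp_support) || abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
      stop("RP probability vectors must be non-negative, match the support, and sum to 1",
           call. = FALSE)
    }
  }
  stopifnot(cfg$noise_height_cm >= 0, cfg$noise_weight_kg >= 0, cfg$noise_leg_cm >= 0,
            cfg$gain_sd_log10 >= 0)
  structure(cfg, class = "sim_config")
}

# Expected 14-month weight gain (kg) as a function of RP and sex:
# log10 E[gain] = log10(peak_sex) + curvature * (log10(rp) - log10(opt))^2.
expected_gain <- function(rp, sex, config) {
  peak <- ifelse(sex == "female", config$gain_peak_female, config$gain_peak_male)
  peak * 10^(config$gain_curvature * (log10(rp) - log10(config$gain_opt_rp))^2)
}

seasonal_level <- function(date, amplitude) {
  yday <- as.POSIXlt(date)$yday
  -amplitude * cos(2 * pi * (yday / 365 - 0.04))
}

lockdown_ramp <- function(date, window) {
  num <- as.numeric(pmin(pmax(date, window[1]), window[2]) - window[1])
  den <- as.numeric(window[2] - window[1])
  num / den
}

#' Simulate a longitudinal cohort with known ground truth
#'
#' Generates roster, measurement records and per-participant truth under the
#' configured study conditions. RNG streams are split per participant, so
#' enlarging the cohort never perturbs existing participants' draws; the
#' truth table is returned separately and never leaks into the cohort files.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (an `rp_cohort`), `truth` (tibble:
#'   `participant_id`, `sex`, `rp_days`, `start_age`, `phv_age`,
#'   `stage_truth`, `expected_gain`, `dsr`, Preece-Baines parameters) and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  n <- config$n_female + config$n_male
  sexes <- c(rep("female", config$n_female), rep("male", config$n_male))
  ids <- sprintf("P%03d", seq_len(n))

  participants <- list(); records <- list(); truth <- list()
  for (i in seq_len(n)) {
    res <- with_local_seed(derive_seed(config$seed, i), {
      sex <- sexes[i]
      pb <- if (sex == "female") config$pb_female else config$pb_male
      h1 <- stats::rnorm(1, pb$h1_mean, pb$h1_sd)
      drop <- max(stats::rnorm(1, pb$drop_mean, pb$drop_sd), 5)
      s0 <- max(stats::rnorm(1, pb$s0_mean, pb$s0_sd), 0.03)
      s1 <- max(stats::rnorm(1, pb$s1_mean, pb$s1_sd), 0.5)
      theta <- stats::rnorm(1, pb$theta_mean, pb$theta_sd)
      start_age <- stats::rnorm(1, config$start_age_mean, config$start_age_sd)

      probs <- if (sex == "female") config$rp_probs_female else config$rp_probs_male
      rp <- sample(config$rp_support, 1, prob = probs)
      dsr <- max(stats::rnorm(1, config$dsr_mean, config$dsr_sd), 1)

      day_offset <- 14 + round(stats::rnorm(1, 0, config$visit_day_jitter_sd))
      visit_dates <- config$visit_months + pmax(pmin(day_offset, 27), 1)
      birth_date <- visit_dates[1] - round(start_age * DAYS_PER_YEAR)
      ages <- decimal_age(birth_date, visit_dates)

      g_mean <- expected_gain(rp, sex, config)
      gain <- g_mean * 10^stats::rnorm(1, 0, config$gain_sd_log10)
      bump <- if (rp >= config$lockdown_rp_min) config$lockdown_bump else 0

      height_true <- pb1_height(ages, h1, h1 - drop, s0, s1, theta)
      bmi0 <- max(stats::rnorm(1, config$start_bmi_mean, config$start_bmi_sd), 14)
      w0 <- bmi0 * (height_true[1] / 100)^2
      frac <- as.numeric(visit_dates - visit_dates[1]) /
        as.numeric(visit_dates[length(visit_dates)] - visit_dates[1])
      weight_true <- w0 + gain * frac +
        seasonal_level(visit_dates, config$seasonal_amplitude) -
        seasonal_level(visit_dates[1], config$seasonal_amplitude) +
        bump * lockdown_ramp(visit_dates, config$lockdown_window)
      leg_true <- config$leg_fraction * height_true

      nv <- length(visit_dates)
      rec <- tibble::tibble(
        participant_id = ids[i],
        visit_date = visit_dates,
        height_cm = height_true + stats::rnorm(nv, 0, config$noise_height_cm),
        leg_length_cm = leg_true + stats::rnorm(nv, 0, config$noise_leg_cm),
        weight_kg = pmax(weight_true + stats::rnorm(nv, 0, config$noise_weight_kg), 10)
      )
      stage_truth <- stage_from_velocity(
        ages, pb1_velocity(ages, h1, h1 - drop, s0, s1, theta))$stage
      list(
        participant = tibble::tibble(participant_id = ids[i], sex = sex,
                                     birth_date = birth_date,
                                     ethnicity = NA_character_),
        records = rec,
        truth = tibble::tibble(
          participant_id = ids[i], sex = sex, rp_days = rp,
          start_age = ages[1], phv_age = pb1_phv_age(h1, h1 - drop, s0, s1, theta),
          stage_truth = stage_truth,
          expected_gain = weight_true[nv] - weight_true[1],
          dsr = dsr, h1 = h1, h_theta = h1 - drop, s0 = s0, s1 = s1, theta = theta)
      )
    })
    participants[[i]] <- res$participant
    records[[i]] <- res$records
    truth[[i]] <- res$truth
  }
  cohort <- new_cohort(dplyr::bind_rows(participants), dplyr::bind_rows(records))
  list(cohort = cohort, truth = dplyr::bind_rows(truth), config = config)
}

#' Simulate enamel histology fields for one participant
#'
#' Produces `n_fields` measurement fields (alternating between a first and a
#' second primary molar, so the two-matching-estimates inclusion rule is
#' exercised both across and within teeth). Cross-striation counts equal the
#' true RP up to occasional one-day miscounts; prism spans are `5 * dsr` with
#' multiplicative mean-zero noise of coefficient of variation `noise_cv`, and
#' Retzius spans are sums of `k - 1` repeat intervals of width `rp * dsr`,
#' each carrying independent noise of the same coefficient of variation.
#'
#' @param true_rp True integer periodicity (days).
#' @param dsr Daily secretion rate (um/day).
#' @param n_fields Number of fields (default 4: two per tooth).
#' @param noise_cv Coefficient of variation of length measurements.
#' @param miscount_rate Per-count probability of a +/-1 day miscount.
#' @param p_count_visible Probability a field has countable striations.
#' @param seed RNG seed.
#' @param participant_id Participant label.
#' @return Tibble in the [read_histology()] layout.
#' @export
simulate_histology <- function(true_rp, dsr = 4, n_fields = 4L, noise_cv = 0.03,
                               miscount_rate = 0.02, p_count_visible = 1,
                               seed = 1L, participant_id = "P001") {
  stopifnot(true_rp >= 1, dsr > 0, n_fields >= 1)
  with_local_seed(seed, {
    teeth <- rep(c("Lm1", "Lm2"), length.out = n_fields)
    field <- stats::ave(seq_len(n_fields), teeth, FUN = seq_along)
    rows <- lapply(seq_len(n_fields), function(j) {
      visible <- stats::runif(1) < p_count_visible
      counts <- if (visible) {
        flips <- stats::rbinom(3, 1, miscount_rate) * sample(c(-1, 1), 3, replace = TRUE)
        pmax(true_rp + flips, 1)
      } else numeric(0)
      spans <- 5 * dsr * (1 + stats::rnorm(6, 0, noise_cv))
      k <- sample(4:6, 1)
      # each of the k-1 repeat intervals varies independently, so the
      # measured span across them averages the interval-level noise down
      rspan <- true_rp * dsr * sum(1 + stats::rnorm(k - 1, 0, noise_cv))
      tibble::tibble(
        participant_id = participant_id,
        tooth_id = teeth[j],
        field_id = paste0(teeth[j], "_", LETTERS[field[j]]),
        method_hint = if (visible) "count" else "dsr_ratio",
        striation_counts = list(counts),
        prism_spans_um = list(pmax(spans, 0.1)),
        retzius_span_um = max(rspan, 0.1),
        retzius_line_count = k,
        stress_excluded = FALSE,
        oblique_excluded = FALSE
      )
    })
    dplyr::bind_rows(rows)
  })
}

#' Simulate histology for a whole simulated cohort
#'
#' @param truth Truth tibble from [simulate_cohort()].
#' @param config The matching [sim_config()].
#' @param n_fields Fields per participant (default 4).
#' @return Tibble in the [read_histology()] layout covering all participants.
#' @export
simulate_cohort_histology <- function(truth, config, n_fields = 4L) {
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    simulate_histology(
      true_rp = truth$rp_days[i], dsr = truth$dsr[i], n_fields = n_fields,
      noise_cv = config$histology_noise_cv,
      miscount_rate = config$miscount_rate,
      p_count_visible = config$p_count_visible,
      seed = derive_seed(config$seed, 100000L + i),
      participant_id = truth$participant_id[i])
  })
  dplyr::bind_rows(rows)
}

#' Write a simulated study to disk
#'
#' Emits `roster.csv`, `measurements.csv`, `histology.csv`,
#' `lms_bmi_synthetic.csv`, `lms_height_synthetic.csv` and `truth.csv`
#' under `dir`.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(sim$cohort, file.path(dir, "measurements.csv"), file.path(dir, "roster.csv"))
  hist <- simulate_cohort_histology(sim$truth, sim$config)
  write_histology(hist, file.path(dir, "histology.csv"))
  write_lms(synthetic_lms_reference("bmi"), file.path(dir, "lms_bmi_synthetic.csv"))
  write_lms(synthetic_lms_reference("height"), file.path(dir, "lms_height_synthetic.csv"))
  readr::write_csv(sim$truth, file.path(dir, "truth.csv"), na = "", eol = "\n")
  invisible(dir)
}
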