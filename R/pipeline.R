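# Full analysis pipeline: RP inclusion -> growth modelling and staging ->
# anthropometric derivations -> association statistics, assembled into a
# structured report whose sections mirror the study's result groups:
# descriptive margins, sex-difference tests, quadratic fits of log gains on
# log RP across window lengths, RP-group comparisons, obesity contingency,
# sex-stratified comparisons, partial correlation, standardised betas,
# seasonal/lockdown gains, and inter-molar RP concordance.

#' Pipeline configuration
#'
#' Every analysis threshold used by [run_pipeline()], resolved once and
#' embedded in the report for reproducibility.
#'
#' @param bandwidth,robust_iterations Growth-smoother settings.
#' @param staging Thresholds from [staging_config()].
#' @param study_start,study_end Full analysis window (dates).
#' @param gain_windows Named list of `c(start, end)` date pairs for the
#'   interval-gain quadratic fits.
#' @param monthly_weight_months First-of-month dates whose average monthly
#'   weights get their own quadratic fits.
#' @param rp_groups RP values compared in the group tests (default 6, 7, 8).
#' @param rp_low,rp_high RP values forming the faster/slower contingency
#'   groups (default 5-6 vs 7-8).
#' @param monthly_rp_range RP values retained in the monthly-weight fits.
#' @param obesity_percentile Obesity cut-off percentile (default 95).
#' @param gain_outlier_policy,bmi_outlier_policy Tukey-fence policies applied
#'   to the responses of the gain and BMI-change fits.
#' @param lockdown Lockdown window (dates) for period labelling.
#' @param seasonal_windows Named list of `c(start, end)` date pairs
#'   partitioning the study for the seasonal gain table.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(
    bandwidth = 1.75, robust_iterations = 2L,
    staging = staging_config(),
    study_start = as.Date("2019-09-01"), study_end = as.Date("2020-10-31"),
    gain_windows = list(
      gain_12mo = as.Date(c("2019-09-01", "2020-08-31")),
      gain_13mo = as.Date(c("2019-09-01", "2020-09-30")),
      gain_14mo = as.Date(c("2019-09-01", "2020-10-31")),
      gain_15mo = as.Date(c("2019-09-01", "2020-11-30"))),
    monthly_weight_months = as.Date(c("2020-08-01", "2020-09-01", "2020-10-01")),
    rp_groups = c(6L, 7L, 8L),
    rp_low = c(5L, 6L), rp_high = c(7L, 8L),
    monthly_rp_range = 5:9,
    obesity_percentile = 95,
    gain_outlier_policy = "extreme_3_0",
    bmi_outlier_policy = "boxplot_1_5",
    lockdown = as.Date(c("2020-03-25", "2020-06-08")),
    seasonal_windows = list(
      spring_2019 = as.Date(c("2019-09-01", "2019-12-01")),
      summer = as.Date(c("2019-12-01", "2020-03-01")),
      lockdown = as.Date(c("2020-03-01", "2020-07-01")),
      winter_2020 = as.Date(c("2020-07-01", "2020-09-01")),
      spring_2020 = as.Date(c("2020-09-01", "2020-11-01")))) {
  structure(as.list(environment()), class = "pipeline_config")
}

# Per-participant BMI series from visits where both height and weight exist.
bmi_series <- function(cohort, participant_id) {
  r <- cohort$records[cohort$records$participant_id == participant_id, ]
  r <- r[!is.na(r$height_cm) & !is.na(r$weight_kg), ]
  r <- r[order(r$visit_date), ]
  p <- cohort$participants[cohort$participants$participant_id == participant_id, ]
  tibble::tibble(
    visit_date = r$visit_date,
    age_years = decimal_age(p$birth_date[1], r$visit_date),
    value = if (nrow(r) > 0) bmi(r$weight_kg, r$height_cm) else numeric(0)
  )
}

#' Build the per-participant analysis frame
#'
#' Joins participant RP (after the inclusion rule), maturity stage, interval
#' gains for each configured window, BMI change, average weight, and start /
#' end BMI percentiles into one tibble — the input to every association
#' analysis.
#'
#' @param cohort An `rp_cohort`.
#' @param rp_table Output of [apply_inclusion_rule()].
#' @param stages Stage tibble from [assign_maturity()].
#' @param lms_bmi BMI-for-age `lms_reference`.
#' @param config A [pipeline_config()].
#' @return One row per participant.
#' @export
build_analysis_frame <- function(cohort, rp_table, stages, lms_bmi,
                                 config = pipeline_config()) {
  ids <- cohort$participants$participant_id
  rows <- lapply(ids, function(id) {
    p <- cohort$participants[cohort$participants$participant_id == id, ]
    w <- participant_series(cohort, id, "weight")
    h <- participant_series(cohort, id, "height")
    l <- participant_series(cohort, id, "leg_length")
    b <- bmi_series(cohort, id)
    full <- c(config$study_start, config$study_end)
    gains <- lapply(config$gain_windows, function(win) interval_gain(w, win)$gain)
    g14 <- interval_gain(w, full)
    out <- tibble::tibble(
      participant_id = id,
      sex = as.character(p$sex),
      start_age = if (nrow(w) > 0) w$age_years[1] else NA_real_,
      weight_gain = g14$gain,
      adjusted_gain_14mo = g14$adjusted_gain_14mo,
      height_gain = interval_gain(h, full)$gain,
      leg_gain = interval_gain(l, full)$gain,
      bmi_change = interval_gain(b, full)$gain,
      avg_weight = average_weight(w, full),
      start_bmi = if (nrow(b) > 0) b$value[1] else NA_real_,
      end_bmi = if (nrow(b) > 0) b$value[nrow(b)] else NA_real_,
      start_bmi_pct = if (nrow(b) > 0)
        bmi_percentile(b$value[1], as.character(p$sex), b$age_years[1], lms_bmi)$percentile
        else NA_real_,
      end_bmi_pct = if (nrow(b) > 0)
        bmi_percentile(b$value[nrow(b)], as.character(p$sex),
                       b$age_years[nrow(b)], lms_bmi)$percentile
        else NA_real_
    )
    for (nm in names(gains)) out[[nm]] <- gains[[nm]]
    out
  })
  frame <- dplyr::bind_rows(rows)
  frame <- dplyr::left_join(
    frame,
    rp_table[, c("participant_id", "included", "rp_days")],
    by = "participant_id")
  dplyr::left_join(frame, stages[, c("participant_id", "stage", "phv_age")],
                   by = "participant_id")
}

quad_on_log <- function(frame, response_col, config, policy,
                        reflect = FALSE, rp_subset = NULL) {
  d <- frame[frame$included %in% TRUE & !is.na(frame$rp_days), ]
  if (!is.null(rp_subset)) d <- d[d$rp_days %in% rp_subset, ]
  y_raw <- d[[response_col]]
  keep <- !is.na(y_raw)
  if (!reflect) keep <- keep & y_raw > 0
  d <- d[keep, ]; y_raw <- y_raw[keep]
  n_dropped <- sum(!keep)
  trans <- transform_log(y_raw, if (reflect) "reflect_then_log10" else "log10")
  fit <- quadratic_fit(log10(d$rp_days), trans$transformed, exclude_outliers = policy)
  fit$analysis <- response_col
  fit$transform <- trans$mode
  fit$reflect_K <- trans$K
  fit$n_nonpositive_dropped <- n_dropped
  fit$vertex_rp <- if (!is.na(fit$vertex_x)) 10^fit$vertex_x else NA_real_
  fit[, c("analysis", "intercept", "b1", "b2", "r", "r2", "p", "p_b2", "n",
          "n_excluded", "n_nonpositive_dropped", "vertex_rp", "transform",
          "reflect_K")]
}

#' Run the full analysis pipeline
#'
#' Executes every stage in fixed order on validated inputs and returns the
#' structured report. Deterministic: identical inputs and configuration give
#' an identical report.
#'
#' @param cohort An `rp_cohort`.
#' @param histology Histology tibble ([read_histology()] layout).
#' @param lms_bmi BMI-for-age `lms_reference`.
#' @param lms_height Optional height-for-age `lms_reference` (used for the
#'   short-for-age flag in staging).
#' @param config A [pipeline_config()].
#' @return An `rp_report`: named list with sections `descriptive`,
#'   `sex_differences`, `quadratic_fits`, `rp_group_comparison`,
#'   `obesity_contingency`, `sex_stratified`, `partial_correlation`,
#'   `standardized_betas`, `seasonal_lockdown`, `rp_concordance`, plus
#'   `frame` (the analysis frame) and the resolved `config`.
#' @export
run_pipeline <- function(cohort, histology, lms_bmi,
                         lms_height = NULL, config = pipeline_config()) {
  diags <- validate_cohort(cohort)
  if (nrow(diags) > 0) {
    stop("cohort fails validation; first issue: ", diags$message[1], call. = FALSE)
  }

  estimates <- estimate_rp(histology)
  rp_table <- apply_inclusion_rule(estimates)

  staging <- assign_maturity(cohort, "height", bandwidth = config$bandwidth,
                             robust_iterations = config$robust_iterations,
                             lms_height = lms_height, config = config$staging)
  frame <- build_analysis_frame(cohort, rp_table, staging$stages, lms_bmi, config)

  inc <- frame[frame$included %in% TRUE, ]

  # -- descriptive margins (per sex and pooled) ------------------------------
  descr_one <- function(d, label) {
    tibble::tibble(
      group = label, n = nrow(d),
      rp_mode = if (nrow(d) > 0) {
        tb <- table(d$rp_days); as.integer(names(tb)[which.max(tb)])
      } else NA_integer_,
      rp_mean = mean(d$rp_days, na.rm = TRUE),
      rp_sd = stats::sd(d$rp_days, na.rm = TRUE),
      start_age_mean = mean(d$start_age, na.rm = TRUE),
      start_age_sd = stats::sd(d$start_age, na.rm = TRUE),
      weight_gain_mean = mean(d$weight_gain, na.rm = TRUE),
      weight_gain_sd = stats::sd(d$weight_gain, na.rm = TRUE),
      height_gain_mean = mean(d$height_gain, na.rm = TRUE),
      leg_gain_mean = mean(d$leg_gain, na.rm = TRUE),
      bmi_change_mean = mean(d$bmi_change, na.rm = TRUE),
      end_bmi_pct_mean = mean(d$end_bmi_pct, na.rm = TRUE),
      stage_1 = sum(d$stage == 1, na.rm = TRUE),
      stage_2 = sum(d$stage == 2, na.rm = TRUE),
      stage_3 = sum(d$stage == 3, na.rm = TRUE),
      stage_4 = sum(d$stage == 4, na.rm = TRUE)
    )
  }
  descriptive <- dplyr::bind_rows(
    descr_one(inc, "all"),
    descr_one(inc[inc$sex == "female", ], "female"),
    descr_one(inc[inc$sex == "male", ], "male"))

  # -- sex differences in gains ---------------------------------------------
  sex_test <- function(col) {
    f <- inc[[col]][inc$sex == "female"]; m <- inc[[col]][inc$sex == "male"]
    res <- t_test_two_tailed(f, m)
    res$variable <- col
    res[, c("variable", "t", "df", "p", "mean_a", "mean_b", "n_a", "n_b")]
  }
  sex_differences <- dplyr::bind_rows(lapply(
    c("weight_gain", "height_gain", "bmi_change", "leg_gain"), sex_test))

  # -- quadratic fits of log gains / average weight on log RP ---------------
  gain_fits <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(names(config$gain_windows), function(nm)
      quad_on_log(frame, nm, config, config$gain_outlier_policy))),
    quad_on_log(frame, "adjusted_gain_14mo", config, config$gain_outlier_policy),
    quad_on_log(frame, "bmi_change", config, config$bmi_outlier_policy,
                reflect = TRUE,
                rp_subset = setdiff(sort(unique(frame$rp_days)), 10L)))
  bf_g <- bonferroni_adjust(gain_fits$p, m = nrow(gain_fits))
  gain_fits$bonferroni_threshold <- bf_g$threshold
  gain_fits$significant_bonferroni <- bf_g$significant

  avg_overall <- quad_on_log(frame, "avg_weight", config, config$gain_outlier_policy)
  monthly_fits <- dplyr::bind_rows(lapply(config$monthly_weight_months, function(m0) {
    month_end <- seq(m0, by = "1 month", length.out = 2)[2] - 1
    col <- paste0("avg_weight_", format(m0, "%Y_%m"))
    frame[[col]] <- vapply(frame$participant_id, function(id) {
      w <- participant_series(cohort, id, "weight")
      average_weight(w, c(m0, month_end))
    }, numeric(1))
    quad_on_log(frame, col, config, "none", rp_subset = config$monthly_rp_range)
  }))
  weight_fits <- dplyr::bind_rows(avg_overall, monthly_fits)
  bf_w <- bonferroni_adjust(weight_fits$p, m = nrow(weight_fits))
  weight_fits$bonferroni_threshold <- bf_w$threshold
  weight_fits$significant_bonferroni <- bf_w$significant

  # -- RP-group comparisons (largest groups) --------------------------------
  grp <- inc[inc$rp_days %in% config$rp_groups, ]
  rp_group_comparison <- list(
    weight_gain = kruskal_wallis_mc(grp$weight_gain, grp$rp_days),
    bmi_change = kruskal_wallis_mc(grp$bmi_change, grp$rp_days))

  # -- obesity contingency at start and end ---------------------------------
  contingency <- function(pct_col) {
    d <- inc[inc$rp_days %in% c(config$rp_low, config$rp_high) & !is.na(inc[[pct_col]]), ]
    obese <- classify_obesity(d[[pct_col]], config$obesity_percentile)
    high <- d$rp_days %in% config$rp_high
    tab <- rbind(c(sum(high & obese), sum(high & !obese)),
                 c(sum(!high & obese), sum(!high & !obese)))
    res <- tryCatch(chi_square_rr(tab), error = function(e) {
      # zero reference-risk cell: RR undefined; keep chi-square and a
      # Haldane-corrected OR where the margins still allow them
      chi <- tryCatch({
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        c(unname(ct$statistic), ct$p.value)
      }, error = function(e2) c(NA_real_, NA_real_))
      or <- ((tab[1, 1] + 0.5) * (tab[2, 2] + 0.5)) /
        ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
      tibble::tibble(chi_sq = chi[1], df = 1L, p = chi[2],
                     relative_risk = NA_real_, odds_ratio = or,
                     or_corrected = TRUE, n = sum(tab))
    })
    res$a <- tab[1, 1]; res$b <- tab[1, 2]; res$c <- tab[2, 1]; res$d <- tab[2, 2]
    res
  }
  obesity_contingency <- list(start = contingency("start_bmi_pct"),
                              end = contingency("end_bmi_pct"))

  # -- sex-stratified RP-group comparisons ----------------------------------
  strat <- function(sex, col) {
    d <- inc[inc$sex == sex & inc$rp_days %in% 6:9 & !is.na(inc[[col]]), ]
    if (nrow(d) >= 5 && length(unique(d$rp_days)) >= 2) {
      kruskal_wallis_mc(d[[col]], d$rp_days)
    } else {
      list(summary = tibble::tibble(H = NA_real_, df = NA_integer_,
                                    p = NA_real_, n = nrow(d)))
    }
  }
  sex_stratified <- list(
    female_weight_gain = strat("female", "weight_gain"),
    female_bmi_change = strat("female", "bmi_change"),
    male_weight_gain = strat("male", "weight_gain"),
    male_bmi_change = strat("male", "bmi_change"))

  # -- partial correlation: RP vs gain controlling starting age -------------
  pc_dat <- inc[!is.na(inc$weight_gain) & inc$weight_gain > 0 & !is.na(inc$start_age), ]
  partial_correlation <- list(
    pearson = correlation(log10(pc_dat$rp_days), log10(pc_dat$weight_gain)),
    partial_given_start_age = correlation(log10(pc_dat$rp_days),
                                          log10(pc_dat$weight_gain),
                                          controls = list(pc_dat$start_age)))

  # -- standardised betas ---------------------------------------------------
  sb_frame <- function(d) {
    d <- d[!is.na(d$weight_gain) & d$weight_gain > 0 &
             !is.na(d$height_gain) & d$height_gain > 0 &
             !is.na(d$leg_gain) & d$leg_gain > 0, ]
    if (nrow(d) < 5) return(tibble::tibble(predictor = character(),
                                           beta = numeric(), p = numeric(),
                                           n = integer()))
    standardized_betas(log10(d$rp_days), list(
      weight_gain = log10(d$weight_gain),
      height_gain = log10(d$height_gain),
      leg_gain = log10(d$leg_gain)))
  }
  standardized_beta_tables <- list(
    all = sb_frame(inc),
    females_stage3 = sb_frame(inc[inc$sex == "female" & inc$stage %in% 3L, ]))

  # -- seasonal / lockdown gains by RP group --------------------------------
  seasonal_rows <- lapply(names(config$seasonal_windows), function(period) {
    win <- config$seasonal_windows[[period]]
    per_part <- vapply(inc$participant_id, function(id) {
      interval_gain(participant_series(cohort, id, "weight"), win)$gain
    }, numeric(1))
    d <- tibble::tibble(rp_days = inc$rp_days, gain = per_part)
    d <- d[!is.na(d$gain) & d$rp_days %in% config$rp_groups, ]
    d |>
      dplyr::group_by(.data$rp_days) |>
      dplyr::summarise(mean_gain = mean(.data$gain), n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(period = period, .before = 1)
  })
  seasonal_lockdown <- dplyr::bind_rows(seasonal_rows)

  # -- inter-molar RP concordance -------------------------------------------
  multi <- rp_table[rp_table$n_teeth >= 2, ]
  rp_concordance <- tibble::tibble(
    n_participants = nrow(rp_table),
    n_included = sum(rp_table$included),
    n_multi_tooth = nrow(multi),
    n_concordant = sum(multi$concordant_teeth),
    prop_concordant = ifelse(nrow(multi) > 0,
                             sum(multi$concordant_teeth) / nrow(multi), NA_real_))

  structure(list(
    descriptive = descriptive,
    sex_differences = sex_differences,
    quadratic_fits = list(gains = gain_fits, average_weight = weight_fits),
    rp_group_comparison = rp_group_comparison,
    obesity_contingency = obesity_contingency,
    sex_stratified = sex_stratified,
    partial_correlation = partial_correlation,
    standardized_betas = standardized_beta_tables,
    seasonal_lockdown = seasonal_lockdown,
    rp_concordance = rp_concordance,
    frame = frame,
    rp_table = rp_table,
    config = config
  ), class = "rp_report")
}

#' @export
print.rp_report <- function(x, ...) {
  cat("<rp_report> sections:",
      paste(setdiff(names(x), c("frame", "rp_table", "config")), collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a report to JSON
#'
#' @param report An `rp_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- report
  out$config <- lapply(unclass(out$config), function(v)
    if (inherits(v, "Date")) format(v) else v)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null",
                       force = TRUE)
  invisible(path)
}

fmt_tbl <- function(df, digits = 2) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) formatC(v, digits = digits, format = "f"))
  widths <- pmax(nchar(names(df)), vapply(df, function(v) max(nchar(v), 0), numeric(1)))
  header <- paste(mapply(formatC, names(df), width = widths), collapse = "  ")
  rows <- apply(df, 1, function(r) paste(mapply(formatC, r, width = widths), collapse = "  "))
  paste(c(header, rows), collapse = "\n")
}

#' Render the report's headline tables as text
#'
#' Produces three tables shaped like the study's descriptive, gain-regression
#' and average-weight-regression tables. Empty sections are replaced by a
#' notice.
#'
#' @param report An `rp_report`.
#' @return Named character vector of formatted tables (printed with `cat`).
#' @export
report_to_tables <- function(report) {
  sect <- function(df, title) {
    if (is.null(df) || nrow(df) == 0) {
      paste0(title, "\n[section empty - omitted]")
    } else {
      paste0(title, "\n", fmt_tbl(df))
    }
  }
  c(
    descriptive = sect(report$descriptive,
      "Descriptive statistics (RP, starting age, gains, maturity stages)"),
    gain_regressions = sect(report$quadratic_fits$gains,
      "Quadratic regressions: log gains vs log RP"),
    weight_regressions = sect(report$quadratic_fits$average_weight,
      "Quadratic regressions: log average weight vs log RP")
  )
}
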