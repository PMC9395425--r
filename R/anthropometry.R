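# Derived anthropometric quantities: BMI, LMS-based BMI-for-age percentiles
# and the 95th-percentile obesity classification, interval gains with the
# 14-month adjusted rate, average weights, and Southern-Hemisphere season /
# Covid-19 lockdown period labelling.

#' Body mass index
#'
#' @param weight_kg Weight in kg (> 0).
#' @param height_cm Height in cm (> 0).
#' @return BMI in kg/m^2, unrounded.
#' @examples
#' bmi(50, 100)  # 50
#' @export
bmi <- function(weight_kg, height_cm) {
  if (any(is.na(weight_kg)) || any(is.na(height_cm)) ||
      any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("weight and height must be positive", call. = FALSE)
  }
  weight_kg / (height_cm / 100)^2
}

#' BMI-for-age z-score and percentile
#'
#' LMS transformation of BMI against an age- and sex-specific reference,
#' with the percentile from the standard normal CDF.
#'
#' @param bmi_value BMI in kg/m^2.
#' @param sex `"female"` or `"male"`.
#' @param age Age in years (inside the reference grid).
#' @param ref An `lms_reference` for BMI (see [read_lms()],
#'   [synthetic_lms_reference()]).
#' @return Tibble with `z` and `percentile` (0-100).
#' @export
bmi_percentile <- function(bmi_value, sex, age, ref) {
  z <- lms_zscore(bmi_value, sex, age, ref)
  tibble::tibble(z = z, percentile = stats::pnorm(z) * 100)
}

#' Classify obesity from a BMI percentile
#'
#' @param percentile BMI-for-age percentile in `[0, 100]`.
#' @param threshold Cut-off percentile (default 95; at or above classifies
#'   as obese).
#' @return Logical vector.
#' @export
classify_obesity <- function(percentile, threshold = 95) {
  stopifnot(all(percentile >= 0 & percentile <= 100, na.rm = TRUE))
  percentile >= threshold
}

#' First-to-last gain over a window, with the adjusted 14-month rate
#'
#' The gain is last minus first in-window measurement; the adjusted rate
#' divides by the elapsed time in standard months (30.4375 days) and the
#' adjusted 14-month gain scales that rate to 14 months.
#'
#' @param series Tibble with `visit_date` and `value` (e.g. from
#'   [participant_series()]).
#' @param window Length-2 `Date` vector; defaults to the series range.
#' @return One-row tibble with `window_start`, `window_end`, `first`, `last`,
#'   `gain`, `elapsed_months`, `adjusted_rate`, `adjusted_gain_14mo`, and a
#'   `reason` of `"insufficient observations"` (values `NA`) when fewer than
#'   two in-window measurements exist.
#' @export
interval_gain <- function(series, window = NULL) {
  if (is.null(window)) window <- range(series$visit_date)
  window <- as.Date(window)
  s <- series[!is.na(series$value) &
                series$visit_date >= window[1] & series$visit_date <= window[2], ]
  s <- s[order(s$visit_date), ]
  if (nrow(s) < 2) {
    return(tibble::tibble(
      window_start = window[1], window_end = window[2],
      first = NA_real_, last = NA_real_, gain = NA_real_,
      elapsed_months = NA_real_, adjusted_rate = NA_real_,
      adjusted_gain_14mo = NA_real_, reason = "insufficient observations"))
  }
  elapsed_days <- as.numeric(s$visit_date[nrow(s)] - s$visit_date[1])
  elapsed_months <- elapsed_days / DAYS_PER_MONTH
  gain <- s$value[nrow(s)] - s$value[1]
  tibble::tibble(
    window_start = window[1], window_end = window[2],
    first = s$value[1], last = s$value[nrow(s)], gain = gain,
    elapsed_months = elapsed_months,
    adjusted_rate = gain / elapsed_months,
    adjusted_gain_14mo = gain / elapsed_months * 14,
    reason = NA_character_
  )
}

#' Average weight over a window
#'
#' @param series Tibble with `visit_date` and `value`.
#' @param window Length-2 `Date` vector; defaults to the series range.
#' @param granularity `"overall"` (one mean) or `"monthly"` (mean per
#'   calendar month; months without a visit are absent from the result).
#' @return For `"overall"`, a single numeric (NA when the window is empty);
#'   for `"monthly"`, a tibble with `month` (first-of-month `Date`) and
#'   `mean_value`.
#' @export
average_weight <- function(series, window = NULL,
                           granularity = c("overall", "monthly")) {
  granularity <- match.arg(granularity)
  if (is.null(window)) window <- range(series$visit_date)
  window <- as.Date(window)
  s <- series[!is.na(series$value) &
                series$visit_date >= window[1] & series$visit_date <= window[2], ]
  if (granularity == "overall") {
    if (nrow(s) == 0) return(NA_real_)
    return(mean(s$value))
  }
  if (nrow(s) == 0) return(tibble::tibble(month = as.Date(character()), mean_value = numeric()))
  s$month <- as.Date(format(s$visit_date, "%Y-%m-01"))
  s |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(mean_value = mean(.data$value), .groups = "drop")
}

#' Season and lockdown label for a date
#'
#' Southern-Hemisphere season mapping (summer = Dec-Feb, autumn = Mar-May,
#' winter = Jun-Aug, spring = Sep-Nov) and a configurable national-lockdown
#' window, defaulting to 2020-03-25 through 2020-06-08.
#'
#' @param date `Date` vector.
#' @param lockdown Length-2 `Date` vector bounding the lockdown (inclusive).
#' @return Tibble with `date`, `season` (factor) and `lockdown` (logical).
#' @export
label_period <- function(date, lockdown = as.Date(c("2020-03-25", "2020-06-08"))) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  season <- dplyr::case_when(
    m %in% c(12, 1, 2) ~ "summer",
    m %in% 3:5 ~ "autumn",
    m %in% 6:8 ~ "winter",
    TRUE ~ "spring"
  )
  tibble::tibble(
    date = date,
    season = factor(season, levels = c("summer", "autumn", "winter", "spring")),
    lockdown = date >= lockdown[1] & date <= lockdown[2]
  )
}
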