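# LMS reference engine: age- and sex-specific Box-Cox power (L), median (M)
# and coefficient of variation (S) curves, with linear interpolation in age.
# The engine is generic; any reference table with columns
# sex,age_years,L,M,S can be plugged in. The package ships *synthetic*
# reference tables (generated by synthetic_lms_reference()) so the pipeline
# is runnable without external data; they are plausible but are NOT a
# national growth reference.

#' Read an LMS reference table
#'
#' CSV schema: `sex,age_years,L,M,S` with sex coded `F`/`M`. The age grid
#' must be strictly increasing within sex, with `M > 0` and `S > 0`.
#'
#' @param path CSV path.
#' @return An `lms_reference` tibble.
#' @export
read_lms <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(
    sex = readr::col_character(), age_years = readr::col_double(),
    L = readr::col_double(), M = readr::col_double(), S = readr::col_double()
  ))
  as_lms_reference(raw)
}

#' Coerce a data frame to an LMS reference
#'
#' @param x Data frame with columns `sex` (`F`/`M`), `age_years`, `L`, `M`, `S`.
#' @return An `lms_reference` tibble.
#' @export
as_lms_reference <- function(x) {
  x <- tibble::as_tibble(x)
  stopifnot(all(c("sex", "age_years", "L", "M", "S") %in% names(x)))
  sex_map <- c(F = "female", M = "male", female = "female", male = "male")
  x$sex <- unname(sex_map[as.character(x$sex)])
  if (anyNA(x$sex)) stop("unknown sex code in LMS table", call. = FALSE)
  if (any(x$M <= 0) || any(x$S <= 0)) stop("LMS table requires M > 0 and S > 0", call. = FALSE)
  for (s in unique(x$sex)) {
    ages <- x$age_years[x$sex == s]
    if (any(diff(ages) <= 0)) stop("LMS age grid must strictly increase within sex", call. = FALSE)
  }
  structure(x[order(x$sex, x$age_years), ], class = c("lms_reference", class(x)))
}

interp_lms <- function(ref, sex, age) {
  sex <- as.character(sex)
  sub <- ref[ref$sex == sex, ]
  if (nrow(sub) == 0) stop("no LMS rows for sex '", sex, "'", call. = FALSE)
  rng <- range(sub$age_years)
  if (any(age < rng[1] - 1e-9) || any(age > rng[2] + 1e-9)) {
    stop(sprintf("age %.3g outside LMS reference grid [%.3g, %.3g]",
                 age[age < rng[1] | age > rng[2]][1], rng[1], rng[2]), call. = FALSE)
  }
  if (nrow(sub) == 1) {
    one <- function(v) rep(v, length(age))
    return(list(L = one(sub$L), M = one(sub$M), S = one(sub$S)))
  }
  list(
    L = stats::approx(sub$age_years, sub$L, age, rule = 2)$y,
    M = stats::approx(sub$age_years, sub$M, age, rule = 2)$y,
    S = stats::approx(sub$age_years, sub$S, age, rule = 2)$y
  )
}

#' LMS z-score for a measurement
#'
#' `z = ((x/M)^L - 1) / (L * S)` when `L != 0`, `z = ln(x/M) / S` when
#' `L = 0`, with L, M, S linearly interpolated at `age`.
#'
#' @param value Measurement (same units as the reference median).
#' @param sex `"female"` or `"male"`.
#' @param age Age in years (inside the reference grid).
#' @param ref An `lms_reference`.
#' @return z-score(s).
#' @export
lms_zscore <- function(value, sex, age, ref) {
  p <- interp_lms(ref, sex, age)
  ifelse(abs(p$L) < 1e-12,
         log(value / p$M) / p$S,
         ((value / p$M)^p$L - 1) / (p$L * p$S))
}

#' Synthetic LMS reference tables
#'
#' Generates smooth, plausible BMI-for-age or height-for-age L, M, S curves
#' for ages 5-18 on a quarter-year grid. These are synthetic stand-ins for a
#' national reference (which cannot be redistributed here); swapping in a
#' real reference is a one-file change via [read_lms()].
#'
#' @param measure `"bmi"` (kg/m^2) or `"height"` (cm).
#' @return An `lms_reference` tibble covering both sexes.
#' @export
synthetic_lms_reference <- function(measure = c("bmi", "height")) {
  measure <- match.arg(measure)
  ages <- seq(5, 18, by = 0.25)
  make <- function(sex) {
    if (measure == "bmi") {
      # median BMI rises slowly through late childhood; skewed right (L < 0)
      m0 <- if (sex == "female") 14.6 else 14.8
      M <- m0 + 0.38 * (ages - 5) + 0.012 * (ages - 5)^2
      L <- rep(-1.6, length(ages))
      S <- 0.095 + 0.0035 * (ages - 5)
    } else {
      # median height from a smooth mid-childhood-to-adolescence curve
      if (sex == "female") {
        M <- pb1_height(ages, h1 = 165.5, h_theta = 152.5, s0 = 0.11, s1 = 1.25, theta = 11.7)
      } else {
        M <- pb1_height(ages, h1 = 177.0, h_theta = 163.0, s0 = 0.105, s1 = 1.20, theta = 13.7)
      }
      L <- rep(1, length(ages))
      S <- rep(0.042, length(ages))
    }
    tibble::tibble(sex = sex, age_years = ages, L = L, M = M, S = S)
  }
  as_lms_reference(dplyr::bind_rows(make("female"), make("male")))
}

#' Write an LMS reference table to CSV
#'
#' @param ref An `lms_reference`.
#' @param path Output CSV path (sex re-encoded `F`/`M`).
#' @return The reference, invisibly.
#' @export
write_lms <- function(ref, path) {
  out <- tibble::as_tibble(ref)
  out$sex <- c(female = "F", male = "M")[out$sex]
  readr::write_csv(out, path, na = "", eol = "\n")
  invisible(ref)
}
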