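# Shared numeric conventions used across the package.

# Mean month length in days used for rate normalisation.
DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

#' Round to the nearest integer, ties away from zero
#'
#' Base `round()` rounds halves to even; integer-day Retzius periodicities are
#' reported with halves rounded away from zero instead, so 6.5 becomes 7.
#'
#' @param x Numeric vector.
#' @return Numeric vector of integers (as doubles).
#' @examples
#' round_half_away(c(6.5, -6.5, 6.49))
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Decimal age in years between two dates
#'
#' @param birth_date,at_date `Date` vectors.
#' @return Age in decimal years (days / 365.25).
#' @export
decimal_age <- function(birth_date, at_date) {
  as.numeric(as.Date(at_date) - as.Date(birth_date)) / DAYS_PER_YEAR
}

# Derive a 32-bit-safe positive integer seed from a base seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 7919) %% 2147483629) + 1L
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
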