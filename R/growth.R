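# Fixed-bandwidth kernel-weighted robust local cubic smoothing of
# longitudinal growth series, with the velocity curve taken as the analytic
# derivative of the local polynomial.
#
# At each evaluation age x0 a cubic in (age - x0) is fitted by weighted least
# squares with weights tricube((age - x0)/bandwidth) * robust_weights; the
# intercept is the fitted value and the linear coefficient the velocity.
# Robustness follows the classic lowess scheme: after each pass, residual
# based bisquare weights downweight gross outliers.

#' Tricube kernel
#'
#' @param u Scaled distances; support is `[-1, 1]`.
#' @return Kernel weights `(1 - |u|^3)^3` inside the support, 0 outside.
#' @export
tricube <- function(u) {
  w <- (1 - pmin(abs(u), 1)^3)^3
  w[abs(u) >= 1] <- 0
  w
}

#' Weighted local polynomial fit at one point
#'
#' Fits a polynomial of `degree` in `(ages - x0)` by weighted least squares
#' with weights `tricube((ages - x0)/bandwidth) * robust_weights`. Falls back
#' to a lower degree (with a warning) when fewer effective points than
#' coefficients are available.
#'
#' @param ages,values Observation ages (years) and values (cm).
#' @param x0 Evaluation age.
#' @param bandwidth Kernel half-width in years (> 0).
#' @param robust_weights Optional per-observation weights in `[0, 1]`.
#' @param degree Polynomial degree (default 3, the cubic).
#' @return List with `fitted` (value at `x0`), `velocity` (first derivative
#'   at `x0`, units per year) and `degree` actually used.
#' @export
fit_local_cubic <- function(ages, values, x0, bandwidth,
                            robust_weights = rep(1, length(ages)), degree = 3L) {
  stopifnot(length(ages) == length(values), bandwidth > 0)
  w <- tricube((ages - x0) / bandwidth) * robust_weights
  if (all(w <= 0)) stop("no observations with positive weight at x0 = ", x0, call. = FALSE)
  n_eff <- sum(w > 0)
  deg <- degree
  if (n_eff < degree + 1) {
    deg <- max(0L, n_eff - 1L)
    warning(sprintf(
      "only %d effective point(s) at x0 = %.3g; falling back to degree %d",
      n_eff, x0, deg), call. = FALSE)
  }
  keep <- w > 0
  d <- ages[keep] - x0
  X <- outer(d, 0:deg, `^`)
  fit <- stats::lm.wfit(X, values[keep], w[keep])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  list(fitted = unname(beta[1]),
       velocity = if (deg >= 1) unname(beta[2]) else 0,
       degree = deg)
}

bisquare_weights <- function(residuals) {
  s <- stats::median(abs(residuals))
  if (s <= .Machine$double.eps) return(rep(1, length(residuals)))
  u <- residuals / (6 * s)
  w <- (1 - pmin(abs(u), 1)^2)^2
  w[abs(u) >= 1] <- 0
  w
}

#' Smooth one participant's growth series
#'
#' Iteratively reweighted local cubic smoothing of a measurement series on a
#' monthly evaluation grid across the observed age span. Robust weights start
#' at 1; after each pass, bisquare weights computed from the residuals at the
#' observation ages replace them.
#'
#' @param series Tibble with `age_years` and `value` columns (e.g. from
#'   [participant_series()]).
#' @param bandwidth Kernel half-width in years (default 1.75).
#' @param robust_iterations Number of reweighting passes (default 2).
#' @param grid_step Evaluation grid spacing in years (default 1/12).
#' @param participant_id,variable Labels carried into the result.
#' @return A `growth_curve` object: list with `participant_id`, `variable`,
#'   `curve` (tibble `age_years`, `fitted`, `velocity`), `robust_weights`,
#'   `bandwidth`, `robust_iterations`, `n_obs`. Returns `NULL` invisibly with
#'   a warning when fewer than 6 observations are available (participant
#'   unmodellable).
#' @export
smooth_series <- function(series, bandwidth = 1.75, robust_iterations = 2L,
                          grid_step = 1 / 12, participant_id = NA_character_,
                          variable = "height") {
  ages <- series$age_years
  values <- series$value
  ok <- !is.na(ages) & !is.na(values)
  ages <- ages[ok]; values <- values[ok]
  if (length(ages) < 6) {
    warning("fewer than 6 observations; participant is unmodellable", call. = FALSE)
    return(invisible(NULL))
  }
  o <- order(ages)
  ages <- ages[o]; values <- values[o]

  rw <- rep(1, length(ages))
  for (it in seq_len(robust_iterations)) {
    fitted_at_obs <- vapply(ages, function(x0) {
      suppressWarnings(fit_local_cubic(ages, values, x0, bandwidth, rw)$fitted)
    }, numeric(1))
    rw <- bisquare_weights(values - fitted_at_obs)
    if (all(rw == 0)) rw <- rep(1, length(ages))  # degenerate guard
  }

  grid <- seq(min(ages), max(ages), by = grid_step)
  if (grid[length(grid)] < max(ages) - 1e-9) grid <- c(grid, max(ages))
  fits <- lapply(grid, function(x0) {
    suppressWarnings(fit_local_cubic(ages, values, x0, bandwidth, rw))
  })
  structure(list(
    participant_id = participant_id,
    variable = variable,
    curve = tibble::tibble(
      age_years = grid,
      fitted = vapply(fits, `[[`, numeric(1), "fitted"),
      velocity = vapply(fits, `[[`, numeric(1), "velocity")
    ),
    robust_weights = rw,
    obs = tibble::tibble(age_years = ages, value = values),
    bandwidth = bandwidth,
    robust_iterations = robust_iterations,
    n_obs = length(ages)
  ), class = "growth_curve")
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s %s: %d obs, grid %.2f-%.2f y, bw %.2f y, %d robust pass(es)\n",
              x$participant_id, x$variable, x$n_obs,
              min(x$curve$age_years), max(x$curve$age_years),
              x$bandwidth, x$robust_iterations))
  invisible(x)
}
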