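# Four-level maturity staging from the shape of a smoothed height (or
# lower-leg-length) velocity curve:
#   1 "pre"   — before the pre-spurt minimum velocity (childhood deceleration)
#   2 "early" — past the pre-spurt minimum but not near peak height velocity
#   3 "peak"  — very close to, or just past, peak height velocity (PHV)
#   4 "late"  — clearly past PHV, approaching the adult asymptote
#
# The verbal definitions are qualitative; the quantitative cut-offs live in
# staging_config() and the full decision cascade is documented in the
# methods vignette. The same rule function is applied to analytic generator
# velocities to define simulation truth, so assigned and true stages share
# one definition.

STAGE_LABELS <- c("1" = "pre", "2" = "early", "3" = "peak", "4" = "late")

#' Staging thresholds
#'
#' @param r_min Minimum sustained velocity rise after a local minimum for it
#'   to count as the pre-spurt minimum (cm/yr, default 0.5).
#' @param d_phv Minimum prominence of a velocity maximum above the preceding
#'   minimum for PHV detection (cm/yr, default 1.5).
#' @param f_near Fraction of the running maximum velocity above which the
#'   participant is "near peak" (default 0.85).
#' @param f_late End-of-window velocity below `f_late` times the peak marks
#'   the late stage (default 0.5).
#' @param t_post Years after PHV during which a participant still counts as
#'   at-peak (default 0.75).
#' @param z_short Height-for-age z-score below which a participant is
#'   short-for-age (default 0).
#' @param accel_near End-of-window acceleration (cm/yr^2) at or below which a
#'   still-rising velocity counts as flattening towards its peak
#'   (default 1.5, below typical mid-spurt acceleration).
#' @param v_late_abs Absolute end-of-window velocity (cm/yr) below which a
#'   declining curve counts as approaching the adult asymptote even when the
#'   in-window maximum already sits post-peak (default 2.5).
#' @return Named list of thresholds.
#' @export
staging_config <- function(r_min = 0.5, d_phv = 1.5, f_near = 0.85,
                           f_late = 0.5, t_post = 0.75, z_short = 0,
                           accel_near = 1.5, v_late_abs = 2.5) {
  list(r_min = r_min, d_phv = d_phv, f_near = f_near, f_late = f_late,
       t_post = t_post, z_short = z_short, accel_near = accel_near,
       v_late_abs = v_late_abs)
}

#' Maturity stage from a velocity curve
#'
#' Deterministic staging of a velocity curve sampled on an age grid. Detects
#' the pre-spurt minimum (interior local minimum followed by a sustained rise
#' of at least `r_min`) and PHV (interior local maximum rising at least
#' `d_phv` above the preceding in-window minimum), then applies a fixed
#' cascade; see the methods vignette for the full rule set.
#'
#' @param ages Strictly increasing age grid (years), length >= 8.
#' @param velocity Velocity at each grid age (cm/yr).
#' @param height_z Optional height-for-age z-score at the window end, used
#'   only for the `short_for_age` flag.
#' @param config Thresholds from [staging_config()].
#' @return Tibble: `stage` (integer 1-4), `stage_label`, `prespurt_min_age`,
#'   `phv_age`, `phv_value`, `short_for_age`.
#' @export
stage_from_velocity <- function(ages, velocity, height_z = NA_real_,
                                config = staging_config()) {
  n <- length(velocity)
  stopifnot(length(ages) == n)
  if (n < 8) {
    return(tibble::tibble(stage = NA_integer_, stage_label = NA_character_,
                          prespurt_min_age = NA_real_, phv_age = NA_real_,
                          phv_value = NA_real_, short_for_age = NA,
                          reason = "fewer than 8 grid points"))
  }
  # light moving-average regularisation so landmark detection responds to the
  # curve's shape, not grid-level wiggles; applied identically to analytic
  # truth curves, so the stage definition is unchanged in substance
  v <- stats::filter(velocity, rep(1 / 5, 5), sides = 2)
  v <- as.numeric(v)
  v[is.na(v)] <- velocity[is.na(v)]
  v_end <- v[n]
  v_max <- max(v)

  # pre-spurt minimum: first interior local minimum with a sustained rise
  interior <- 2:(n - 1)
  is_min <- vapply(interior, function(i) v[i] <= v[i - 1] && v[i] <= v[i + 1], logical(1))
  prespurt_idx <- NA_integer_
  for (i in interior[is_min]) {
    if (max(v[i:n]) - v[i] >= config$r_min) { prespurt_idx <- i; break }
  }
  prespurt_detected <- !is.na(prespurt_idx)

  # PHV: interior local maximum with enough prominence over the preceding
  # in-window minimum (the pre-spurt minimum when it falls in the window,
  # the window start otherwise)
  is_max <- vapply(interior, function(j) v[j] >= v[j - 1] && v[j] >= v[j + 1], logical(1))
  phv_idx <- NA_integer_
  cand <- interior[is_max]
  if (length(cand) > 0) {
    prom <- vapply(cand, function(j) v[j] - min(v[1:j]), numeric(1))
    ok <- cand[prom >= config$d_phv]
    if (length(ok) > 0) phv_idx <- ok[which.max(v[ok])]
  }
  phv_detected <- !is.na(phv_idx)

  # flattening: end-of-window acceleration (slope of velocity over the last
  # half year) small enough that the velocity is levelling off towards its peak
  tail_idx <- which(ages >= ages[n] - 0.5)
  if (length(tail_idx) < 2) tail_idx <- c(n - 1, n)
  accel_end <- unname(stats::coef(stats::lm.fit(
    cbind(1, ages[tail_idx]), v[tail_idx]))[2])
  flattening <- accel_end <= config$accel_near

  short_for_age <- if (is.na(height_z)) NA else height_z < config$z_short

  stage <- NA_integer_
  if (phv_detected) {
    past <- ages[n] > ages[phv_idx] + config$t_post
    stage <- if (v_end < config$f_late * v[phv_idx] && past) 4L else 3L
  } else if (prespurt_detected) {
    # near peak only when the spurt is substantially underway and levelling
    near_peak <- (v_end - v[prespurt_idx] >= config$d_phv) && flattening
    stage <- if (near_peak) 3L else 2L
  } else if (which.max(v) == n) {
    # still rising at the window end: the spurt was entered before the window
    if (v_end - min(v) >= config$r_min) {
      stage <- if ((v_end - min(v) >= config$d_phv) && flattening) 3L else 2L
    } else {
      stage <- 1L
    }
  } else {
    # declining or hump-shaped with no qualifying landmarks: the in-window
    # maximum is already behind; classify by how far velocity has fallen,
    # with a very low absolute end velocity marking the adult asymptote
    stage <- if (v_end < config$f_late * v_max || v_end < config$v_late_abs) 4L
             else if (v_end < config$f_near * v_max) 3L
             else 1L
  }

  tibble::tibble(
    stage = stage,
    stage_label = unname(STAGE_LABELS[as.character(stage)]),
    prespurt_min_age = if (prespurt_detected) ages[prespurt_idx] else NA_real_,
    phv_age = if (phv_detected) ages[phv_idx] else NA_real_,
    phv_value = if (phv_detected) v[phv_idx] else NA_real_,
    short_for_age = short_for_age,
    reason = NA_character_
  )
}

#' Trim a growth-curve grid away from its boundaries
#'
#' Local-polynomial derivative estimates have their largest variance within
#' half a bandwidth of the data boundary, where the kernel support is
#' one-sided. Staging therefore operates on the interior of the grid when
#' enough of it remains (at least 8 points); otherwise the full grid is used.
#'
#' @param model A `growth_curve`.
#' @return Logical vector marking the grid points staged on.
#' @export
staging_support <- function(model) {
  g <- model$curve$age_years
  keep <- g >= min(g) + model$bandwidth / 2 & g <= max(g) - model$bandwidth / 2
  if (sum(keep) >= 8) keep else rep(TRUE, length(g))
}

#' Assign a maturity stage to a smoothed growth curve
#'
#' Applies [stage_from_velocity()] to the boundary-trimmed part of the
#' velocity curve (see [staging_support()]).
#'
#' @param model A `growth_curve` from [smooth_series()] (or `NULL` for an
#'   unmodellable participant).
#' @param height_z Optional height-for-age z-score at the last visit.
#' @param config Thresholds from [staging_config()].
#' @return One-row tibble as in [stage_from_velocity()], plus
#'   `participant_id`.
#' @export
assign_maturity_stage <- function(model, height_z = NA_real_,
                                  config = staging_config()) {
  if (is.null(model)) {
    return(tibble::tibble(participant_id = NA_character_, stage = NA_integer_,
                          stage_label = NA_character_, prespurt_min_age = NA_real_,
                          phv_age = NA_real_, phv_value = NA_real_,
                          short_for_age = NA, reason = "unmodellable"))
  }
  keep <- staging_support(model)
  res <- stage_from_velocity(model$curve$age_years[keep],
                             model$curve$velocity[keep],
                             height_z = height_z, config = config)
  dplyr::bind_cols(tibble::tibble(participant_id = model$participant_id), res)
}

#' Smooth and stage every participant in a cohort
#'
#' Convenience wrapper: extracts each participant's series for `variable`,
#' smooths it and assigns a maturity stage. Participants with fewer than six
#' observations are reported with `reason = "unmodellable"`.
#'
#' @param cohort An `rp_cohort`.
#' @param variable `"height"` (default) or `"leg_length"`.
#' @param bandwidth,robust_iterations Passed to [smooth_series()].
#' @param lms_height Optional height-for-age LMS reference (see
#'   [read_lms()]) used for the `short_for_age` flag.
#' @param config Thresholds from [staging_config()].
#' @return List with `stages` (tibble, one row per participant) and `models`
#'   (named list of `growth_curve` objects).
#' @export
assign_maturity <- function(cohort, variable = c("height", "leg_length"),
                            bandwidth = 1.75, robust_iterations = 2L,
                            lms_height = NULL, config = staging_config()) {
  variable <- match.arg(variable)
  ids <- cohort$participants$participant_id
  models <- list()
  rows <- lapply(ids, function(id) {
    series <- participant_series(cohort, id, variable)
    model <- withCallingHandlers(
      smooth_series(series, bandwidth = bandwidth,
                    robust_iterations = robust_iterations,
                    participant_id = id, variable = variable),
      warning = function(w) invokeRestart("muffleWarning")
    )
    models[[id]] <<- model
    hz <- NA_real_
    if (!is.null(lms_height) && nrow(series) > 0) {
      sex <- as.character(cohort$participants$sex[ids == id])
      last <- series[nrow(series), ]
      hz <- tryCatch(
        lms_zscore(last$value, sex, last$age_years, lms_height),
        error = function(e) NA_real_
      )
    }
    assign_maturity_stage(model, height_z = hz, config = config) |>
      dplyr::mutate(participant_id = id)
  })
  list(stages = dplyr::bind_rows(rows), models = models)
}
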