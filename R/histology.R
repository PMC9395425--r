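# Retzius periodicity (RP) estimation from enamel histology.
#
# Two standard estimators are provided. The primary one counts the daily
# cross striations along an enamel prism between two adjacent Retzius lines;
# the mean count, rounded to the nearest whole day, is the RP. When
# consecutive striations are not clearly visible, RP is instead obtained from
# the local daily secretion rate (DSR): prism lengths spanning six cross
# striations correspond to five days of enamel formation, their mean gives a
# grand-mean DSR in um/day, and the spacing of adjacent Retzius lines divided
# by that DSR yields the periodicity.

RP_SANITY_RANGE <- c(5L, 12L)  # human inter-individual range, days

check_rp_range <- function(raw_rp) {
  if (raw_rp < RP_SANITY_RANGE[1] || raw_rp > RP_SANITY_RANGE[2]) {
    warning(sprintf(
      "RP estimate %.2f days lies outside the human range %d-%d days",
      raw_rp, RP_SANITY_RANGE[1], RP_SANITY_RANGE[2]), call. = FALSE)
  }
}

#' Retzius periodicity by direct cross-striation counting
#'
#' Each element of `striation_counts` is the number of daily cross striations
#' counted along one prism between a pair of adjacent Retzius lines. The raw
#' RP is their arithmetic mean; the reported RP is the nearest whole day
#' (ties away from zero).
#'
#' @param striation_counts Integer vector, each count >= 1.
#' @return Tibble with `raw_rp`, `rp_days`, `method = "count"`.
#' @examples
#' rp_from_count(6)            # 6-day periodicity
#' rp_from_count(c(6, 7, 6, 7))  # mean 6.5 -> 7 days
#' @export
rp_from_count <- function(striation_counts) {
  if (length(striation_counts) == 0) {
    stop("at least one cross-striation count is required", call. = FALSE)
  }
  if (any(is.na(striation_counts)) || any(striation_counts != round(striation_counts))) {
    stop("cross-striation counts must be whole numbers", call. = FALSE)
  }
  if (any(striation_counts < 1)) {
    stop("cross-striation counts must be >= 1", call. = FALSE)
  }
  raw <- mean(striation_counts)
  check_rp_range(raw)
  tibble::tibble(raw_rp = raw, rp_days = as.integer(round_half_away(raw)), method = "count")
}

#' Grand-mean daily secretion rate
#'
#' Each prism span covers six cross striations, i.e. five days of enamel
#' formation; the local DSR is span/5 and the grand mean is the average of
#' the local DSRs. Six replicate spans are the convention; fewer trigger an
#' under-replication warning.
#'
#' @param prism_spans_um Positive lengths in micrometres.
#' @param n_expected Expected replicate count (default 6).
#' @return Grand-mean DSR in um/day.
#' @examples
#' grand_mean_dsr(rep(20, 6))  # 4 um/day
#' @export
grand_mean_dsr <- function(prism_spans_um, n_expected = 6L) {
  if (length(prism_spans_um) == 0) stop("at least one prism span is required", call. = FALSE)
  if (any(is.na(prism_spans_um)) || any(prism_spans_um <= 0)) {
    stop("prism spans must be positive lengths in um", call. = FALSE)
  }
  if (length(prism_spans_um) < n_expected) {
    warning(sprintf("grand-mean DSR computed from %d span(s); %d replicates expected",
                    length(prism_spans_um), n_expected), call. = FALSE)
  }
  mean(prism_spans_um / 5)
}

#' Retzius periodicity from the DSR-ratio method
#'
#' The measured distance across `retzius_line_count` adjacent Retzius lines
#' contains `retzius_line_count - 1` repeat intervals; dividing the
#' per-interval width by the grand-mean DSR gives the periodicity in days.
#'
#' @param retzius_span_um Distance in um across the Retzius lines.
#' @param retzius_line_count Number of adjacent Retzius lines spanned (4-6).
#' @param dsr Grand-mean daily secretion rate in um/day.
#' @return Tibble with `raw_rp`, `rp_days`, `method = "dsr_ratio"`.
#' @examples
#' rp_from_dsr(120, 6, 4)  # 24 um per interval / 4 um/day = 6 days
#' @export
rp_from_dsr <- function(retzius_span_um, retzius_line_count, dsr) {
  if (!retzius_line_count %in% 4:6) {
    stop("retzius_line_count must be 4, 5 or 6 (three to five repeat intervals)",
         call. = FALSE)
  }
  if (is.na(retzius_span_um) || retzius_span_um <= 0) {
    stop("retzius_span_um must be a positive length", call. = FALSE)
  }
  if (is.na(dsr) || dsr <= 0) stop("dsr must be positive", call. = FALSE)
  interval_um <- retzius_span_um / (retzius_line_count - 1)
  raw <- interval_um / dsr
  check_rp_range(raw)
  tibble::tibble(raw_rp = raw, rp_days = as.integer(round_half_away(raw)),
                 method = "dsr_ratio")
}

#' Estimate RP for every histology field in a measurement table
#'
#' Applies the counting method when striation counts are available for a
#' field and falls back to the DSR-ratio method otherwise (the counting
#' method wins when both could be used). Fields flagged as stress-affected or
#' from oblique sections are dropped before estimation.
#'
#' @param histology Tibble as returned by [read_histology()] (one row per
#'   field, list-columns `striation_counts` and `prism_spans_um`).
#' @return Tibble: `participant_id`, `tooth_id`, `field_id`, `raw_rp`,
#'   `rp_days`, `method`.
#' @export
estimate_rp <- function(histology) {
  h <- histology
  if ("stress_excluded" %in% names(h)) h <- h[!isTRUE_vec(h$stress_excluded), ]
  if ("oblique_excluded" %in% names(h)) h <- h[!isTRUE_vec(h$oblique_excluded), ]
  est <- lapply(seq_len(nrow(h)), function(i) {
    counts <- h$striation_counts[[i]]
    if (!is.null(counts) && length(counts) > 0 && !all(is.na(counts))) {
      rp_from_count(counts[!is.na(counts)])
    } else {
      dsr <- grand_mean_dsr(h$prism_spans_um[[i]])
      rp_from_dsr(h$retzius_span_um[i], h$retzius_line_count[i], dsr)
    }
  })
  tibble::tibble(
    participant_id = h$participant_id,
    tooth_id = h$tooth_id,
    field_id = h$field_id,
    raw_rp = vapply(est, `[[`, numeric(1), "raw_rp"),
    rp_days = vapply(est, `[[`, integer(1), "rp_days"),
    method = vapply(est, `[[`, character(1), "method")
  )
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Apply the two-matching-estimates inclusion rule
#'
#' A participant is included when at least two RP estimates agree exactly on
#' the integer day value, either from two different primary molars or from
#' two independent fields of a single molar. The matched value becomes the
#' participant's RP. Participants whose estimates never agree are excluded
#' with reason `"no matching pair"`; when two different values each have a
#' matching pair the participant is excluded as `"ambiguous match"`. The
#' inter-molar concordance flag records whether all measured teeth agree.
#'
#' @param estimates Tibble from [estimate_rp()] (may cover many participants).
#' @return One row per participant: `participant_id`, `included`, `rp_days`,
#'   `n_estimates`, `n_teeth`, `concordant_teeth`, `reason`.
#' @export
apply_inclusion_rule <- function(estimates) {
  stopifnot(nrow(estimates) >= 1)
  one <- function(d) {
    tab <- table(d$rp_days)
    matched <- as.integer(names(tab)[tab >= 2])
    per_tooth <- tapply(d$rp_days, d$tooth_id, function(v) unique(v))
    concordant <- length(unique(unlist(per_tooth))) == 1 && length(per_tooth) >= 1
    if (length(matched) == 1) {
      tibble::tibble(included = TRUE, rp_days = matched,
                     n_estimates = nrow(d), n_teeth = length(per_tooth),
                     concordant_teeth = concordant, reason = NA_character_)
    } else if (length(matched) == 0) {
      tibble::tibble(included = FALSE, rp_days = NA_integer_,
                     n_estimates = nrow(d), n_teeth = length(per_tooth),
                     concordant_teeth = concordant, reason = "no matching pair")
    } else {
      tibble::tibble(included = FALSE, rp_days = NA_integer_,
                     n_estimates = nrow(d), n_teeth = length(per_tooth),
                     concordant_teeth = concordant, reason = "ambiguous match")
    }
  }
  estimates |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ one(.x)) |>
    dplyr::ungroup()
}

#' Read an enamel histology measurement table
#'
#' CSV schema: `participant_id,tooth_id,field_id,method_hint,
#' striation_counts,prism_spans_um,retzius_span_um,retzius_line_count,
#' stress_excluded,oblique_excluded`, where `striation_counts` and
#' `prism_spans_um` are semicolon-separated lists (may be empty).
#'
#' @param path Path to the CSV file.
#' @return Tibble with list-columns for the measurement lists.
#' @export
read_histology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  split_nums <- function(x) {
    lapply(x, function(s) {
      if (is.na(s) || !nzchar(s)) numeric(0) else as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
    })
  }
  tibble::tibble(
    participant_id = raw$participant_id,
    tooth_id = raw$tooth_id,
    field_id = raw$field_id,
    method_hint = raw$method_hint %||% NA_character_,
    striation_counts = split_nums(raw$striation_counts),
    prism_spans_um = split_nums(raw$prism_spans_um),
    retzius_span_um = parse_num(raw$retzius_span_um),
    retzius_line_count = as.integer(parse_num(raw$retzius_line_count)),
    stress_excluded = tolower(raw$stress_excluded %||% "false") %in% c("true", "1", "t"),
    oblique_excluded = tolower(raw$oblique_excluded %||% "false") %in% c("true", "1", "t")
  )
}

#' Write an enamel histology measurement table
#'
#' Inverse of [read_histology()]; list columns are serialised as
#' semicolon-separated values.
#'
#' @param histology Tibble with the [read_histology()] layout.
#' @param path Output CSV path.
#' @return The input, invisibly.
#' @export
write_histology <- function(histology, path) {
  join_nums <- function(lst) {
    vapply(lst, function(v) paste(format(v, trim = TRUE, scientific = FALSE),
                                  collapse = ";"), character(1))
  }
  out <- tibble::tibble(
    participant_id = histology$participant_id,
    tooth_id = histology$tooth_id,
    field_id = histology$field_id,
    method_hint = histology$method_hint %||% NA_character_,
    striation_counts = join_nums(histology$striation_counts),
    prism_spans_um = join_nums(histology$prism_spans_um),
    retzius_span_um = histology$retzius_span_um,
    retzius_line_count = histology$retzius_line_count,
    stress_excluded = histology$stress_excluded,
    oblique_excluded = histology$oblique_excluded
  )
  readr::write_csv(out, path, na = "", eol = "\n")
  invisible(histology)
}
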