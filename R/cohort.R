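# Cohort data model: roster + longitudinal measurement records, with
# validation and CSV round-trip I/O.
#
# File schemas (UTF-8, LF, header row, fixed column order):
#   roster:       participant_id,sex,birth_date,ethnicity
#   measurements: participant_id,visit_date,height_cm,leg_length_cm,weight_kg
# Sex is coded "F"/"M" on disk and normalised to a factor; dates are ISO-8601;
# missing measurements are empty cells.

COHORT_SEX_LEVELS <- c("female", "male")

#' Construct a cohort object
#'
#' Bundles a participant roster and a table of longitudinal measurement
#' records. The object is a plain list of tibbles with class `rp_cohort`;
#' every accessor in the package takes and returns tibbles.
#'
#' @param participants Tibble with columns `participant_id`, `sex`
#'   (factor `"female"`/`"male"`), `birth_date` (`Date`), `ethnicity`
#'   (character, may be `NA`).
#' @param records Tibble with columns `participant_id`, `visit_date` (`Date`),
#'   `height_cm`, `leg_length_cm`, `weight_kg` (numeric, `NA` when not taken).
#' @param study_window Length-2 `Date` vector (start, end). Defaults to the
#'   range of `visit_date`.
#' @param validate If `TRUE` (default) stop when [validate_cohort()] reports
#'   any violation.
#' @return An `rp_cohort` object.
#' @export
new_cohort <- function(participants, records, study_window = NULL, validate = TRUE) {
  participants <- tibble::as_tibble(participants)
  records <- tibble::as_tibble(records)
  participants$sex <- factor(as.character(participants$sex), levels = COHORT_SEX_LEVELS)
  participants$birth_date <- as.Date(participants$birth_date)
  records$visit_date <- as.Date(records$visit_date)
  if (!"ethnicity" %in% names(participants)) participants$ethnicity <- NA_character_
  if (is.null(study_window)) {
    study_window <- range(records$visit_date)
  }
  study_window <- as.Date(study_window)
  cohort <- structure(
    list(participants = participants, records = records, study_window = study_window),
    class = "rp_cohort"
  )
  if (validate) {
    diags <- validate_cohort(cohort)
    if (nrow(diags) > 0) {
      stop("invalid cohort:\n", paste(utils::head(diags$message, 10), collapse = "\n"),
           call. = FALSE)
    }
  }
  cohort
}

#' @export
print.rp_cohort <- function(x, ...) {
  cat(sprintf(
    "<rp_cohort> %d participants (%d F / %d M), %d measurement rows, %s to %s\n",
    nrow(x$participants),
    sum(x$participants$sex == "female", na.rm = TRUE),
    sum(x$participants$sex == "male", na.rm = TRUE),
    nrow(x$records), x$study_window[1], x$study_window[2]
  ))
  invisible(x)
}

diag_row <- function(participant_id, date, field, rule, message) {
  tibble::tibble(
    participant_id = as.character(participant_id),
    date = as.character(date), field = field, rule = rule, message = message
  )
}

#' Validate a cohort against its structural invariants
#'
#' Pure check: returns a diagnostics tibble (zero rows when the cohort is
#' valid) and never mutates or throws. Rules checked: unique participant ids;
#' known sex codes; every record's participant on the roster; birth date
#' strictly before every visit; strictly increasing visit dates per
#' participant and variable (no duplicate visit per variable); positive
#' measurements; at least one measurement per row; study window ordered.
#'
#' @param cohort An `rp_cohort`.
#' @return Tibble with columns `participant_id`, `date`, `field`, `rule`,
#'   `message`.
#' @export
validate_cohort <- function(cohort) {
  p <- cohort$participants
  r <- cohort$records
  out <- list()

  dup <- p$participant_id[duplicated(p$participant_id)]
  for (id in unique(dup)) {
    out[[length(out) + 1]] <- diag_row(id, NA, "participant_id", "uniqueness",
      sprintf("participant id '%s' appears more than once in the roster", id))
  }
  bad_sex <- p$participant_id[is.na(p$sex)]
  for (id in bad_sex) {
    out[[length(out) + 1]] <- diag_row(id, NA, "sex", "sex_code",
      sprintf("participant '%s' has an unknown sex code", id))
  }
  orphan <- setdiff(r$participant_id, p$participant_id)
  for (id in orphan) {
    out[[length(out) + 1]] <- diag_row(id, NA, "participant_id", "roster_membership",
      sprintf("records reference participant '%s' absent from the roster", id))
  }
  if (length(cohort$study_window) != 2 || !(cohort$study_window[1] < cohort$study_window[2])) {
    out[[length(out) + 1]] <- diag_row(NA, NA, "study_window", "window_order",
      "study window start must precede its end")
  }

  birth <- stats::setNames(p$birth_date, p$participant_id)
  meas_cols <- c("height_cm", "leg_length_cm", "weight_kg")
  for (i in seq_len(nrow(r))) {
    row <- r[i, ]
    id <- row$participant_id
    if (id %in% names(birth) && !is.na(birth[[id]]) && row$visit_date <= birth[[id]]) {
      out[[length(out) + 1]] <- diag_row(id, row$visit_date, "visit_date", "chronology",
        sprintf("row %d: visit %s on/before birth date %s for '%s'",
                i, row$visit_date, birth[[id]], id))
    }
    vals <- unlist(row[meas_cols])
    if (all(is.na(vals))) {
      out[[length(out) + 1]] <- diag_row(id, row$visit_date, "measurements", "presence",
        sprintf("row %d: no measurement present for '%s' on %s", i, id, row$visit_date))
    }
    for (col in meas_cols) {
      v <- row[[col]]
      if (!is.na(v) && v <= 0) {
        out[[length(out) + 1]] <- diag_row(id, row$visit_date, col, "positivity",
          sprintf("row %d: %s = %g must be > 0 for '%s' on %s", i, col, v, id, row$visit_date))
      }
    }
  }

  for (col in meas_cols) {
    sub <- r[!is.na(r[[col]]), c("participant_id", "visit_date")]
    if (nrow(sub) == 0) next
    key <- paste(sub$participant_id, sub$visit_date, col)
    dups <- sub[duplicated(key), , drop = FALSE]
    for (j in seq_len(nrow(dups))) {
      out[[length(out) + 1]] <- diag_row(dups$participant_id[j], dups$visit_date[j],
        col, "visit_order",
        sprintf("duplicate %s for '%s' on %s (visit dates must strictly increase)",
                col, dups$participant_id[j], dups$visit_date[j]))
    }
  }

  if (length(out) == 0) {
    diag_row(character(), character(), character(), character(), character())[0, ]
  } else {
    dplyr::bind_rows(out)
  }
}

parse_num <- function(x) suppressWarnings(as.numeric(x))

#' Read a cohort from roster and measurement CSV files
#'
#' Dates are parsed as ISO-8601; rows with unparseable dates or non-positive
#' measurements are rejected with a row-level error message. Sex codes `F`/`M`
#' are normalised to `female`/`male`.
#'
#' @param measurements_path,roster_path Paths to the CSV files.
#' @return A validated `rp_cohort`.
#' @export
read_cohort <- function(measurements_path, roster_path) {
  for (path in c(measurements_path, roster_path)) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  }
  roster <- readr::read_csv(roster_path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("participant_id", "sex", "birth_date")
  if (!all(need %in% names(roster))) {
    stop("roster is missing required columns: ",
         paste(setdiff(need, names(roster)), collapse = ", "), call. = FALSE)
  }
  sex_map <- c(F = "female", M = "male", female = "female", male = "male")
  sex_raw <- as.character(roster$sex)
  unknown <- setdiff(unique(sex_raw), names(sex_map))
  if (length(unknown) > 0) {
    stop("unknown sex code(s) in roster: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  birth <- as.Date(roster$birth_date, format = "%Y-%m-%d")
  if (anyNA(birth)) {
    stop("unparseable birth_date at roster row(s): ",
         paste(which(is.na(birth)), collapse = ", "), call. = FALSE)
  }
  participants <- tibble::tibble(
    participant_id = roster$participant_id,
    sex = factor(unname(sex_map[sex_raw]), levels = COHORT_SEX_LEVELS),
    birth_date = birth,
    ethnicity = if ("ethnicity" %in% names(roster)) roster$ethnicity else NA_character_
  )

  meas <- readr::read_csv(measurements_path,
                          col_types = readr::cols(.default = readr::col_character()))
  need <- c("participant_id", "visit_date", "height_cm", "leg_length_cm", "weight_kg")
  if (!all(need %in% names(meas))) {
    stop("measurements file is missing required columns: ",
         paste(setdiff(need, names(meas)), collapse = ", "), call. = FALSE)
  }
  visit <- as.Date(meas$visit_date, format = "%Y-%m-%d")
  if (anyNA(visit)) {
    stop("unparseable visit_date at measurement row(s): ",
         paste(which(is.na(visit)), collapse = ", "), call. = FALSE)
  }
  records <- tibble::tibble(
    participant_id = meas$participant_id,
    visit_date = visit,
    height_cm = parse_num(meas$height_cm),
    leg_length_cm = parse_num(meas$leg_length_cm),
    weight_kg = parse_num(meas$weight_kg)
  )
  for (col in c("height_cm", "leg_length_cm", "weight_kg")) {
    bad <- which(!is.na(records[[col]]) & records[[col]] <= 0)
    if (length(bad) > 0) {
      stop(sprintf("non-positive %s at measurement row(s): %s",
                   col, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  new_cohort(participants, records)
}

#' Write a cohort to roster and measurement CSV files
#'
#' Inverse of [read_cohort()]: emits UTF-8 CSVs with LF line endings, the
#' documented column order, `F`/`M` sex codes and empty cells for missing
#' measurements, so that reading them back reproduces the cohort field by
#' field.
#'
#' @param cohort An `rp_cohort`.
#' @param measurements_path,roster_path Output paths.
#' @return The cohort, invisibly.
#' @export
write_cohort <- function(cohort, measurements_path, roster_path) {
  roster <- tibble::tibble(
    participant_id = cohort$participants$participant_id,
    sex = c(female = "F", male = "M")[as.character(cohort$participants$sex)],
    birth_date = format(cohort$participants$birth_date, "%Y-%m-%d"),
    ethnicity = cohort$participants$ethnicity
  )
  readr::write_csv(roster, roster_path, na = "", eol = "\n")
  meas <- dplyr::mutate(
    cohort$records[, c("participant_id", "visit_date", "height_cm", "leg_length_cm", "weight_kg")],
    visit_date = format(.data$visit_date, "%Y-%m-%d")
  )
  readr::write_csv(meas, measurements_path, na = "", eol = "\n")
  invisible(cohort)
}

#' Per-visit ages and measurements for one participant
#'
#' Joins a participant's records with their birth date and returns decimal
#' ages alongside the requested variable, dropping missing values.
#'
#' @param cohort An `rp_cohort`.
#' @param participant_id Participant to extract.
#' @param variable One of `"height"`, `"leg_length"`, `"weight"`.
#' @return Tibble with `visit_date`, `age_years`, `value`, sorted by date.
#' @export
participant_series <- function(cohort, participant_id,
                               variable = c("height", "leg_length", "weight")) {
  variable <- match.arg(variable)
  col <- c(height = "height_cm", leg_length = "leg_length_cm", weight = "weight_kg")[[variable]]
  p <- cohort$participants[cohort$participants$participant_id == participant_id, ]
  if (nrow(p) == 0) stop("unknown participant: ", participant_id, call. = FALSE)
  r <- cohort$records[cohort$records$participant_id == participant_id, ]
  r <- r[!is.na(r[[col]]), ]
  r <- r[order(r$visit_date), ]
  tibble::tibble(
    visit_date = r$visit_date,
    age_years = decimal_age(p$birth_date[1], r$visit_date),
    value = r[[col]]
  )
}
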