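# Shared fixtures, built in code at test time.

# Minimal two-participant cohort with clean monthly visits.
tiny_cohort <- function() {
  participants <- tibble::tibble(
    participant_id = c("A1", "B2"),
    sex = c("female", "male"),
    birth_date = as.Date(c("2009-05-01", "2009-07-15")),
    ethnicity = c("NZ European", NA)
  )
  dates <- seq(as.Date("2019-09-15"), by = "1 month", length.out = 8)
  records <- dplyr::bind_rows(
    tibble::tibble(participant_id = "A1", visit_date = dates,
                   height_cm = seq(140, 143.5, by = 0.5),
                   leg_length_cm = seq(38, 39.4, by = 0.2),
                   weight_kg = seq(35, 38.5, by = 0.5)),
    tibble::tibble(participant_id = "B2", visit_date = dates,
                   height_cm = seq(138, 141.5, by = 0.5),
                   leg_length_cm = seq(37, 38.4, by = 0.2),
                   weight_kg = seq(33, 36.5, by = 0.5))
  )
  new_cohort(participants, records)
}

# Preece-Baines parameter sets used as staging/PHV oracles.
pb_typical_female <- list(h1 = 166, h_theta = 152.5, s0 = 0.11, s1 = 1.25, theta = 11.4)
pb_typical_male <- list(h1 = 177, h_theta = 163, s0 = 0.105, s1 = 1.2, theta = 13.6)

pb_h <- function(t, p) pb1_height(t, p$h1, p$h_theta, p$s0, p$s1, p$theta)
pb_v <- function(t, p) pb1_velocity(t, p$h1, p$h_theta, p$s0, p$s1, p$theta)

# Independent weighted-least-squares oracle: solve the normal equations
# directly for a polynomial in (x - x0).
wls_poly_oracle <- function(x, y, w, x0, degree = 3) {
  d <- x - x0
  X <- outer(d, 0:degree, `^`)
  W <- diag(w)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  as.numeric(beta)
}
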