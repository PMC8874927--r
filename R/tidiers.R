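#' Tidy a risk assessment into per-encounter rows
#'
#' @param x A `risk_assessment`.
#' @param ... Unused.
#' @return A tibble with one row per encounter: `person_id`, `visit_id`,
#'   `day_offset`, `n_findings`, `any_red_finding`, `level`.
#' @export
#' @exportS3Method
tidy.risk_assessment <- function(x, ...) {
  as_tibble(x$profiles)
}

#' One-row summary of a risk assessment
#'
#' @inheritParams tidy.risk_assessment
#' @return A one-row tibble: encounter and patient counts, patients at
#'   each level, and median onset days.
#' @export
#' @exportS3Method
glance.risk_assessment <- function(x, ...) {
  tibble(
    n_encounters = nrow(x$profiles),
    n_patients = nrow(x$onsets),
    n_patients_any_risk = sum(!is.na(x$onsets$onset_standard)),
    n_patients_red_flag = sum(!is.na(x$onsets$onset_red_flag)),
    median_onset_standard = median(x$onsets$onset_standard, na.rm = TRUE),
    baseline_mode = x$baseline_mode
  )
}

#' Tidy a lead-time evaluation into per-patient rows
#'
#' @param x A `delta_eval`.
#' @param ... Unused.
#' @return The per-patient tibble (`person_id`, `evaluable`, `reason`,
#'   `onset_day`, `reference_day`, `delta`, `status`).
#' @export
#' @exportS3Method
tidy.delta_eval <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a lead-time evaluation
#'
#' @inheritParams tidy.delta_eval
#' @return The [summarize_deltas()] one-row tibble.
#' @export
#' @exportS3Method
glance.delta_eval <- function(x, ...) {
  summarize_deltas(x)
}
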