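#' Earliest provider reference day per patient
#'
#' The reference day is the earliest day offset bearing a recorded
#' diagnosis of a target cardiovascular condition (or a configured
#' intervention marker code), the anchor against which detection lead time
#' is measured.
#'
#' @param harmonized A `harmonized_record_set`.
#' @param targets A [target_conditions()] tibble (`label`, `code_prefix`);
#'   intervention markers may be appended as additional rows.
#' @return A tibble `person_id`, `reference_day` (one row per patient with
#'   at least one target diagnosis).
#' @export
reference_days <- function(harmonized, targets = target_conditions()) {
  if (nrow(targets) == 0L) {
    abort("Target condition list is empty.", class = "matcvrisk_config_error")
  }
  harmonized$Diagnosis |>
    filter(matches_prefix(.data$code, targets$code_prefix)) |>
    group_by(.data$person_id) |>
    summarise(reference_day = safe_min(.data$day_offset), .groups = "drop")
}

#' Signed detection delta in days
#'
#' `reference - onset`: positive when the engine detected risk before the
#' provider's recorded diagnosis or intervention, zero on the same day,
#' negative when detection came later. Undefined when either day is
#' missing.
#'
#' @param onset Engine onset day offset(s).
#' @param reference Provider reference day offset(s).
#' @return Integer vector; NA where not computable.
#' @export
#' @examples
#' compute_delta(30, 51)
compute_delta <- function(onset, reference) {
  as.integer(reference) - as.integer(onset)
}

#' Evaluability of a patient for lead-time analysis
#'
#' Patients who delivered at their index encounter contribute no
#' retrospective data, and patients with a single included encounter
#' cannot exhibit trends; both are excluded, with the delivered-first
#' reason taking precedence so the reasons partition the cohort.
#'
#' @param n_visits Included-encounter count per patient.
#' @param delivered_at_index Logical: delivery procedure on day 0.
#' @return A tibble `evaluable`, `reason` (NA when evaluable).
#' @export
is_evaluable <- function(n_visits, delivered_at_index) {
  reason <- dplyr::case_when(
    delivered_at_index ~ "delivered_first_visit",
    n_visits <= 1L ~ "single_visit",
    TRUE ~ NA_character_
  )
  tibble(evaluable = is.na(reason), reason = reason)
}

#' Lead time between engine detection and provider action
#'
#' Joins engine onsets to provider reference days, applies the
#' evaluability exclusions, and computes the signed delta per patient.
#' Patients with an engine onset but no recorded target diagnosis are kept
#' and labelled `detected_never_diagnosed` (candidate false positives or
#' missed diagnoses).
#'
#' @param assessment A `risk_assessment` from [assess_cohort()].
#' @param harmonized The matching `harmonized_record_set`.
#' @param targets A [target_conditions()] tibble.
#' @param delivery_codes Procedure-code prefixes identifying the delivery
#'   (for the delivered-at-index exclusion).
#' @param level Onset level anchoring the delta: `"standard"` (earliest
#'   standard-or-higher onset, default) or `"red_flag"`.
#' @return A `delta_eval` object: tibble with one row per patient
#'   (`person_id`, `evaluable`, `reason`, `onset_day`, `reference_day`,
#'   `delta`, `status`).
#' @export
evaluate_deltas <- function(assessment, harmonized,
                            targets = target_conditions(),
                            delivery_codes = c("10D0", "10E0"),
                            level = c("standard", "red_flag")) {
  level <- match.arg(level)
  stopifnot(inherits(assessment, "risk_assessment"))

  n_visits <- harmonized$Visit |> count(.data$person_id, name = "n_visits")
  delivered_idx <- harmonized$Diagnosis |>
    filter(.data$sub_category == "procedure",
           matches_prefix(.data$code, delivery_codes)) |>
    group_by(.data$person_id) |>
    summarise(delivered_at_index = safe_min(.data$day_offset) %in% 0L,
              .groups = "drop")

  onset <- assessment$onsets |>
    transmute(.data$person_id,
              onset_day = if (level == "standard") .data$onset_standard
              else .data$onset_red_flag)
  refs <- reference_days(harmonized, targets)

  out <- n_visits |>
    left_join(delivered_idx, by = "person_id") |>
    mutate(delivered_at_index = dplyr::coalesce(.data$delivered_at_index,
                                                FALSE)) |>
    left_join(onset, by = "person_id") |>
    left_join(refs, by = "person_id")
  ev <- is_evaluable(out$n_visits, out$delivered_at_index)
  out <- out |>
    mutate(
      evaluable = ev$evaluable, reason = ev$reason,
      delta = if_else(.data$evaluable, compute_delta(.data$onset_day,
                                                     .data$reference_day),
                      NA_integer_),
      status = dplyr::case_when(
        !.data$evaluable ~ .data$reason,
        is.na(.data$onset_day) & is.na(.data$reference_day) ~ "no_signal",
        is.na(.data$reference_day) ~ "detected_never_diagnosed",
        is.na(.data$onset_day) ~ "diagnosed_never_detected",
        .data$delta > 0L ~ "detected_earlier",
        .data$delta == 0L ~ "same_day",
        TRUE ~ "detected_later"
      )
    ) |>
    select("person_id", "n_visits", "evaluable", "reason", "onset_day",
           "reference_day", "delta", "status")
  structure(out, class = c("delta_eval", class(out)), level = level)
}

#' Summarize a set of detection deltas
#'
#' Summary over evaluable patients with computable deltas: counts
#' partitioned by sign (detected earlier / same day / later), and the
#' median and quartiles of the delta distribution. An empty input yields
#' an all-zero summary, not an error.
#'
#' @param deltas A `delta_eval` tibble (or any tibble with `evaluable` and
#'   `delta` columns).
#' @return A one-row tibble of counts and distribution summaries.
#' @export
summarize_deltas <- function(deltas) {
  d <- deltas$delta[deltas$evaluable & !is.na(deltas$delta)]
  tibble(
    n_patients = nrow(deltas),
    n_evaluable = sum(deltas$evaluable),
    n_computable = length(d),
    n_detected_earlier = sum(d > 0L),
    n_same_day = sum(d == 0L),
    n_detected_later = sum(d < 0L),
    median_delta = if (length(d)) median(d) else NA_real_,
    q1_delta = if (length(d)) unname(quantile(d, 0.25)) else NA_real_,
    q3_delta = if (length(d)) unname(quantile(d, 0.75)) else NA_real_
  )
}

#' @export
print.delta_eval <- function(x, ...) {
  s <- summarize_deltas(x)
  cat(sprintf("<delta_eval> level=%s; %d patients, %d evaluable, %d computable\n",
              attr(x, "level"), s$n_patients, s$n_evaluable, s$n_computable))
  cat(sprintf("  earlier=%d same-day=%d later=%d; median delta %s days\n",
              s$n_detected_earlier, s$n_same_day, s$n_detected_later,
              format(s$median_delta)))
  invisible(x)
}
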