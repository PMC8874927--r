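#' Format a percentage the way the cohort-overview table prints it
#'
#' `100 * numerator / denominator`, rounded half-up to two decimal places,
#' with trailing zeros (and a trailing decimal point) trimmed: 55.8332
#' prints as `"55.83"`, 10.7007 as `"10.7"`, 100 as `"100"`.
#'
#' @param numerator,denominator Nonnegative counts; `denominator` must be
#'   positive.
#' @return A character vector.
#' @export
#' @examples
#' format_percentage(18095, 32409)
#' format_percentage(3468, 32409)
format_percentage <- function(numerator, denominator) {
  if (any(denominator <= 0)) {
    abort("Percentage undefined: denominator must be positive.",
          class = "matcvrisk_contract_error")
  }
  if (any(numerator < 0)) {
    abort("Numerator must be nonnegative.", class = "matcvrisk_contract_error")
  }
  pct <- 100 * numerator / denominator
  # round half-up at 2 dp; a hair of slack absorbs binary representation
  rounded <- floor(pct * 100 + 0.5 + 1e-9) / 100
  out <- formatC(rounded, format = "f", digits = 2)
  out <- sub("0+$", "", out)
  sub("\\.$", "", out)
}

# birth multiplicity by delivery-outcome code prefix
.birth_outcomes <- tibble::tibble(
  code_prefix = c("Z37.0", "Z37.1", "Z37.2", "Z37.5"),
  outcome = c("Single live births", "Stillbirths", "Twin births",
              "Triplet births"),
  babies = c(1L, 1L, 2L, 3L)
)

#' Build the cohort-overview summary report
#'
#' Reproduces the database-overview row set: total patients, patients with
#' at least one risk identified, delivered-on-first-visit and single-visit
#' patients, red-flag patients (each against the total-patient
#' denominator); birth counts by plurality and stillbirths (against total
#' births); patients per detected target condition (diagnosis-code
#' derived, as labelled); and patients per static-risk category. Every
#' percentage is produced by [format_percentage()] against its section's
#' denominator.
#'
#' @param harmonized A `harmonized_record_set`.
#' @param assessment A `risk_assessment` over the same cohort.
#' @param deltas A `delta_eval` over the same cohort.
#' @param targets A [target_conditions()] tibble.
#' @return A `summary_report` tibble: `section`, `label`, `count`,
#'   `denominator`, `percentage`.
#' @export
build_summary <- function(harmonized, assessment, deltas,
                          targets = target_conditions()) {
  for (obj in list(harmonized, assessment, deltas)) {
    if (is.null(obj)) {
      abort("An upstream stage output is missing; run the full pipeline first.",
            class = "matcvrisk_stage_error")
    }
  }
  n_pat <- nrow(harmonized$Person)
  if (n_pat == 0L) {
    abort("Empty cohort: nothing to summarize.",
          class = "matcvrisk_stage_error")
  }

  any_risk <- assessment$onsets |>
    filter(!is.na(.data$onset_standard)) |>
    nrow()
  red_flag <- assessment$onsets |>
    filter(!is.na(.data$onset_red_flag)) |>
    nrow()
  n_df <- sum(deltas$reason %in% "delivered_first_visit")
  n_sv <- sum(deltas$reason %in% "single_visit")

  outcomes <- harmonized$Diagnosis |>
    filter(matches_prefix(.data$code, .birth_outcomes$code_prefix)) |>
    mutate(outcome_prefix = substr(.data$code, 1L, 5L)) |>
    count(.data$outcome_prefix, name = "count") |>
    inner_join(.birth_outcomes, by = c(outcome_prefix = "code_prefix"))
  total_births <- sum(outcomes$count * outcomes$babies)

  condition_counts <- purrr::map_int(targets$code_prefix, function(p) {
    harmonized$Diagnosis |>
      filter(matches_prefix(.data$code, p)) |>
      distinct(.data$person_id) |>
      nrow()
  })

  static_count <- function(fid) {
    length(unique(assessment$static$person_id[
      assessment$static$factor_id == fid]))
  }
  static_rows <- tibble(
    label = c("BMI >= 35", "African American", "History of substance use"),
    factor_id = c("prepregnancy_obesity", "race_african_american",
                  "substance_use")
  )
  static_rows$count <- vapply(static_rows$factor_id, static_count, integer(1))

  row <- function(section, label, count, denom) {
    tibble(section = section, label = label, count = as.integer(count),
           denominator = as.integer(denom),
           percentage = format_percentage(count, denom))
  }
  report <- bind_rows(
    row("cohort", "Total patients in the database", n_pat, n_pat),
    row("cohort", "Patients with at least one risk identified", any_risk, n_pat),
    row("cohort", "Patients who delivered on the first visit", n_df, n_pat),
    row("cohort", "Patients who only had 1 visit", n_sv, n_pat),
    row("cohort", "Patients with red flag risk levels identified", red_flag,
        n_pat),
    if (total_births > 0L) bind_rows(
      row("births", "Total births", total_births, total_births),
      purrr::pmap_dfr(outcomes, function(outcome, count, babies, ...) {
        row("births", outcome, count, total_births)
      })
    ),
    purrr::map2_dfr(targets$label, condition_counts, function(lbl, cnt) {
      row("detected conditions", lbl, cnt, n_pat)
    }),
    purrr::pmap_dfr(static_rows, function(label, count, ...) {
      row("static risks", label, count, n_pat)
    })
  )
  structure(report, class = c("summary_report", class(report)))
}

#' @export
print.summary_report <- function(x, ...) {
  cat("Database overview\n")
  for (sec in unique(x$section)) {
    rows <- x[x$section == sec, ]
    cat(sprintf("-- %s (denominator %s) --\n", sec,
                format(rows$denominator[1], big.mark = ",")))
    for (k in seq_len(nrow(rows))) {
      cat(sprintf("  %-48s %10s (%s)\n", rows$label[k],
                  format(rows$count[k], big.mark = ","), rows$percentage[k]))
    }
  }
  invisible(x)
}
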