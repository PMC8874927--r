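# level coding shared across the engine
.levels <- c("none", "standard", "red_flag")

level_factor <- function(x) factor(x, levels = .levels, ordered = TRUE)

# vectorized numeric-threshold evaluation; returns "none"/"standard"/"red_flag"
# (direction/thresholds recycle against the value vector)
numeric_level <- function(value, direction, std, red) {
  ge <- rep_len(direction == "ge", length(value))
  meets <- function(th) {
    th <- rep_len(th, length(value))
    !is.na(th) & !is.na(value) & ifelse(ge, value >= th, value <= th)
  }
  dplyr::case_when(
    meets(red) ~ "red_flag",
    meets(std) ~ "standard",
    TRUE ~ "none"
  )
}

#' Evaluate a numeric observation against one risk-factor definition
#'
#' Thresholds are inclusive in the trigger direction: the red-flag level is
#' returned when the red-flag threshold is met, otherwise the standard
#' level when the standard threshold is met, otherwise no finding.
#'
#' @param quantity Canonical quantity label of the observation (must match
#'   the definition's quantity; a mismatch is a contract error).
#' @param value Observation value in canonical units.
#' @param def One catalog row (numeric trigger) from [risk_catalog()].
#' @return A one-row finding tibble (`factor_id`, `level`), or `NULL` when
#'   no threshold is met.
#' @export
#' @examples
#' cat <- risk_catalog()
#' evaluate_numeric("systolic_bp", 160, cat[cat$factor_id == "sbp_high", ])
evaluate_numeric <- function(quantity, value, def) {
  stopifnot(is.data.frame(def), nrow(def) == 1L)
  if (def$trigger != "numeric" || !identical(def$quantity, quantity)) {
    abort(sprintf("Definition `%s` does not evaluate quantity `%s`.",
                  def$factor_id, quantity),
          class = "matcvrisk_contract_error")
  }
  lvl <- numeric_level(value, def$direction, def$threshold_standard,
                       def$threshold_red)
  if (lvl == "none") return(NULL)
  tibble(factor_id = def$factor_id, level = lvl)
}

#' Evaluate a coded symptom, finding, or history item for presence
#'
#' Presence of a red-flag presence factor (dyspnea, orthopnea) yields a
#' red-flag finding; presence of any other catalog factor yields a standard
#' finding; items outside the catalog yield nothing.
#'
#' @param item Coded item label (case-insensitive).
#' @param catalog A [risk_catalog()].
#' @return A one-row finding tibble, or `NULL`.
#' @export
#' @examples
#' evaluate_presence("dyspnea", risk_catalog())
evaluate_presence <- function(item, catalog = risk_catalog()) {
  lmap <- catalog_label_map(filter(catalog, .data$trigger == "presence"))
  hit <- lmap$factor_id[match(tolower(item), lmap$label)]
  if (is.na(hit)) return(NULL)
  def <- catalog[catalog$factor_id == hit, ]
  tibble(factor_id = hit,
         level = if (def$red_flag_on_presence) "red_flag" else "standard")
}

#' Evaluate a patient's static risk factors
#'
#' Static risks are patient information that does not change over the
#' pregnancy: demographics (age, race) and prepregnancy history. Each
#' satisfied static factor yields one finding that is active at every
#' encounter of the patient.
#'
#' @param static A one-row tibble (or list) with elements `age` (years),
#'   `race`, `bmi` (prepregnancy BMI, NA if unknown), and `history`, a
#'   character vector of coded history item labels.
#' @param catalog A [risk_catalog()].
#' @return A finding tibble (possibly zero rows).
#' @export
#' @examples
#' evaluate_static(list(age = 29, race = "African American", bmi = 36,
#'                      history = "prepregnancy diabetes"))
evaluate_static <- function(static, catalog = risk_catalog()) {
  statics <- filter(catalog, .data$persistence == "static")
  findings <- list()
  num_defs <- filter(statics, .data$trigger == "numeric")
  vals <- c(age = static$age %||% NA_real_, bmi = static$bmi %||% NA_real_)
  for (k in seq_len(nrow(num_defs))) {
    v <- vals[[num_defs$quantity[k]]]
    lvl <- numeric_level(v, num_defs$direction[k],
                         num_defs$threshold_standard[k],
                         num_defs$threshold_red[k])
    if (lvl != "none") {
      findings[[length(findings) + 1L]] <-
        tibble(factor_id = num_defs$factor_id[k], level = lvl)
    }
  }
  items <- c(tolower(static$race %||% character(0)),
             tolower(static$history %||% character(0)))
  pres <- catalog_label_map(filter(statics, .data$trigger == "presence")) |>
    filter(.data$label %in% items) |>
    distinct(.data$factor_id) |>
    mutate(level = "standard")
  bind_rows(c(findings, list(pres)))
}

#' Assess one encounter from its deduplicated findings
#'
#' The profile level is red-flag when any single red-flag finding is
#' present or when 4 or more distinct risk factors are active at the
#' encounter; standard when at least one finding is active; none
#' otherwise.
#'
#' @param findings A finding tibble (`factor_id`, `level`); duplicated
#'   factor ids are collapsed to their highest level before counting.
#' @return A one-row tibble `level`, `n_findings`, `any_red_finding`.
#' @export
#' @examples
#' assess_encounter(tibble::tibble(
#'   factor_id = c("chest_pain", "sbp_high"),
#'   level = c("standard", "red_flag")))
assess_encounter <- function(findings) {
  if (is.null(findings) || nrow(findings) == 0L) {
    return(tibble(level = "none", n_findings = 0L, any_red_finding = FALSE))
  }
  dedup <- findings |>
    mutate(level = level_factor(.data$level)) |>
    group_by(.data$factor_id) |>
    summarise(level = max(.data$level), .groups = "drop")
  n <- nrow(dedup)
  any_red <- any(dedup$level == "red_flag")
  tibble(
    level = if (any_red || n >= 4L) "red_flag" else "standard",
    n_findings = n,
    any_red_finding = any_red
  )
}

# variable findings for a set of harmonized events, vectorized over rows
variable_findings <- function(events, catalog, threshold_shift = NULL) {
  variable <- filter(catalog, .data$persistence == "variable")
  lmap <- catalog_label_map(variable) |>
    left_join(select(variable, "factor_id", "trigger", "quantity",
                     "direction", "threshold_standard", "threshold_red",
                     "red_flag_on_presence"),
              by = "factor_id")
  ev <- events |>
    mutate(label = tolower(.data$event_label)) |>
    inner_join(lmap, by = "label")
  if (!is.null(threshold_shift) && nrow(threshold_shift)) {
    ev <- ev |>
      left_join(threshold_shift, by = c("person_id", "quantity")) |>
      mutate(shift = dplyr::coalesce(.data$shift, 0),
             threshold_standard = .data$threshold_standard + .data$shift,
             threshold_red = .data$threshold_red + .data$shift)
  }
  usable <- if ("flagged_unit" %in% names(ev)) !ev$flagged_unit else TRUE
  ev |>
    filter(usable) |>
    mutate(level = if_else(
      .data$trigger == "presence",
      if_else(.data$red_flag_on_presence, "red_flag", "standard"),
      numeric_level(.data$value, .data$direction, .data$threshold_standard,
                    .data$threshold_red)
    )) |>
    filter(.data$level != "none") |>
    select("person_id", "visit_id", "day_offset", "factor_id", "level")
}

# static findings per person from the harmonized tables
static_findings <- function(harmonized, catalog) {
  statics <- filter(catalog, .data$persistence == "static")
  lmap <- catalog_label_map(filter(statics, .data$trigger == "presence"))

  race <- harmonized$Race |>
    mutate(label = tolower(.data$race)) |>
    inner_join(lmap, by = "label") |>
    transmute(.data$person_id, .data$factor_id, level = "standard")
  history <- harmonized$Event |>
    mutate(label = tolower(.data$event_label)) |>
    inner_join(lmap, by = "label") |>
    distinct(.data$person_id, .data$factor_id) |>
    mutate(level = "standard")

  num <- filter(statics, .data$trigger == "numeric")
  bmi_def <- filter(num, .data$quantity == "bmi")
  bmi <- harmonized$Event |>
    filter(tolower(.data$event_label) %in% tolower(unlist(bmi_def$labels))) |>
    group_by(.data$person_id) |>
    summarise(value = .data$value[1], .groups = "drop") |>
    mutate(level = numeric_level(.data$value, bmi_def$direction,
                                 bmi_def$threshold_standard,
                                 bmi_def$threshold_red)) |>
    filter(.data$level != "none") |>
    transmute(.data$person_id, factor_id = bmi_def$factor_id, .data$level)
  age_def <- filter(num, .data$quantity == "age")
  age <- harmonized$Person |>
    mutate(level = numeric_level(.data$age_at_index, age_def$direction,
                                 age_def$threshold_standard,
                                 age_def$threshold_red)) |>
    filter(.data$level != "none") |>
    transmute(.data$person_id, factor_id = age_def$factor_id, .data$level)

  bind_rows(race, history, bmi, age) |>
    distinct(.data$person_id, .data$factor_id, .keep_all = TRUE)
}

#' Run the risk engine over a harmonized cohort
#'
#' Evaluates every included encounter in chronological order (day offset,
#' then clock time) against the risk catalog: variable findings are
#' per-encounter (a symptom or exceedance counts only at encounters where
#' it is recorded), static findings are active at every encounter of the
#' patient. Each encounter receives a risk profile (none / standard /
#' red-flag per the single-severe-factor-or-4-plus rule) and each patient
#' the earliest day offset reaching each level.
#'
#' Individual-baseline mode (disabled by default, matching the study
#' configuration) shifts each patient's numeric thresholds by the
#' difference between their computed baseline and the population norm
#' midpoint; patients whose baseline falls outside the accepted norms are
#' flagged and keep unshifted thresholds.
#'
#' @param harmonized A `harmonized_record_set`.
#' @param catalog A [risk_catalog()].
#' @param baseline_mode Enable per-patient baselines (default `FALSE`).
#' @param norms Accepted per-quantity ranges, see [quantity_norms()].
#' @param k_baseline Observations per quantity used for a baseline.
#' @return A `risk_assessment`: list with `profiles` (one row per
#'   encounter: level, finding count, any red finding), `findings`
#'   (encounter-level findings), `static` (per-person static findings),
#'   `onsets` (per person: `onset_standard`, `onset_red_flag` day offsets,
#'   NA when never reached), `baseline` (per-patient baselines when
#'   enabled) and `catalog`.
#' @export
assess_cohort <- function(harmonized, catalog = risk_catalog(),
                          baseline_mode = FALSE, norms = quantity_norms(),
                          k_baseline = 3L) {
  stopifnot(inherits(harmonized, "harmonized_record_set"))
  validate_catalog(catalog)

  shift <- NULL
  baselines <- NULL
  if (baseline_mode) {
    baselines <- cohort_baselines(harmonized, k_baseline, norms)
    shift <- baselines |>
      filter(.data$conforms) |>
      inner_join(select(norms, "quantity", "midpoint"), by = "quantity") |>
      transmute(.data$person_id, .data$quantity,
                shift = .data$baseline - .data$midpoint)
  }

  vfind <- variable_findings(harmonized$Event, catalog, shift)
  sfind <- static_findings(harmonized, catalog)

  visits <- harmonized$Visit |>
    arrange(.data$person_id, .data$day_offset, .data$registration_time,
            .data$visit_id)
  enc_find <- bind_rows(
    vfind,
    visits |>
      select("person_id", "visit_id", "day_offset") |>
      inner_join(sfind, by = "person_id", relationship = "many-to-many")
  ) |>
    mutate(level = level_factor(.data$level)) |>
    group_by(.data$person_id, .data$visit_id, .data$day_offset,
             .data$factor_id) |>
    summarise(level = safe_max(.data$level), .groups = "drop")

  profiles <- visits |>
    select("person_id", "visit_id", "day_offset") |>
    left_join(
      enc_find |>
        group_by(.data$person_id, .data$visit_id, .data$day_offset) |>
        summarise(n_findings = dplyr::n_distinct(.data$factor_id),
                  any_red_finding = any(.data$level == "red_flag"),
                  .groups = "drop"),
      by = c("person_id", "visit_id", "day_offset")
    ) |>
    mutate(
      n_findings = dplyr::coalesce(.data$n_findings, 0L),
      any_red_finding = dplyr::coalesce(.data$any_red_finding, FALSE),
      level = dplyr::case_when(
        .data$any_red_finding | .data$n_findings >= 4L ~ "red_flag",
        .data$n_findings >= 1L ~ "standard",
        TRUE ~ "none"
      )
    )

  onsets <- profiles |>
    group_by(.data$person_id) |>
    summarise(
      onset_standard = suppressWarnings(
        min(.data$day_offset[.data$level %in% c("standard", "red_flag")])),
      onset_red_flag = suppressWarnings(
        min(.data$day_offset[.data$level == "red_flag"])),
      .groups = "drop"
    ) |>
    mutate(across(c("onset_standard", "onset_red_flag"), function(v) {
      v[is.infinite(v)] <- NA_real_
      as.integer(v)
    }))

  structure(
    list(profiles = profiles, findings = enc_find, static = sfind,
         onsets = onsets, baseline = baselines, catalog = catalog,
         baseline_mode = baseline_mode),
    class = "risk_assessment"
  )
}

#' @export
print.risk_assessment <- function(x, ...) {
  tab <- table(factor(x$profiles$level, levels = .levels))
  cat(sprintf("<risk_assessment> %d encounters, %d patients (baseline mode %s)\n",
              nrow(x$profiles), nrow(x$onsets),
              if (x$baseline_mode) "on" else "off"))
  cat("  encounter levels:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Replay one patient's timeline through the engine
#'
#' Encounters are processed strictly in chronological order (unordered
#' input is sorted internally; ties on day and time resolve by stable
#' visit order). Output is deterministic for fixed input.
#'
#' @param harmonized A `harmonized_record_set` (only the given patient's
#'   rows are used).
#' @param person_id One pseudonymized person id.
#' @inheritParams assess_cohort
#' @return A list: `profiles` (per-encounter tibble), `onset_standard`,
#'   `onset_red_flag` (day offsets or NA).
#' @export
run_patient <- function(harmonized, person_id, catalog = risk_catalog(),
                        baseline_mode = FALSE, norms = quantity_norms(),
                        k_baseline = 3L) {
  sub <- harmonized
  for (nm in c("Person", "Visit", "Event", "Diagnosis", "Race", "FamilyHX")) {
    sub[[nm]] <- filter(harmonized[[nm]], .data$person_id == !!person_id)
  }
  if (nrow(sub$Visit) == 0L) {
    abort(sprintf("No encounters for person `%s`.", person_id),
          class = "matcvrisk_contract_error")
  }
  a <- assess_cohort(sub, catalog, baseline_mode, norms, k_baseline)
  list(
    profiles = a$profiles,
    onset_standard = a$onsets$onset_standard[1],
    onset_red_flag = a$onsets$onset_red_flag[1]
  )
}

# per-patient, per-quantity baselines over the first k observations
cohort_baselines <- function(harmonized, k, norms) {
  qmap <- catalog_label_map(
    filter(risk_catalog(), .data$trigger == "numeric",
           .data$persistence == "variable")
  ) |>
    left_join(
      risk_catalog() |>
        filter(.data$trigger == "numeric") |>
        select("factor_id", "quantity"),
      by = "factor_id"
    )
  harmonized$Event |>
    mutate(label = tolower(.data$event_label)) |>
    inner_join(qmap, by = "label") |>
    filter(!is.na(.data$value)) |>
    arrange(.data$person_id, .data$day_offset, .data$event_time) |>
    group_by(.data$person_id, .data$quantity) |>
    filter(dplyr::row_number() <= k, dplyr::n() >= k) |>
    summarise(baseline = median(.data$value), .groups = "drop") |>
    left_join(norms, by = "quantity") |>
    mutate(conforms = .data$baseline >= .data$lower &
             .data$baseline <= .data$upper) |>
    select("person_id", "quantity", "baseline", "conforms")
}

#' Compute one patient's baseline metrics
#'
#' The baseline per numeric quantity is the median of the patient's first
#' `k` observations; a baseline outside the medically accepted range marks
#' the patient as non-conforming (excluded from any calibration set). With
#' fewer than `k` observations the baseline is undefined and evaluation
#' falls back to catalog thresholds.
#'
#' @inheritParams run_patient
#' @param k Observation count per quantity.
#' @return A `patient_baseline` tibble: `quantity`, `baseline`,
#'   `conforms`; attribute `conforming_patient` is FALSE when any quantity
#'   is out of range.
#' @export
compute_baseline <- function(harmonized, person_id, k = 3L,
                             norms = quantity_norms()) {
  sub <- harmonized
  sub$Event <- filter(harmonized$Event, .data$person_id == !!person_id)
  out <- cohort_baselines(sub, k, norms) |>
    select(-"person_id")
  structure(out, class = c("patient_baseline", class(out)),
            conforming_patient = all(out$conforms))
}
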