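#' Default categorization rules (the three-level category scheme)
#'
#' Every record receives a category triple: CATEGORY (the parent hierarchy,
#' e.g. event vs diagnosis, signifying the source table family),
#' SUB_CATEGORY (context-dependent: labs, measurements, symptoms, history,
#' admitting/discharge diagnosis, ...), and CLINICAL_CAT (optional finer
#' grouping such as vitals, weight and BMI, hematology, metabolic panel).
#' Rules are applied in order of significance, first match wins; records
#' matching no rule go to a review queue, never dropped. Site hierarchies
#' differ between institutions, so the rule set is plain data: edit the
#' tibble or maintain it as YAML via [read_category_rules()].
#'
#' @return A tibble with columns `target` (`"event"` or `"diagnosis"`),
#'   `field`, `pattern` (regular expression, case-insensitive),
#'   `category`, `sub_category`, `clinical_cat`.
#' @export
category_rules <- function() {
  r <- function(target, field, pattern, category, sub, clin = NA_character_) {
    tibble(target = target, field = field, pattern = pattern,
           category = category, sub_category = sub, clinical_cat = clin)
  }
  bind_rows(
    r("event", "event_label",
      "^(systolic blood pressure|heart rate|respiratory rate|oxygen saturation)$",
      "event", "measurements", "vitals"),
    r("event", "event_label", "^(weight|prepregnancy bmi)$",
      "event", "measurements", "weight and BMI"),
    r("event", "event_label", "^(hemoglobin|platelet count)$",
      "event", "labs", "hematology"),
    r("event", "event_label", "^(glucose|creatinine|alt|ast)$",
      "event", "labs", "metabolic panel"),
    r("event", "event_label",
      paste0("^(dyspnea|shortness of breath|orthopnea|tachypnea|chest pain|",
             "heart palpitations|palpitations|dizziness|syncope|",
             "new or worsening headache|swelling in face or hands|",
             "facial swelling|asthma unresponsive to therapy|",
             "nausea of pregnancy)$"),
      "event", "symptoms"),
    r("event", "event_label", "^(loud heart murmur|basilar crackles)",
      "event", "physical findings"),
    r("event", "event_label", "^(history of|prepregnancy )",
      "event", "history"),
    r("diagnosis", "diagnosis_type", "^admitting diagnosis$",
      "diagnosis", "admitting diagnosis"),
    r("diagnosis", "diagnosis_type", "^discharge diagnosis$",
      "diagnosis", "discharge diagnosis"),
    r("diagnosis", "diagnosis_type", "^encounter diagnosis$",
      "diagnosis", "encounter diagnosis"),
    r("diagnosis", "diagnosis_type", "^procedure$",
      "diagnosis", "procedure")
  )
}

#' Read or write categorization rules as YAML
#' @param path YAML file path.
#' @param rules A rules tibble as returned by [category_rules()].
#' @return `read_category_rules()` returns a rules tibble.
#' @export
read_category_rules <- function(path) {
  purrr::map_dfr(yaml::read_yaml(path), function(r) {
    tibble(target = r$target, field = r$field, pattern = r$pattern,
           category = r$category, sub_category = r$sub_category,
           clinical_cat = r$clinical_cat %||% NA_character_)
  })
}

#' @rdname read_category_rules
#' @export
write_category_rules <- function(rules, path) {
  yaml::write_yaml(purrr::pmap(rules, function(...) {
    x <- list(...)
    x[!vapply(x, function(v) length(v) == 1 && is.na(v), logical(1))]
  }), path)
  invisible(path)
}

#' Assign category triples to records
#'
#' Applies the rule set in order (first match wins) on the configured field
#' of each record. Categorization is total: every input row comes back
#' either categorized or flagged for the review queue
#' (`matched == FALSE`).
#'
#' @param records A tibble of events or diagnoses.
#' @param rules A rules tibble, filtered internally to `target`.
#' @param target `"event"` or `"diagnosis"`.
#' @return `records` with `category`, `sub_category`, `clinical_cat`, and
#'   `matched` columns appended.
#' @export
categorize_records <- function(records, rules = category_rules(),
                               target = c("event", "diagnosis")) {
  target <- match.arg(target)
  rules <- filter(rules, .data$target == !!target)
  out <- records |>
    mutate(category = NA_character_, sub_category = NA_character_,
           clinical_cat = NA_character_, matched = FALSE)
  for (k in seq_len(nrow(rules))) {
    field_vals <- tolower(out[[rules$field[k]]])
    hit <- !out$matched & grepl(rules$pattern[k], field_vals,
                                ignore.case = TRUE)
    out$category[hit] <- rules$category[k]
    out$sub_category[hit] <- rules$sub_category[k]
    out$clinical_cat[hit] <- rules$clinical_cat[k]
    out$matched <- out$matched | hit
  }
  out
}

KG_PER_LB <- 0.45359237

#' Normalize observation values to canonical units
#'
#' Weight entered in pounds is converted to kilograms
#' (`lb * 0.45359237`, rounded to 0.01 kg); values already in a canonical
#' unit (kg, mm Hg, bpm, %, breaths/min, kg/m2, g/dL, mg/dL or unitless)
#' pass through; unknown units are flagged for review and excluded from
#' risk evaluation. Idempotent: normalizing twice equals normalizing once.
#'
#' @param value Numeric vector of observed values.
#' @param unit Character vector of unit labels.
#' @return A tibble with columns `value`, `unit` (canonical), `flagged`.
#' @export
#' @examples
#' normalize_value(154.324, "lb")
normalize_value <- function(value, unit) {
  canonical <- c("kg", "mm Hg", "bpm", "%", "breaths/min", "kg/m2", "g/dL",
                 "mg/dL", "")
  unit <- as.character(unit)
  unit[is.na(unit)] <- ""
  is_lb <- unit == "lb"
  pass <- unit %in% canonical
  tibble(
    value = dplyr::case_when(
      is_lb ~ round(value * KG_PER_LB, 2),
      pass ~ value,
      TRUE ~ value
    ),
    unit = dplyr::case_when(is_lb ~ "kg", TRUE ~ unit),
    flagged = !(is_lb | pass) & !is.na(value)
  )
}

# field-level descriptions backing the data catalog
.catalog_descriptions <- c(
  "Person.person_id" = "Pseudonymized patient identifier",
  "Person.visit_id" = "Pseudonymized identifier of the patient's index visit",
  "Person.age_at_index" = "Age in completed years at the index visit",
  "Person.urbanicity" = "Urban/rural/suburban generalization of residence zip",
  "Visit.visit_id" = "Pseudonymized encounter identifier",
  "Visit.person_id" = "Pseudonymized patient identifier",
  "Visit.day_offset" = "Calendar days from the patient's index visit",
  "Visit.registration_time" = "Registration clock time (HH:MM:SS)",
  "Visit.visit_type" = "Encounter type (clinic appointment, admission, ...)",
  "Event.person_id" = "Pseudonymized patient identifier",
  "Event.visit_id" = "Pseudonymized encounter identifier",
  "Event.event_label" = "Observation label (shared value field design)",
  "Event.value" = "Observation value in the canonical unit",
  "Event.unit" = "Canonical result unit",
  "Event.category" = "CATEGORY: parent hierarchy (source table family)",
  "Event.sub_category" = "SUB_CATEGORY: context-dependent grouping",
  "Event.clinical_cat" = "CLINICAL_CAT: optional clinical grouping",
  "Event.day_offset" = "Calendar days from the patient's index visit",
  "Event.event_time" = "Event clock time for within-day sequencing",
  "Event.flagged_unit" = "TRUE when the source unit was unknown (review)",
  "Diagnosis.person_id" = "Pseudonymized patient identifier",
  "Diagnosis.visit_id" = "Pseudonymized encounter identifier",
  "Diagnosis.code" = "Diagnosis or procedure code",
  "Diagnosis.code_system" = "Coding system of the code",
  "Diagnosis.category" = "CATEGORY: parent hierarchy",
  "Diagnosis.sub_category" = "SUB_CATEGORY: diagnosis context",
  "Diagnosis.day_offset" = "Calendar days from the patient's index visit",
  "Diagnosis.diagnosis_time" = "Diagnosis clock time",
  "FamilyHX.person_id" = "Pseudonymized patient identifier",
  "FamilyHX.item" = "Family-history item (person grain)",
  "Race.person_id" = "Pseudonymized patient identifier",
  "Race.race" = "Self-reported race (person grain)"
)

build_data_catalog <- function(tables) {
  purrr::imap_dfr(tables, function(tbl, nm) {
    tibble(
      table = nm,
      field = names(tbl),
      description = unname(.catalog_descriptions[paste(nm, names(tbl),
                                                       sep = ".")]),
      source = "matcvrisk harmonization",
      last_updated = sprintf("rows=%d", nrow(tbl))
    )
  }) |>
    mutate(description = dplyr::coalesce(.data$description,
                                         "Implementation-defined field"))
}

#' Assemble the final harmonized relational schema
#'
#' Builds the six analysis tables (Person, Visit, Event, Diagnosis,
#' FamilyHX, Race) from a de-identified record set: parses the shared
#' character result field to numeric where possible, normalizes units,
#' collapses exact duplicate observations, attaches category triples, and
#' regenerates the data catalog covering every emitted field. All tables
#' except FamilyHX and Race carry both the pseudonymized person id and a
#' visit id.
#'
#' @param deid A `deid_record_set` from [deidentify_records()].
#' @param rules Categorization rules, see [category_rules()].
#' @return A `harmonized_record_set`: list of the six tables plus
#'   `catalog` (the data dictionary) and `review_queue` (uncategorized
#'   records).
#' @export
harmonize_records <- function(deid, rules = category_rules()) {
  stopifnot(inherits(deid, "deid_record_set"))

  ev <- deid$events |>
    distinct(.data$person_id, .data$visit_id, .data$event_label,
             .data$result_value, .data$result_unit, .data$day_offset,
             .data$event_time) |>
    categorize_records(rules, target = "event")
  num <- suppressWarnings(as.numeric(ev$result_value))
  norm <- normalize_value(num, ev$result_unit)
  event_tbl <- ev |>
    mutate(value = norm$value, unit = norm$unit,
           flagged_unit = norm$flagged) |>
    select("person_id", "visit_id", "event_label", "value", "unit",
           "category", "sub_category", "clinical_cat", "day_offset",
           "event_time", "flagged_unit", "matched") |>
    arrange(.data$person_id, .data$day_offset, .data$event_time,
            .data$event_label)

  dxc <- categorize_records(deid$diagnoses, rules, target = "diagnosis")
  diagnosis_tbl <- dxc |>
    select("person_id", "visit_id", "code", "code_system", "category",
           "sub_category", "day_offset", "diagnosis_time", "matched") |>
    arrange(.data$person_id, .data$day_offset, .data$code)

  index_visit <- deid$visits |>
    group_by(.data$person_id) |>
    slice_min(.data$day_offset, n = 1L, with_ties = FALSE) |>
    ungroup() |>
    select("person_id", index_visit_id = "visit_id")

  person_tbl <- deid$persons |>
    left_join(index_visit, by = "person_id") |>
    transmute(.data$person_id, visit_id = .data$index_visit_id,
              .data$age_at_index, .data$urbanicity) |>
    arrange(.data$person_id)
  race_tbl <- deid$persons |>
    select("person_id", "race") |>
    arrange(.data$person_id)
  visit_tbl <- deid$visits |>
    select("visit_id", "person_id", "day_offset", "registration_time",
           "visit_type") |>
    arrange(.data$person_id, .data$day_offset, .data$visit_id)
  fh_tbl <- deid$family_history |> arrange(.data$person_id, .data$item)

  # orphan events are an integrity error, not a warning
  orphans <- setdiff(event_tbl$visit_id, visit_tbl$visit_id)
  if (length(orphans)) {
    abort(paste0("Events reference unknown visits: ",
                 paste(head(orphans, 5L), collapse = ", ")),
          class = "matcvrisk_integrity_error")
  }

  review_queue <- bind_rows(
    event_tbl |> filter(!.data$matched) |>
      transmute(.data$person_id, .data$visit_id, kind = "event",
                label = .data$event_label),
    diagnosis_tbl |> filter(!.data$matched) |>
      transmute(.data$person_id, .data$visit_id, kind = "diagnosis",
                label = .data$code)
  )
  event_tbl <- select(event_tbl, -"matched")
  diagnosis_tbl <- select(diagnosis_tbl, -"matched")

  tables <- list(Person = person_tbl, Visit = visit_tbl, Event = event_tbl,
                 Diagnosis = diagnosis_tbl, FamilyHX = fh_tbl, Race = race_tbl)
  structure(
    c(tables, list(catalog = build_data_catalog(tables),
                   review_queue = review_queue)),
    class = "harmonized_record_set"
  )
}

#' @export
print.harmonized_record_set <- function(x, ...) {
  cat("<harmonized_record_set>\n")
  for (nm in c("Person", "Visit", "Event", "Diagnosis", "FamilyHX", "Race")) {
    cat(sprintf("  %-10s %6d rows\n", nm, nrow(x[[nm]])))
  }
  cat(sprintf("  catalog: %d fields; review queue: %d records\n",
              nrow(x$catalog), nrow(x$review_queue)))
  invisible(x)
}

#' Read a harmonized record set back from its CSV export
#' @param dir Directory written by [write_harmonized_records()].
#' @return A `harmonized_record_set`.
#' @export
read_harmonized_records <- function(dir) {
  rd <- function(f, types) {
    readr::read_csv(file.path(dir, f), col_types = types, progress = FALSE,
                    na = "NA")
  }
  tables <- list(
    Person = rd("Person.csv", readr::cols(
      person_id = "c", visit_id = "c", age_at_index = "i", urbanicity = "c")),
    Visit = rd("Visit.csv", readr::cols(
      visit_id = "c", person_id = "c", day_offset = "i",
      registration_time = "c", visit_type = "c")),
    Event = rd("Event.csv", readr::cols(
      person_id = "c", visit_id = "c", event_label = "c", value = "d",
      unit = "c", category = "c", sub_category = "c", clinical_cat = "c",
      day_offset = "i", event_time = "c", flagged_unit = "l")),
    Diagnosis = rd("Diagnosis.csv", readr::cols(
      person_id = "c", visit_id = "c", code = "c", code_system = "c",
      category = "c", sub_category = "c", day_offset = "i",
      diagnosis_time = "c")),
    FamilyHX = rd("FamilyHX.csv", readr::cols(person_id = "c", item = "c")),
    Race = rd("Race.csv", readr::cols(person_id = "c", race = "c"))
  )
  structure(
    c(tables, list(
      catalog = rd("data_catalog.csv", readr::cols(.default = "c")),
      review_queue = rd("review_queue.csv", readr::cols(.default = "c"))
    )),
    class = "harmonized_record_set"
  )
}

#' Write harmonized tables, catalog and review queue as CSV
#' @param harmonized A `harmonized_record_set`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_harmonized_records <- function(harmonized, dir) {
  stopifnot(inherits(harmonized, "harmonized_record_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("Person", "Visit", "Event", "Diagnosis", "FamilyHX", "Race")) {
    readr::write_csv(harmonized[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  readr::write_csv(harmonized$catalog, file.path(dir, "data_catalog.csv"))
  readr::write_csv(harmonized$review_queue, file.path(dir, "review_queue.csv"))
  invisible(dir)
}
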