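#' Classify zip codes as urban, rural, or suburban
#'
#' Generalizes geography: each zip is looked up in an urbanicity table and
#' only the class is retained downstream; the zip itself never appears in
#' the de-identified export. Zips absent from the table map to
#' `"unknown"` with a warning rather than an error.
#'
#' @param zip Character vector of 5-digit zip codes.
#' @param table A lookup tibble with columns `zip` and `class`
#'   (urban/rural/suburban), e.g. [synthetic_urbanicity_table()] or
#'   [read_urbanicity_table()].
#' @return A character vector of classes.
#' @export
#' @examples
#' classify_zip("30001", synthetic_urbanicity_table())
classify_zip <- function(zip, table = synthetic_urbanicity_table()) {
  stopifnot(all(c("zip", "class") %in% names(table)))
  bad <- setdiff(unique(table$class), c("urban", "rural", "suburban"))
  if (length(bad)) {
    abort(paste0("Urbanicity classes limited to urban/rural/suburban; found: ",
                 paste(bad, collapse = ", ")),
          class = "matcvrisk_config_error")
  }
  cls <- table$class[match(zip, table$zip)]
  if (anyNA(cls)) {
    warn(sprintf("%d zip code(s) missing from the urbanicity table; classed 'unknown'.",
                 sum(is.na(cls))))
    cls[is.na(cls)] <- "unknown"
  }
  cls
}

#' Read an urbanicity table from a two-column CSV
#' @param path CSV with columns `zip`, `class`.
#' @return A tibble.
#' @export
read_urbanicity_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(zip = "c", class = "c"),
                  progress = FALSE)
}

#' Compute day offsets from each patient's index visit
#'
#' The index visit is a patient's earliest included encounter; its offset
#' is 0 and every other encounter's offset is the calendar-day difference
#' to it. Clock times are retained separately for within-day sequencing.
#' Offsets may be negative for records imported from before the index
#' visit.
#'
#' @param visits A tibble with columns `visit_id`, `person_id`, and
#'   `registration_datetime` (included visits only).
#' @return A tibble `visit_id`, `person_id`, `day_offset`,
#'   `registration_time`.
#' @export
compute_day_offsets <- function(visits) {
  stopifnot(nrow(visits) >= 1L)
  visits |>
    group_by(.data$person_id) |>
    mutate(
      day_offset = days_between(min(as.Date(.data$registration_datetime)),
                                as.Date(.data$registration_datetime)),
      registration_time = format(.data$registration_datetime, "%H:%M:%S",
                                 tz = "UTC")
    ) |>
    ungroup() |>
    select("visit_id", "person_id", "day_offset", "registration_time")
}

#' Pseudonymize person and visit ids with a keyed one-way transform
#'
#' Each id is replaced by the first 16 hex characters of an HMAC-SHA256 of
#' the id under a secret salt: deterministic for a fixed salt, one-way
#' without it. Collisions abort with the colliding inputs named. The
#' returned master key holds the salt and the forward/inverse maps,
#' permitting exact recovery of originals for revalidation; it must be
#' stored in the trusted zone, never alongside the analysis export.
#'
#' @param ids Character vector of original ids.
#' @param salt Secret character salt.
#' @return A tibble with columns `original` and `pseudonym`.
#' @export
pseudonymize_ids <- function(ids, salt) {
  stopifnot(is.character(salt), length(salt) == 1L, nzchar(salt))
  ids <- unique(ids)
  pseud <- vapply(ids, function(id) {
    substr(digest::hmac(salt, id, algo = "sha256"), 1L, 16L)
  }, character(1), USE.NAMES = FALSE)
  dup <- duplicated(pseud) | duplicated(pseud, fromLast = TRUE)
  if (any(dup)) {
    abort(paste0("Pseudonym collision for ids: ",
                 paste(ids[dup], collapse = ", ")),
          class = "matcvrisk_integrity_error")
  }
  tibble(original = ids, pseudonym = pseud)
}

#' Recover original ids from a master key
#' @param key A `master_key` from [deidentify_records()].
#' @param pseudonyms Character vector of pseudonymized ids.
#' @param type `"person"` or `"visit"`.
#' @return Character vector of original ids (NA where unknown).
#' @export
lookup_original_id <- function(key, pseudonyms, type = c("person", "visit")) {
  type <- match.arg(type)
  map <- if (type == "person") key$persons else key$visits
  map$original[match(pseudonyms, map$pseudonym)]
}

default_free_text_labels <- function() {
  c("comment", "note", "registration note", "free text", "date entry")
}

#' Strip free-text entry events
#'
#' Removes events whose label is in the configured free-text /comment/
#' date-entry list, where identifying information could have been typed;
#' all other events pass through unchanged. Removal counts are attached as
#' an attribute.
#'
#' @param events An event tibble with an `event_label` column.
#' @param labels Labels (case-insensitive) to remove.
#' @return The filtered event tibble with attribute `removed` (named
#'   counts per stripped label).
#' @export
strip_free_text <- function(events, labels = default_free_text_labels()) {
  hit <- tolower(events$event_label) %in% tolower(labels)
  out <- events[!hit, , drop = FALSE]
  removed <- table(tolower(events$event_label[hit]))
  attr(out, "removed") <- setNames(as.integer(removed), names(removed))
  out
}

#' De-identify an extracted record set
#'
#' Applies the anonymization stages in order: restriction to included
#' encounters, free-text stripping, geographic generalization
#' (zip to urbanicity), date splitting with index-visit day offsets (dates
#' of birth replaced by age at index in completed years), and keyed
#' pseudonymization of person and visit ids with referential integrity
#' preserved across every table. Diagnosis rows of cohort members keep
#' their day offsets even when attached to non-included encounters (e.g.
#' the delivery admission), so downstream lead-time evaluation can see
#' provider actions.
#'
#' @param records A `raw_record_set`.
#' @param included_visits Visit ids surviving [extract_cohort()].
#' @param salt Secret salt for pseudonymization.
#' @param urbanicity Urbanicity lookup table.
#' @param free_text_labels Event labels stripped as free text.
#' @return A list with `records` (a `deid_record_set`: tibbles `persons`,
#'   `visits`, `events`, `diagnoses`, `family_history`) and `master_key`
#'   (a `master_key`: salt plus person and visit id maps).
#' @export
deidentify_records <- function(records, included_visits, salt,
                               urbanicity = synthetic_urbanicity_table(),
                               free_text_labels = default_free_text_labels()) {
  stopifnot(inherits(records, "raw_record_set"))
  visits <- records$visits |> filter(.data$visit_id %in% included_visits)
  if (nrow(visits) == 0L) {
    abort("No included visits to de-identify.",
          class = "matcvrisk_validation_error")
  }
  persons <- records$persons |> filter(.data$person_id %in% visits$person_id)
  events <- records$events |>
    filter(.data$visit_id %in% included_visits) |>
    strip_free_text(free_text_labels)
  stripped_counts <- attr(events, "removed")
  attr(events, "removed") <- NULL
  diagnoses <- records$diagnoses |>
    filter(.data$person_id %in% persons$person_id)
  family_history <- records$family_history |>
    filter(.data$person_id %in% persons$person_id)

  offsets <- compute_day_offsets(visits)
  index_dates <- visits |>
    group_by(.data$person_id) |>
    summarise(index_date = min(as.Date(.data$registration_datetime)),
              .groups = "drop")

  pmap <- pseudonymize_ids(persons$person_id, salt)
  vmap <- pseudonymize_ids(unique(c(visits$visit_id, diagnoses$visit_id)), salt)
  p_of <- function(x) pmap$pseudonym[match(x, pmap$original)]
  v_of <- function(x) vmap$pseudonym[match(x, vmap$original)]

  deid_persons <- persons |>
    left_join(index_dates, by = "person_id") |>
    transmute(
      person_id = p_of(.data$person_id),
      age_at_index = age_in_completed_years(.data$date_of_birth,
                                            .data$index_date),
      race = .data$race,
      urbanicity = classify_zip(.data$zip, urbanicity)
    )
  deid_visits <- visits |>
    left_join(offsets, by = c("visit_id", "person_id")) |>
    transmute(
      visit_id = v_of(.data$visit_id),
      person_id = p_of(.data$person_id),
      day_offset = .data$day_offset,
      registration_time = .data$registration_time,
      visit_type = .data$visit_type
    )
  deid_events <- events |>
    left_join(index_dates, by = "person_id") |>
    transmute(
      visit_id = v_of(.data$visit_id),
      person_id = p_of(.data$person_id),
      event_label = .data$event_label,
      result_value = .data$result_value,
      result_unit = .data$result_unit,
      day_offset = days_between(.data$index_date,
                                as.Date(.data$event_datetime)),
      event_time = format(.data$event_datetime, "%H:%M:%S", tz = "UTC")
    )
  deid_diagnoses <- diagnoses |>
    left_join(index_dates, by = "person_id") |>
    transmute(
      visit_id = v_of(.data$visit_id),
      person_id = p_of(.data$person_id),
      code = .data$code,
      code_system = .data$code_system,
      diagnosis_type = .data$diagnosis_type,
      day_offset = days_between(.data$index_date,
                                as.Date(.data$diagnosis_datetime)),
      diagnosis_time = format(.data$diagnosis_datetime, "%H:%M:%S", tz = "UTC")
    )
  deid_fh <- family_history |>
    transmute(person_id = p_of(.data$person_id), item = .data$item)

  key <- structure(list(salt = salt, persons = pmap, visits = vmap),
                   class = "master_key")
  deid <- structure(
    list(persons = deid_persons, visits = deid_visits, events = deid_events,
         diagnoses = deid_diagnoses, family_history = deid_fh,
         stripped = stripped_counts),
    class = "deid_record_set"
  )
  list(records = deid, master_key = key)
}

#' Read a de-identified record set back from its CSV export
#' @param dir Directory written by [write_deid_records()].
#' @return A `deid_record_set`.
#' @export
read_deid_records <- function(dir) {
  rd <- function(f, types) {
    readr::read_csv(file.path(dir, f), col_types = types, progress = FALSE,
                    na = "NA")
  }
  structure(
    list(
      persons = rd("person.csv", readr::cols(
        person_id = "c", age_at_index = "i", race = "c", urbanicity = "c")),
      visits = rd("visit.csv", readr::cols(
        visit_id = "c", person_id = "c", day_offset = "i",
        registration_time = "c", visit_type = "c")),
      events = rd("clinical_event.csv", readr::cols(
        visit_id = "c", person_id = "c", event_label = "c",
        result_value = "c", result_unit = "c", day_offset = "i",
        event_time = "c")),
      diagnoses = rd("diagnosis.csv", readr::cols(
        visit_id = "c", person_id = "c", code = "c", code_system = "c",
        diagnosis_type = "c", day_offset = "i", diagnosis_time = "c")),
      family_history = rd("family_history.csv",
                          readr::cols(person_id = "c", item = "c")),
      stripped = NULL
    ),
    class = "deid_record_set"
  )
}

#' @export
print.deid_record_set <- function(x, ...) {
  cat("<deid_record_set>\n")
  for (nm in c("persons", "visits", "events", "diagnoses", "family_history")) {
    cat(sprintf("  %-15s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' @export
print.master_key <- function(x, ...) {
  cat(sprintf("<master_key> %d person ids, %d visit ids (salt withheld)\n",
              nrow(x$persons), nrow(x$visits)))
  invisible(x)
}

#' Write a de-identified record set (and, separately, its master key)
#'
#' The analysis export and the master key are never co-located: the key is
#' written only when `key_dir` is supplied and must point somewhere other
#' than `dir`.
#'
#' @param deid A `deid_record_set`.
#' @param dir Output directory for the analysis export.
#' @param master_key Optional `master_key`.
#' @param key_dir Access-restricted directory for the key; must differ
#'   from `dir`. Omit (default) to disable key emission.
#' @return `dir`, invisibly.
#' @export
write_deid_records <- function(deid, dir, master_key = NULL, key_dir = NULL) {
  stopifnot(inherits(deid, "deid_record_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(persons = "person.csv", visits = "visit.csv",
             events = "clinical_event.csv", diagnoses = "diagnosis.csv",
             family_history = "family_history.csv")
  for (nm in names(files)) {
    readr::write_csv(deid[[nm]], file.path(dir, files[[nm]]))
  }
  if (!is.null(master_key)) {
    if (is.null(key_dir) || normalizePath(key_dir, mustWork = FALSE) ==
        normalizePath(dir, mustWork = FALSE)) {
      abort("The master key must be written to a separate, restricted directory.",
            class = "matcvrisk_config_error")
    }
    dir.create(key_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(master_key$persons, file.path(key_dir, "key_persons.csv"))
    readr::write_csv(master_key$visits, file.path(key_dir, "key_visits.csv"))
  }
  invisible(dir)
}
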