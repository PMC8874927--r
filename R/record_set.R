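#' Construct a raw (identifiable) visit-centric record set
#'
#' Bundles the five source tables of a visit-centric EHR extract and checks
#' referential integrity: unique person/visit ids, every visit referencing
#' an existing person, every event and diagnosis referencing an existing
#' visit. The clinical-event table uses one shared character result-value
#' field for every variable plus a unit field, mirroring the source data
#' model.
#'
#' @param persons,visits,events,diagnoses,family_history Tibbles with the
#'   documented columns (see the synthetic generator for the canonical
#'   headers).
#' @return A `raw_record_set` (a named list of tibbles).
#' @export
raw_record_set <- function(persons, visits, events, diagnoses, family_history) {
  x <- structure(
    list(persons = as_tibble(persons), visits = as_tibble(visits),
         events = as_tibble(events), diagnoses = as_tibble(diagnoses),
         family_history = as_tibble(family_history)),
    class = "raw_record_set"
  )
  validate_record_set(x)
}

validate_record_set <- function(x) {
  if (anyDuplicated(x$persons$person_id)) {
    abort("Duplicate person ids.", class = "matcvrisk_integrity_error")
  }
  if (anyDuplicated(x$visits$visit_id)) {
    abort("Duplicate visit ids.", class = "matcvrisk_integrity_error")
  }
  orphan_v <- setdiff(x$visits$person_id, x$persons$person_id)
  orphan_e <- setdiff(x$events$visit_id, x$visits$visit_id)
  orphan_d <- setdiff(x$diagnoses$visit_id, x$visits$visit_id)
  if (length(orphan_v) || length(orphan_e) || length(orphan_d)) {
    abort(
      sprintf("Referential integrity violated (%d visits, %d events, %d diagnoses orphaned).",
              length(orphan_v), length(orphan_e), length(orphan_d)),
      class = "matcvrisk_integrity_error"
    )
  }
  x
}

#' @export
print.raw_record_set <- function(x, ...) {
  cat("<raw_record_set>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-15s %6d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, seed %d\n",
              nrow(x$truth$patients), x$config$seed))
  print(x$records)
  grp <- table(x$truth$patients$risk_group)
  cat("  planted risk groups:",
      paste(sprintf("%s=%d", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}

#' Inject artifact visits (historical uploads and communications)
#'
#' Adds the two artifact classes the extraction filters must remove:
#' visits whose registration date falls in the year 1900 (historical
#' uploads from another source) and communication-only visits (patient
#' portal messages, phone calls) carrying zero clinical events. Both
#' classes carry a pregnancy-supervision diagnosis code so they reach the
#' exclusion stage rather than silently failing the prenatal-code filter;
#' every injected visit is recorded in the ground truth for
#' filter-verification. With `frac_artifact_visits = 0` the cohort is
#' returned unchanged.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param config The same [generator_config()]; injection count is
#'   `frac_artifact_visits` times the current visit count. A seed offset of
#'   the configured seed keeps injection deterministic and independent of
#'   the generation stream.
#' @return The cohort with artifact visits appended and
#'   `truth$artifacts` populated.
#' @export
inject_artifacts <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "synthetic_cohort"),
            inherits(config, "generator_config"))
  n_inject <- round(config$frac_artifact_visits * nrow(cohort$records$visits))
  if (n_inject == 0L) {
    return(cohort)
  }
  withr::with_seed(config$seed + 1L, inject_artifacts_impl(cohort, n_inject))
}

inject_artifacts_impl <- function(cohort, n_inject) {
  records <- cohort$records
  truth <- cohort$truth
  pat <- truth$patients

  n_1900 <- n_inject %/% 2L
  n_comm <- n_inject - n_1900
  kind <- c(rep("registration_1900", n_1900), rep("communication", n_comm))
  who <- sample(pat$person_id, n_inject, replace = TRUE)
  pat_idx <- match(who, pat$person_id)

  date_1900 <- as.Date("1900-01-01") + sample(0:364, n_inject, replace = TRUE)
  date_comm <- pat$delivery_date[pat_idx] - sample(1:250, n_inject, replace = TRUE)
  vdate <- dplyr::if_else(kind == "registration_1900", date_1900, date_comm)
  vtype <- ifelse(kind == "registration_1900", "historical upload",
                  sample(c("portal message", "phone call"), n_inject,
                         replace = TRUE))
  visit_id <- format_ids("VA", seq_len(n_inject), 5L)

  new_visits <- tibble(
    visit_id = visit_id, person_id = who,
    registration_datetime = as.POSIXct(paste(vdate, random_times(n_inject)),
                                       tz = "UTC"),
    visit_type = vtype
  )
  new_dx <- tibble(
    diagnosis_id = format_ids("DA", seq_len(n_inject), 5L),
    visit_id = visit_id, person_id = who,
    code = sample(.prenatal_code_pool, n_inject, replace = TRUE),
    code_system = "ICD-10-CM", diagnosis_type = "encounter diagnosis",
    diagnosis_datetime = as.POSIXct(paste(vdate, random_times(n_inject)),
                                    tz = "UTC")
  )
  # about half of the historical uploads carry an imported vital so the
  # 1900-exclusion is exercised on visits that DO have clinical data
  is_1900 <- kind == "registration_1900"
  carry <- is_1900 & runif(n_inject) < 0.5
  new_events <- tibble(
    event_id = format_ids("EA", seq_len(sum(carry)), 5L),
    visit_id = visit_id[carry], person_id = who[carry],
    event_label = "systolic blood pressure",
    result_value = as.character(round(rnorm(sum(carry), 114, 5))),
    result_unit = "mm Hg",
    event_datetime = as.POSIXct(paste(vdate[carry], random_times(sum(carry))),
                                tz = "UTC")
  )

  records$visits <- bind_rows(records$visits, new_visits)
  records$diagnoses <- bind_rows(records$diagnoses, new_dx)
  records$events <- bind_rows(records$events, new_events)
  truth$artifacts <- bind_rows(
    truth$artifacts,
    tibble(visit_id = visit_id, person_id = who, kind = kind)
  )
  cohort$records <- validate_record_set(records)
  cohort$truth <- truth
  cohort
}

# CSV serialization ---------------------------------------------------------

#' Write or read a raw record set as one CSV per table
#'
#' Raw exports use ISO-8601 dates and datetimes and a header row, one file
#' per table (`person.csv`, `visit.csv`, `clinical_event.csv`,
#' `diagnosis.csv`, `family_history.csv`). `write_ground_truth()` writes
#' the ground-truth tibbles alongside
#' (`ground_truth_patients.csv`, `ground_truth_trajectories.csv`,
#' `ground_truth_artifacts.csv`).
#'
#' @param records A `raw_record_set`.
#' @param dir Output (or input) directory; created if missing.
#' @return `write_raw_records()` and `write_ground_truth()` return the
#'   directory invisibly; `read_raw_records()` returns a `raw_record_set`.
#' @export
write_raw_records <- function(records, dir) {
  stopifnot(inherits(records, "raw_record_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(persons = "person.csv", visits = "visit.csv",
             events = "clinical_event.csv", diagnoses = "diagnosis.csv",
             family_history = "family_history.csv")
  for (nm in names(files)) {
    readr::write_csv(records[[nm]], file.path(dir, files[[nm]]))
  }
  invisible(dir)
}

#' @rdname write_raw_records
#' @export
read_raw_records <- function(dir) {
  rd <- function(f, types) {
    readr::read_csv(file.path(dir, f), col_types = types, progress = FALSE,
                    na = "NA")
  }
  raw_record_set(
    persons = rd("person.csv", readr::cols(
      person_id = "c", given_name = "c", family_name = "c",
      date_of_birth = readr::col_date(), race = "c", zip = "c")),
    visits = rd("visit.csv", readr::cols(
      visit_id = "c", person_id = "c",
      registration_datetime = readr::col_datetime(), visit_type = "c")),
    events = rd("clinical_event.csv", readr::cols(
      event_id = "c", visit_id = "c", person_id = "c", event_label = "c",
      result_value = "c", result_unit = "c",
      event_datetime = readr::col_datetime())),
    diagnoses = rd("diagnosis.csv", readr::cols(
      diagnosis_id = "c", visit_id = "c", person_id = "c", code = "c",
      code_system = "c", diagnosis_type = "c",
      diagnosis_datetime = readr::col_datetime())),
    family_history = rd("family_history.csv",
                        readr::cols(person_id = "c", item = "c"))
  )
}

#' @rdname write_raw_records
#' @param truth A `ground_truth` object.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(truth$patients, file.path(dir, "ground_truth_patients.csv"))
  readr::write_csv(truth$trajectories,
                   file.path(dir, "ground_truth_trajectories.csv"))
  readr::write_csv(truth$artifacts,
                   file.path(dir, "ground_truth_artifacts.csv"))
  invisible(dir)
}
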