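# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# noise-free 500-patient cohort run end to end: the study-condition fixture
noise_free_run <- function() {
  cached("noise_free_run", function() {
    cfg <- generator_config(n_patients = 500, noise_sd = 0, seed = 101)
    cohort <- inject_artifacts(generate_cohort(cfg))
    extraction <- extract_cohort(cohort$records)
    deid <- deidentify_records(cohort$records, extraction$included_visits,
                               salt = "fixture-salt")
    harmonized <- harmonize_records(deid$records)
    assessment <- assess_cohort(harmonized)
    deltas <- evaluate_deltas(assessment, harmonized)
    list(config = cfg, cohort = cohort, extraction = extraction,
         deid = deid$records, key = deid$master_key,
         harmonized = harmonized, assessment = assessment, deltas = deltas)
  })
}

# map pseudonymized person ids in `tbl` back to originals as column `orig`
with_original_ids <- function(tbl, key) {
  tbl$orig <- lookup_original_id(key, tbl$person_id, "person")
  tbl
}

# NA-aware elementwise equality
eq_na <- function(x, y) {
  (is.na(x) & is.na(y)) | (!is.na(x) & !is.na(y) & x == y)
}

# a tiny hand-built raw record set: four patients around the age and date
# boundaries, one 1900 artifact, one communication visit, one missing DOB
boundary_record_set <- function() {
  mk_dt <- function(x) as.POSIXct(paste(x, "10:00:00"), tz = "UTC")
  persons <- tibble::tibble(
    person_id = sprintf("P%05d", 1:6),
    given_name = "Test", family_name = "Patient",
    # ages at the 2018-06-01 encounter: 17, 18, 35, 36, 25, NA
    date_of_birth = as.Date(c("2000-06-02", "2000-06-01", "1983-06-01",
                              "1982-05-31", "1993-01-01", NA)),
    race = "Other", zip = "30001"
  )
  visits <- tibble::tibble(
    visit_id = sprintf("V%06d", 1:9),
    person_id = c(sprintf("P%05d", 1:6), "P00005", "P00005", "P00005"),
    registration_datetime = mk_dt(c(rep("2018-06-01", 6), "1900-03-01",
                                    "2018-06-10", "2018-06-20")),
    visit_type = c(rep("clinic appointment", 6), "historical upload",
                   "portal message", "portal message")
  )
  events <- tibble::tibble(
    event_id = "E0000001", visit_id = "V000009", person_id = "P00005",
    event_label = "systolic blood pressure", result_value = "118",
    result_unit = "mm Hg", event_datetime = mk_dt("2018-06-20")
  )
  diagnoses <- tibble::tibble(
    diagnosis_id = sprintf("D%03d", 1:15),
    visit_id = c(sprintf("V%06d", 1:9), sprintf("V%06d", 1:6)),
    person_id = c(persons$person_id, "P00005", "P00005", "P00005",
                  persons$person_id),
    code = c(rep("Z34.90", 9), rep("10D00Z0", 6)),
    code_system = c(rep("ICD-10-CM", 9), rep("ICD-10-PCS", 6)),
    diagnosis_type = c(rep("encounter diagnosis", 9), rep("procedure", 6)),
    diagnosis_datetime = mk_dt(c(rep("2018-06-01", 6), "1900-03-01",
                                 "2018-06-10", "2018-06-20",
                                 rep("2018-07-15", 6)))
  )
  raw_record_set(
    persons = persons, visits = visits, events = events,
    diagnoses = diagnoses,
    family_history = tibble::tibble(person_id = character(),
                                    item = character())
  )
}

# minimal harmonized set for one patient with a scripted vital timeline
scripted_harmonized <- function(sbp = c(118, 141, 165),
                                days = c(0L, 20L, 40L),
                                race = "Other", bmi = 24,
                                history = character(0),
                                age = 28L) {
  pid <- "patient01"
  vid <- sprintf("visit%02d", seq_along(days))
  events <- tibble::tibble(
    person_id = pid, visit_id = vid, event_label = "systolic blood pressure",
    value = sbp, unit = "mm Hg", category = "event",
    sub_category = "measurements", clinical_cat = "vitals",
    day_offset = days, event_time = "09:00:00", flagged_unit = FALSE
  )
  extra <- tibble::tibble(
    person_id = pid, visit_id = vid[1],
    event_label = c("prepregnancy BMI", history),
    value = c(bmi, rep(NA_real_, length(history))),
    unit = c("kg/m2", rep("", length(history))),
    category = "event",
    sub_category = c("measurements", rep("history", length(history))),
    clinical_cat = c("weight and BMI", rep(NA_character_, length(history))),
    day_offset = days[1], event_time = "09:05:00", flagged_unit = FALSE
  )
  structure(
    list(
      Person = tibble::tibble(person_id = pid, visit_id = vid[1],
                              age_at_index = age, urbanicity = "urban"),
      Visit = tibble::tibble(visit_id = vid, person_id = pid,
                             day_offset = days,
                             registration_time = "08:00:00",
                             visit_type = "clinic appointment"),
      Event = dplyr::bind_rows(events, extra),
      Diagnosis = tibble::tibble(
        person_id = character(), visit_id = character(), code = character(),
        code_system = character(), category = character(),
        sub_category = character(), day_offset = integer(),
        diagnosis_time = character()),
      FamilyHX = tibble::tibble(person_id = character(), item = character()),
      Race = tibble::tibble(person_id = pid, race = race)
    ),
    class = "harmonized_record_set"
  )
}
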