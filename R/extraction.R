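#' Cohort selection and encounter inclusion criteria
#'
#' Bundles every criterion applied when building the study cohort: the
#' delivery window, the prenatal diagnosis-code prefixes used to identify
#' prenatal encounters, the delivery procedure-code prefixes, the inclusive
#' age range at the time of the encounter, the visit types removed when
#' they carry no clinical data (staff-patient communications), and the
#' registration years treated as historical-upload artifacts.
#'
#' The shipped prenatal and delivery code lists are editable placeholders:
#' the source study defers to an external (CDC) delivery definition and
#' does not print its ICD-10 lists, so sites must substitute their own.
#'
#' @param delivery_window Two dates; deliveries on the endpoints count.
#' @param prenatal_codes Character vector of diagnosis-code prefixes
#'   identifying prenatal encounters.
#' @param delivery_codes Character vector of procedure-code prefixes
#'   identifying a documented delivery.
#' @param age_min,age_max Inclusive age bounds in completed years at the
#'   encounter registration date.
#' @param excluded_visit_types Visit types removed when the visit carries
#'   no clinical events.
#' @param excluded_registration_years Registration years marking
#'   historical-upload artifacts.
#' @return A `cohort_criteria` object.
#' @export
cohort_criteria <- function(delivery_window = c("2017-01-01", "2020-12-31"),
                            prenatal_codes = c("Z34", "O09"),
                            delivery_codes = c("10D0", "10E0"),
                            age_min = 18L,
                            age_max = 35L,
                            excluded_visit_types = c("portal message",
                                                     "phone call"),
                            excluded_registration_years = 1900L) {
  if (age_min > age_max) {
    abort("`age_min` must be <= `age_max`.", class = "matcvrisk_config_error")
  }
  structure(
    list(
      delivery_window = as_date_window(delivery_window, "delivery_window"),
      prenatal_codes = as.character(prenatal_codes),
      delivery_codes = as.character(delivery_codes),
      age_min = as.integer(age_min), age_max = as.integer(age_max),
      excluded_visit_types = as.character(excluded_visit_types),
      excluded_registration_years = as.integer(excluded_registration_years)
    ),
    class = "cohort_criteria"
  )
}

#' Read or write cohort criteria as YAML
#' @param path YAML file path.
#' @param criteria A [cohort_criteria()] object.
#' @return `read_cohort_criteria()` returns a `cohort_criteria`;
#'   `write_cohort_criteria()` returns `path` invisibly.
#' @export
read_cohort_criteria <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_criteria(
    delivery_window = unlist(y$delivery_window),
    prenatal_codes = unlist(y$prenatal_codes),
    delivery_codes = unlist(y$delivery_codes),
    age_min = y$age_min %||% 18L, age_max = y$age_max %||% 35L,
    excluded_visit_types = unlist(y$excluded_visit_types),
    excluded_registration_years = unlist(y$excluded_registration_years)
  )
}

#' @rdname read_cohort_criteria
#' @export
write_cohort_criteria <- function(criteria, path) {
  y <- unclass(criteria)
  y$delivery_window <- format(y$delivery_window)
  yaml::write_yaml(y, path)
  invisible(path)
}

matches_prefix <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

#' Select the delivery cohort
#'
#' Returns the ids of persons with at least one documented delivery
#' procedure dated inside the delivery window (endpoints inclusive).
#'
#' @param records A `raw_record_set`.
#' @param criteria A [cohort_criteria()].
#' @return A character vector of person ids.
#' @export
select_delivery_cohort <- function(records, criteria) {
  dx <- records$diagnoses
  if (any(is.na(dx$diagnosis_datetime))) {
    bad <- dx$diagnosis_id[is.na(dx$diagnosis_datetime)]
    abort(paste0("Malformed diagnosis dates for rows: ",
                 paste(head(bad, 10L), collapse = ", ")),
          class = "matcvrisk_validation_error")
  }
  ddate <- as.Date(dx$diagnosis_datetime)
  dx |>
    filter(.data$diagnosis_type == "procedure",
           matches_prefix(.data$code, criteria$delivery_codes),
           ddate >= criteria$delivery_window[1],
           ddate <= criteria$delivery_window[2]) |>
    pull("person_id") |>
    unique() |>
    sort()
}

# earliest in-window delivery date per cohort person
delivery_dates <- function(records, cohort, criteria) {
  records$diagnoses |>
    filter(.data$person_id %in% cohort,
           .data$diagnosis_type == "procedure",
           matches_prefix(.data$code, criteria$delivery_codes)) |>
    mutate(delivery_date = as.Date(.data$diagnosis_datetime)) |>
    filter(.data$delivery_date >= criteria$delivery_window[1],
           .data$delivery_date <= criteria$delivery_window[2]) |>
    group_by(.data$person_id) |>
    summarise(delivery_date = min(.data$delivery_date), .groups = "drop")
}

#' Collect prenatal encounters for the cohort
#'
#' Returns the visits of cohort members that carry at least one prenatal
#' diagnosis code and are dated on or before the patient's delivery
#' (visits on the delivery date itself are retained so delivered-on-first-
#' visit patients remain detectable downstream).
#'
#' @inheritParams select_delivery_cohort
#' @param cohort Person ids from [select_delivery_cohort()].
#' @return A character vector of visit ids.
#' @export
collect_prenatal_visits <- function(records, cohort, criteria) {
  if (length(criteria$prenatal_codes) == 0L) {
    abort("Prenatal code list is empty.", class = "matcvrisk_config_error")
  }
  deliv <- delivery_dates(records, cohort, criteria)
  prenatal_visits <- records$diagnoses |>
    filter(.data$person_id %in% cohort,
           matches_prefix(.data$code, criteria$prenatal_codes)) |>
    distinct(.data$visit_id, .data$person_id)
  records$visits |>
    semi_join(prenatal_visits, by = "visit_id") |>
    inner_join(deliv, by = "person_id") |>
    filter(as.Date(.data$registration_datetime) <= .data$delivery_date) |>
    pull("visit_id") |>
    unique() |>
    sort()
}

#' Apply the study exclusions to a set of visits
#'
#' Removes (a) visits registered in an excluded year (historical uploads),
#' (b) communication-type visits carrying no clinical events, and (c)
#' visits where the patient's age in completed years at registration falls
#' outside the inclusive age range. Visits of patients with a missing date
#' of birth are never silently dropped: they are routed to a review list
#' attached to the result.
#'
#' @inheritParams select_delivery_cohort
#' @param visits Visit ids, e.g. from [collect_prenatal_visits()].
#' @return A character vector of retained visit ids, with attributes
#'   `review` (visit ids needing manual review) and `tally` (named counts
#'   of removals per criterion).
#' @export
apply_exclusions <- function(records, visits, criteria) {
  v <- records$visits |>
    filter(.data$visit_id %in% visits) |>
    left_join(select(records$persons, "person_id", "date_of_birth"),
              by = "person_id") |>
    mutate(
      reg_date = as.Date(.data$registration_datetime),
      reg_year = as.integer(format(.data$reg_date, "%Y")),
      has_events = .data$visit_id %in% records$events$visit_id,
      excl_year = .data$reg_year %in% criteria$excluded_registration_years,
      excl_comm = .data$visit_type %in% criteria$excluded_visit_types &
        !.data$has_events,
      age = age_in_completed_years(.data$date_of_birth, .data$reg_date),
      excl_age = !is.na(.data$age) &
        (.data$age < criteria$age_min | .data$age > criteria$age_max),
      review = is.na(.data$date_of_birth)
    )
  kept <- v |>
    filter(!.data$excl_year, !.data$excl_comm, !.data$excl_age, !.data$review) |>
    pull("visit_id") |>
    sort()
  structure(
    kept,
    review = sort(v$visit_id[v$review]),
    tally = c(
      registration_year = sum(v$excl_year),
      communication = sum(v$excl_comm & !v$excl_year),
      age = sum(v$excl_age & !v$excl_year & !v$excl_comm),
      review = sum(v$review)
    )
  )
}

#' Run the full extraction stage
#'
#' Convenience wrapper: delivery cohort, prenatal-visit collection, and
#' exclusions in one call.
#'
#' @inheritParams select_delivery_cohort
#' @return A `cohort_extraction` list: `cohort` (person ids),
#'   `included_visits` (visit ids), `review` (visit ids), `tally`
#'   (exclusion counts).
#' @export
extract_cohort <- function(records, criteria = cohort_criteria()) {
  cohort <- select_delivery_cohort(records, criteria)
  prenatal <- collect_prenatal_visits(records, cohort, criteria)
  kept <- apply_exclusions(records, prenatal, criteria)
  structure(
    list(cohort = cohort,
         included_visits = as.character(kept),
         review = attr(kept, "review"),
         tally = attr(kept, "tally")),
    class = "cohort_extraction"
  )
}

#' @export
print.cohort_extraction <- function(x, ...) {
  cat(sprintf("<cohort_extraction> %d persons, %d included visits\n",
              length(x$cohort), length(x$included_visits)))
  cat("  exclusions:", paste(sprintf("%s=%d", names(x$tally), x$tally),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Validate extraction coverage against a risk catalog
#'
#' Mirrors the manual events-list comb-through: reports catalog variables
#' with no matching event in the extract, event labels matching no catalog
#' entry, and a seeded random sample of visits for manual review listing
#' their uncategorized events.
#'
#' @inheritParams select_delivery_cohort
#' @param visits Included visit ids.
#' @param catalog A [risk_catalog()].
#' @param sample_size Number of visits to sample for manual review.
#' @param seed Seed for the review sample (deterministic re-runs).
#' @return A `validation_report` list: `missing_variables`,
#'   `uncategorized_labels`, `review_sample` (tibble of sampled visit ids
#'   and their uncategorized labels).
#' @export
validate_extraction <- function(records, visits, catalog = risk_catalog(),
                                sample_size = 5L, seed = 1L) {
  ev <- records$events |>
    filter(.data$visit_id %in% visits) |>
    mutate(label = tolower(.data$event_label))
  lmap <- catalog_label_map(catalog)
  known_aux <- c("weight", "hemoglobin", "glucose", "age")
  missing_vars <- catalog |>
    filter(!purrr::map_lgl(.data$labels,
                           ~ any(tolower(.x) %in% ev$label))) |>
    pull("factor_id")
  uncat <- sort(setdiff(unique(ev$label), c(lmap$label, known_aux)))
  sampled <- withr::with_seed(seed, {
    pool <- sort(unique(ev$visit_id))
    sample(pool, min(sample_size, length(pool)))
  })
  review_sample <- ev |>
    filter(.data$visit_id %in% sampled, .data$label %in% uncat) |>
    distinct(.data$visit_id, .data$label) |>
    arrange(.data$visit_id, .data$label)
  structure(
    list(missing_variables = missing_vars,
         uncategorized_labels = uncat,
         sampled_visits = sampled,
         review_sample = review_sample),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  cat("  catalog variables with no events:",
      if (length(x$missing_variables)) paste(x$missing_variables, collapse = ", ")
      else "none", "\n")
  cat("  uncategorized event labels:",
      if (length(x$uncategorized_labels))
        paste(x$uncategorized_labels, collapse = ", ") else "none", "\n")
  cat(sprintf("  sampled visits for review: %d\n", length(x$sampled_visits)))
  invisible(x)
}
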