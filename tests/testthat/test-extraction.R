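test_that("delivery-window selection is inclusive and requires a delivery", {
  records <- boundary_record_set()
  crit <- cohort_criteria()
  expect_setequal(select_delivery_cohort(records, crit),
                  records$persons$person_id)   # all deliver 2018-07-15

  # move one delivery outside the window; drop another patient's entirely
  records2 <- records
  records2$diagnoses$diagnosis_datetime[
    records2$diagnoses$code == "10D00Z0" &
      records2$diagnoses$person_id == "P00001"] <-
    as.POSIXct("2021-01-01 10:00:00", tz = "UTC")
  records2$diagnoses <- records2$diagnoses |>
    dplyr::filter(!(code == "10D00Z0" & person_id == "P00002"))
  got <- select_delivery_cohort(records2, crit)
  expect_false("P00001" %in% got)   # dated 2021-01-01
  expect_false("P00002" %in% got)   # no delivery record
  # window endpoints are inclusive
  records3 <- records
  records3$diagnoses$diagnosis_datetime[
    records3$diagnoses$code == "10D00Z0" &
      records3$diagnoses$person_id == "P00001"] <-
    as.POSIXct("2020-12-31 23:00:00", tz = "UTC")
  expect_true("P00001" %in% select_delivery_cohort(records3, crit))
})

test_that("prenatal-visit collection needs cohort membership and a listed code", {
  records <- boundary_record_set()
  crit <- cohort_criteria()
  cohort <- select_delivery_cohort(records, crit)
  visits <- collect_prenatal_visits(records, cohort, crit)
  expect_true("V000001" %in% visits)

  # visit of a non-cohort person excluded
  visits2 <- collect_prenatal_visits(records, setdiff(cohort, "P00001"), crit)
  expect_false("V000001" %in% visits2)

  # a visit with no listed code excluded
  records3 <- records
  records3$diagnoses <- records3$diagnoses |>
    dplyr::filter(!(visit_id == "V000001" & code == "Z34.90"))
  expect_false("V000001" %in%
                 collect_prenatal_visits(records3, cohort, crit))

  expect_error(
    collect_prenatal_visits(records, cohort,
                            cohort_criteria(prenatal_codes = character(0))),
    class = "matcvrisk_config_error"
  )
})

test_that("exclusions: 1900 registrations, eventless communications, age 18-35 inclusive", {
  records <- boundary_record_set()
  crit <- cohort_criteria()
  cohort <- select_delivery_cohort(records, crit)
  visits <- collect_prenatal_visits(records, cohort, crit)
  kept <- apply_exclusions(records, visits, crit)

  expect_false("V000001" %in% kept)   # age 17 at encounter
  expect_true("V000002" %in% kept)    # exactly 18: inclusive
  expect_true("V000003" %in% kept)    # exactly 35: inclusive
  expect_false("V000004" %in% kept)   # age 36
  expect_false("V000007" %in% kept)   # registered 1900
  expect_false("V000008" %in% kept)   # portal message, no events
  expect_true("V000009" %in% kept)    # portal message WITH a clinical event
  # missing date of birth: routed to review, not silently dropped
  expect_false("V000006" %in% kept)
  expect_equal(attr(kept, "review"), "V000006")
})

test_that("the three exclusion criteria commute", {
  records <- boundary_record_set()
  cohort <- select_delivery_cohort(records, cohort_criteria())
  visits <- collect_prenatal_visits(records, cohort, cohort_criteria())

  # single-criterion variants (others disabled)
  crits <- list(
    year = cohort_criteria(age_min = 0, age_max = 200,
                           excluded_visit_types = character(0)),
    comm = cohort_criteria(age_min = 0, age_max = 200,
                           excluded_registration_years = integer(0)),
    age = cohort_criteria(excluded_visit_types = character(0),
                          excluded_registration_years = integer(0))
  )
  apply_seq <- function(order) {
    v <- visits
    for (nm in order) {
      v <- as.character(apply_exclusions(records, v, crits[[nm]]))
    }
    sort(v)
  }
  perms <- list(c("year", "comm", "age"), c("year", "age", "comm"),
                c("comm", "year", "age"), c("comm", "age", "year"),
                c("age", "year", "comm"), c("age", "comm", "year"))
  results <- lapply(perms, apply_seq)
  for (r in results[-1]) expect_identical(r, results[[1]])
  # and together they equal the one-shot application (minus the review row)
  combined <- apply_exclusions(records, visits, cohort_criteria())
  expect_identical(setdiff(results[[1]], attr(combined, "review")),
                   sort(as.character(combined)))
})

test_that("on synthetic data the filters remove exactly the injected artifacts", {
  run <- noise_free_run()
  tally <- run$extraction$tally
  artifacts <- run$cohort$truth$artifacts
  expect_equal(unname(tally[["registration_year"]] + tally[["communication"]]),
               nrow(artifacts))
  expect_equal(unname(tally[["age"]]), 0L)   # generator keeps ages in range
  # injected visit ids are exactly the ones missing from the included set
  expect_length(intersect(run$extraction$included_visits,
                          artifacts$visit_id), 0L)
})

test_that("extraction is idempotent", {
  records <- boundary_record_set()
  crit <- cohort_criteria()
  ex1 <- extract_cohort(records, crit)
  # re-applying the exclusion stage to the surviving set removes nothing
  again <- apply_exclusions(records, ex1$included_visits, crit)
  expect_setequal(as.character(again), ex1$included_visits)
  # and the whole stage is deterministic
  ex2 <- extract_cohort(records, crit)
  expect_identical(ex1$included_visits, ex2$included_visits)
})

test_that("extraction validation reports gaps both ways and samples reproducibly", {
  records <- boundary_record_set()
  visits <- c("V000009")
  rep1 <- validate_extraction(records, visits, risk_catalog(),
                              sample_size = 5, seed = 3)
  # catalog variable with no events anywhere in the subset
  expect_true("heart_rate_high" %in% rep1$missing_variables)
  expect_false("sbp_high" %in% rep1$missing_variables)

  records2 <- records
  records2$events <- dplyr::bind_rows(
    records2$events,
    tibble::tibble(event_id = "E0000002", visit_id = "V000009",
                   person_id = "P00005", event_label = "serum rhubarb",
                   result_value = "12", result_unit = "mg/dL",
                   event_datetime = records$events$event_datetime[1])
  )
  rep2 <- validate_extraction(records2, visits, risk_catalog(), seed = 3)
  expect_true("serum rhubarb" %in% rep2$uncategorized_labels)

  rep3 <- validate_extraction(records2, visits, risk_catalog(), seed = 3)
  expect_identical(rep2$sampled_visits, rep3$sampled_visits)
})
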