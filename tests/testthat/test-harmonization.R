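test_that("categorization assigns the documented triples, first match wins", {
  ev <- tibble::tibble(event_label = c("hemoglobin", "systolic blood pressure",
                                       "weight", "serum rhubarb"))
  out <- categorize_records(ev, target = "event")
  expect_equal(out$category[1], "event")
  expect_equal(out$sub_category[1], "labs")
  expect_equal(out$clinical_cat[1], "hematology")
  expect_equal(out$clinical_cat[2], "vitals")
  expect_equal(out$clinical_cat[3], "weight and BMI")
  expect_false(out$matched[4])   # review queue, not dropped

  dx <- tibble::tibble(diagnosis_type = c("admitting diagnosis", "procedure"))
  outd <- categorize_records(dx, target = "diagnosis")
  expect_equal(outd$sub_category, c("admitting diagnosis", "procedure"))
  expect_true(is.na(outd$clinical_cat[1]))
})

test_that("categorization is total over a full cohort", {
  run <- noise_free_run()
  h <- run$harmonized
  n_events_in <- run$deid$events |>
    dplyr::distinct(person_id, visit_id, event_label, result_value,
                    result_unit, day_offset, event_time) |>
    nrow()
  n_event_reviews <- sum(h$review_queue$kind == "event")
  categorized <- sum(!is.na(h$Event$category))
  expect_equal(categorized + n_event_reviews, n_events_in)
  expect_gt(n_event_reviews, 0L)   # the out-of-rules lab lands here
})

test_that("unit normalization converts pounds, passes canonical units, flags unknowns", {
  got <- normalize_value(154.324, "lb")
  expect_equal(got$value, 70.00)
  expect_equal(got$unit, "kg")
  expect_identical(normalize_value(70, "kg")$value, 70)
  expect_false(normalize_value(120, "mm Hg")$flagged)
  expect_true(normalize_value(120, "furlongs")$flagged)

  # idempotence
  once <- normalize_value(c(154.324, 70, 98), c("lb", "kg", "%"))
  twice <- normalize_value(once$value, once$unit)
  expect_equal(twice$value, once$value)
  expect_equal(twice$unit, once$unit)

  # lb -> kg -> lb round trip within 0.02 lb
  lb <- runif(50, 90, 260)
  kg <- normalize_value(lb, rep("lb", 50))$value
  expect_true(all(abs(kg / 0.45359237 - lb) < 0.02))
})

test_that("the final schema keeps ids as documented and catalogs every field", {
  h <- noise_free_run()$harmonized
  for (nm in c("Person", "Visit", "Event", "Diagnosis")) {
    expect_true(all(c("person_id", "visit_id") %in% names(h[[nm]])),
                label = nm)
  }
  expect_false("visit_id" %in% names(h$FamilyHX))
  expect_false("visit_id" %in% names(h$Race))

  n_fields <- sum(vapply(h[c("Person", "Visit", "Event", "Diagnosis",
                             "FamilyHX", "Race")], ncol, integer(1)))
  expect_equal(nrow(h$catalog), n_fields)
  expect_equal(anyDuplicated(h$catalog[c("table", "field")]), 0L)
  expect_true(all(!is.na(h$catalog$description)))
})

test_that("exact duplicate observations collapse to one row", {
  run <- noise_free_run()
  deid <- run$deid
  dup <- deid
  dup$events <- dplyr::bind_rows(deid$events, deid$events[1, ])
  h1 <- harmonize_records(deid)
  h2 <- harmonize_records(dup)
  expect_equal(nrow(h2$Event), nrow(h1$Event))
})

test_that("orphan events break assembly with an integrity error", {
  run <- noise_free_run()
  broken <- run$deid
  broken$events$visit_id[1] <- "deadbeefdeadbeef"
  expect_error(harmonize_records(broken),
               class = "matcvrisk_integrity_error")
})

test_that("harmonized CSV round trip preserves the six tables", {
  run <- noise_free_run()
  dir <- withr::local_tempdir()
  write_harmonized_records(run$harmonized, dir)
  back <- read_harmonized_records(dir)
  for (nm in c("Person", "Visit", "Event", "Diagnosis", "FamilyHX", "Race")) {
    expect_equal(as.data.frame(back[[nm]]),
                 as.data.frame(run$harmonized[[nm]]), label = nm)
  }
})
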