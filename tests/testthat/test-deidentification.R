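test_that("zip classification generalizes and survives lookup misses", {
  table <- synthetic_urbanicity_table()
  expect_equal(classify_zip("30001", table), "urban")
  expect_equal(classify_zip("30031", table), "suburban")
  expect_warning(cls <- classify_zip("99999", table), "unknown")
  expect_equal(cls, "unknown")
  expect_error(classify_zip("30001", tibble::tibble(zip = "30001",
                                                    class = "metropolis")),
               class = "matcvrisk_config_error")
})

test_that("day offsets anchor at the index visit and preserve gaps", {
  mk <- function(person, dates) {
    tibble::tibble(
      visit_id = sprintf("%s-v%d", person, seq_along(dates)),
      person_id = person,
      registration_datetime = as.POSIXct(paste(dates, "08:30:00"), tz = "UTC")
    )
  }
  off <- compute_day_offsets(mk("a", c("2019-03-01", "2019-03-22")))
  expect_equal(off$day_offset, c(0L, 21L))
  expect_equal(compute_day_offsets(mk("b", "2019-05-05"))$day_offset, 0L)

  # property: pairwise offset differences equal true calendar-day gaps
  run <- noise_free_run()
  raw_visits <- run$cohort$records$visits |>
    dplyr::filter(visit_id %in% run$extraction$included_visits)
  off2 <- compute_day_offsets(raw_visits) |>
    dplyr::left_join(raw_visits, by = c("visit_id", "person_id"))
  per <- split(off2, off2$person_id)
  for (p in per[1:40]) {
    d <- as.Date(p$registration_datetime)
    expect_equal(outer(p$day_offset, p$day_offset, "-"),
                 unname(outer(as.integer(d), as.integer(d), "-")))
  }
})

test_that("pseudonymization is keyed, deterministic, and exactly invertible", {
  m1 <- pseudonymize_ids(c("P00001", "P00002"), salt = "salt-a")
  m2 <- pseudonymize_ids(c("P00001", "P00002"), salt = "salt-a")
  m3 <- pseudonymize_ids(c("P00001", "P00002"), salt = "salt-b")
  expect_identical(m1, m2)
  expect_false(any(m1$pseudonym == m3$pseudonym))
  expect_false(any(m1$pseudonym %in% m1$original))

  # exhaustive round trip over a full cohort's master key
  run <- noise_free_run()
  key <- run$key
  back_p <- lookup_original_id(key, key$persons$pseudonym, "person")
  expect_identical(back_p, key$persons$original)
  back_v <- lookup_original_id(key, key$visits$pseudonym, "visit")
  expect_identical(back_v, key$visits$original)
  # bijection on the dataset's id universe
  expect_equal(anyDuplicated(key$persons$pseudonym), 0L)
  expect_equal(anyDuplicated(key$visits$pseudonym), 0L)
})

test_that("free-text event types are stripped and counted, others untouched", {
  ev <- tibble::tibble(
    event_label = c("comment", "systolic blood pressure", "registration note"),
    result_value = c("Patient Jane Doe", "120", "DOB 1990-01-01")
  )
  out <- strip_free_text(ev)
  expect_equal(out$event_label, "systolic blood pressure")
  expect_equal(sum(attr(out, "removed")), 2L)
  empty <- strip_free_text(ev[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("the serialized de-identified export contains no raw identifiers", {
  run <- noise_free_run()
  dir <- withr::local_tempdir()
  write_deid_records(run$deid, dir)
  text <- unlist(lapply(list.files(dir, full.names = TRUE), readLines))

  raw <- run$cohort$records
  # original person / visit ids (P\d{5}, V\d{6}, VA\d{5})
  expect_false(any(grepl("\\bP\\d{5}\\b", text)))
  expect_false(any(grepl("\\bVA?\\d{5,6}\\b", text)))
  # calendar dates in any ISO form
  expect_false(any(grepl("\\d{4}-\\d{2}-\\d{2}", text)))
  # names (given or family) as standalone words
  name_pat <- paste0("\\b(", paste(unique(c(raw$persons$given_name,
                                            raw$persons$family_name)),
                                   collapse = "|"), ")\\b")
  expect_false(any(grepl(name_pat, text)))
  # zips as complete CSV fields
  zips <- unique(raw$persons$zip)
  zip_pat <- paste0("(^|,)(", paste(zips, collapse = "|"), ")(,|$)")
  expect_false(any(grepl(zip_pat, text)))
})

test_that("the master key cannot be co-located with the analysis export", {
  run <- noise_free_run()
  dir <- withr::local_tempdir()
  expect_error(
    write_deid_records(run$deid, dir, master_key = run$key, key_dir = dir),
    class = "matcvrisk_config_error"
  )
  key_dir <- withr::local_tempdir()
  write_deid_records(run$deid, dir, master_key = run$key, key_dir = key_dir)
  expect_true(file.exists(file.path(key_dir, "key_persons.csv")))
  expect_false(file.exists(file.path(dir, "key_persons.csv")))
})

test_that("de-identified tables keep referential integrity under pseudonyms", {
  run <- noise_free_run()
  deid <- run$deid
  expect_true(all(deid$visits$person_id %in% deid$persons$person_id))
  expect_true(all(deid$events$visit_id %in% deid$visits$visit_id))
  expect_true(all(deid$events$person_id %in% deid$persons$person_id))
  expect_true(all(deid$family_history$person_id %in% deid$persons$person_id))
  # index visit day offset is 0 for every patient
  idx <- deid$visits |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(m = min(day_offset))
  expect_true(all(idx$m == 0L))
})
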