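test_that("generated cohorts honour the configured size and delivery window", {
  cfg <- generator_config(n_patients = 100, seed = 7)
  cohort <- generate_cohort(cfg)
  expect_equal(nrow(cohort$records$persons), 100L)

  deliveries <- cohort$records$diagnoses |>
    dplyr::filter(diagnosis_type == "procedure")
  # every patient has >= 1 documented delivery procedure inside the window
  expect_setequal(unique(deliveries$person_id), cohort$records$persons$person_id)
  ddate <- as.Date(deliveries$diagnosis_datetime)
  expect_true(all(ddate >= cfg$date_window[1] & ddate <= cfg$date_window[2]))

  # shared value field is character; units populated for vitals
  expect_type(cohort$records$events$result_value, "character")
  expect_true(any(cohort$records$events$result_unit == "mm Hg"))
  expect_true(all(c("lb", "kg") %in%
                    cohort$records$events$result_unit))
})

test_that("identical config and seed give byte-identical cohorts", {
  cfg <- generator_config(n_patients = 40, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  # and artifact injection is equally deterministic
  expect_identical(serialize(inject_artifacts(a), NULL),
                   serialize(inject_artifacts(b), NULL))
})

test_that("planted proportions are recovered within 3-SD binomial bounds", {
  run <- noise_free_run()
  gt <- run$cohort$truth$patients
  cfg <- run$config
  n <- nrow(gt)
  check_prop <- function(observed, p) {
    bound <- 3 * sqrt(p * (1 - p) / n)
    expect_lt(abs(observed / n - p), bound)
  }
  check_prop(sum(!is.na(gt$sbp_red_flag_day)), cfg$frac_red_flag)
  check_prop(sum(gt$category == "delivery_first"),
             cfg$frac_delivery_first_visit)
  check_prop(sum(gt$category == "single_visit"), cfg$frac_single_visit)
  check_prop(sum(!is.na(gt$sbp_standard_day)), cfg$frac_with_risk)
})

test_that("ground-truth crossing days replay exactly from the raw values", {
  run <- noise_free_run()
  records <- run$cohort$records
  truth <- run$cohort$truth
  catalog <- risk_catalog()
  def <- catalog[catalog$factor_id == "sbp_high", ]

  sbp <- records$events |>
    dplyr::filter(event_label == "systolic blood pressure",
                  !visit_id %in% truth$artifacts$visit_id) |>
    dplyr::mutate(value = as.numeric(result_value),
                  date = as.Date(event_datetime))
  idx <- truth$patients |> dplyr::select(person_id, index_date)
  crossings <- sbp |>
    dplyr::inner_join(idx, by = "person_id") |>
    dplyr::mutate(day = as.integer(date - index_date)) |>
    dplyr::arrange(person_id, day) |>
    dplyr::group_by(person_id) |>
    dplyr::summarise(
      std = day[value >= def$threshold_standard][1],
      red = day[value >= def$threshold_red][1],
      .groups = "drop"
    )
  replay <- truth$trajectories |>
    dplyr::left_join(crossings, by = "person_id")
  expect_true(all(eq_na(replay$standard_crossing_day, replay$std)))
  expect_true(all(eq_na(replay$red_flag_crossing_day, replay$red)))
})

test_that("ground-truth internal invariants hold", {
  gt <- noise_free_run()$cohort$truth$patients
  both <- !is.na(gt$sbp_red_flag_day) & !is.na(gt$sbp_standard_day)
  expect_true(all(gt$sbp_red_flag_day[both] >= gt$sbp_standard_day[both]))
  dx <- !is.na(gt$diagnosis_day)
  expect_true(all(gt$diagnosis_day[dx] >= gt$sbp_standard_day[dx]))
})

test_that("artifact injection marks exactly what it adds, and 0 is a no-op", {
  cfg <- generator_config(n_patients = 30, frac_artifact_visits = 0, seed = 3)
  cohort <- generate_cohort(cfg)
  expect_identical(serialize(inject_artifacts(cohort), NULL),
                   serialize(cohort, NULL))

  cfg2 <- generator_config(n_patients = 30, frac_artifact_visits = 0.1,
                           seed = 3)
  with_art <- inject_artifacts(generate_cohort(cfg2))
  art <- with_art$truth$artifacts
  expect_equal(nrow(art),
               round(0.1 * (nrow(with_art$records$visits) - nrow(art))))
  comm <- art$visit_id[art$kind == "communication"]
  comm_visits <- with_art$records$visits |>
    dplyr::filter(visit_id %in% comm)
  expect_true(all(comm_visits$visit_type %in% c("portal message",
                                                "phone call")))
  expect_equal(sum(with_art$records$events$visit_id %in% comm), 0L)
  y1900 <- with_art$records$visits |>
    dplyr::filter(visit_id %in% art$visit_id[art$kind == "registration_1900"])
  expect_true(all(format(y1900$registration_datetime, "%Y") == "1900"))
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(frac_with_risk = 1.2),
               class = "matcvrisk_config_error")
  expect_error(generator_config(n_patients = 0),
               class = "matcvrisk_config_error")
  expect_error(generator_config(date_window = c("2020-01-01", "2019-01-01")),
               class = "matcvrisk_config_error")
  expect_error(generator_config(frac_red_flag = 0.5, frac_with_risk = 0.2),
               class = "matcvrisk_config_error")
  expect_error(generator_config(frac_single_visit = 0.7,
                                frac_delivery_first_visit = 0.7),
               class = "matcvrisk_config_error")
})

test_that("raw CSV round trip preserves the record set", {
  cohort <- generate_cohort(generator_config(n_patients = 15, seed = 5))
  dir <- withr::local_tempdir()
  write_raw_records(cohort$records, dir)
  back <- read_raw_records(dir)
  for (nm in names(cohort$records)) {
    expect_equal(as.data.frame(back[[nm]]),
                 as.data.frame(cohort$records[[nm]]))
  }
})
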