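catalog <- risk_catalog()
def_of <- function(id) catalog[catalog$factor_id == id, ]

test_that("numeric thresholds are inclusive at every catalog boundary", {
  cases <- list(
    # factor, values, expected levels at value-1, value, value+1
    list("heart_rate_high", 110, c("none", "standard", "standard")),
    list("heart_rate_high", 120, c("standard", "red_flag", "red_flag")),
    list("sbp_high", 140, c("none", "standard", "standard")),
    list("sbp_high", 160, c("standard", "red_flag", "red_flag")),
    list("resp_rate_high", 24, c("none", "standard", "standard")),
    list("resp_rate_high", 30, c("standard", "red_flag", "red_flag")),
    # spo2 triggers downward: level rises as the value falls
    list("spo2_low", 96, c("standard", "standard", "none")),
    list("spo2_low", 94, c("red_flag", "red_flag", "standard"))
  )
  for (cs in cases) {
    def <- def_of(cs[[1]])
    for (k in 1:3) {
      value <- cs[[2]] + (k - 2L)
      finding <- evaluate_numeric(def$quantity, value, def)
      got <- if (is.null(finding)) "none" else finding$level
      expect_equal(got, cs[[3]][k],
                   label = sprintf("%s at %s", cs[[1]], value))
    }
  }
})

test_that("static numeric boundaries (BMI 35, age 40) are inclusive", {
  for (bmi in c(34, 34.9, 35, 36)) {
    f <- evaluate_static(list(age = 28, race = "Other", bmi = bmi,
                              history = character(0)), catalog)
    expect_equal("prepregnancy_obesity" %in% f$factor_id, bmi >= 35,
                 label = sprintf("BMI %s", bmi))
  }
  for (age in c(39, 40, 41)) {
    f <- evaluate_static(list(age = age, race = "Other", bmi = 22,
                              history = character(0)), catalog)
    expect_equal("age_40" %in% f$factor_id, age >= 40,
                 label = sprintf("age %s", age))
  }
})

test_that("presence factors map to their configured levels", {
  expect_equal(evaluate_presence("dyspnea", catalog)$level, "red_flag")
  expect_equal(evaluate_presence("orthopnea", catalog)$level, "red_flag")
  expect_equal(evaluate_presence("chest pain", catalog)$level, "standard")
  expect_null(evaluate_presence("common cold", catalog))
  # quantity/definition mismatch is a contract error
  expect_error(evaluate_numeric("heart_rate", 100, def_of("sbp_high")),
               class = "matcvrisk_contract_error")
})

test_that("static evaluation covers history items and demographics", {
  f <- evaluate_static(list(age = 29, race = "African American", bmi = 36,
                            history = c("prepregnancy diabetes",
                                        "prepregnancy hypertension")),
                       catalog)
  expect_setequal(f$factor_id,
                  c("race_african_american", "prepregnancy_obesity",
                    "prepregnancy_diabetes", "prepregnancy_hypertension"))
  none <- evaluate_static(list(age = 29, race = "Other", bmi = 24,
                               history = character(0)), catalog)
  expect_equal(nrow(none), 0L)
})

test_that("encounter assessment matches brute force over all 256 combinations", {
  # reduced 8-factor catalog: 2 red-flag presence + 6 standard factors
  ids <- c("dyspnea", "orthopnea", "chest_pain", "palpitations",
           "tachypnea_symptom", "dizziness_syncope", "swelling_face_hands",
           "basilar_crackles")
  red <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE)
  for (mask in 0:255) {
    present <- as.logical(bitwAnd(mask, 2^(0:7)))
    findings <- tibble::tibble(
      factor_id = ids[present],
      level = ifelse(red[present], "red_flag", "standard")
    )
    got <- assess_encounter(findings)$level
    # independent brute-force statement of the rule
    expected <- if (any(red & present) || sum(present) >= 4L) {
      "red_flag"
    } else if (any(present)) "standard" else "none"
    expect_equal(got, expected, label = sprintf("mask %d", mask))
  }
})

test_that("encounter assessment deduplicates by factor id", {
  dup <- tibble::tibble(
    factor_id = c("sbp_high", "sbp_high", "chest_pain"),
    level = c("standard", "standard", "standard")
  )
  expect_equal(assess_encounter(dup)$n_findings, 2L)
  # duplicate at two levels keeps the highest
  two <- tibble::tibble(factor_id = c("sbp_high", "sbp_high"),
                        level = c("standard", "red_flag"))
  a <- assess_encounter(two)
  expect_equal(a$level, "red_flag")
  expect_equal(a$n_findings, 1L)
})

test_that("profile level is monotone in findings and in numeric severity", {
  lvl <- function(f) {
    factor(assess_encounter(f)$level, levels = c("none", "standard",
                                                 "red_flag"), ordered = TRUE)
  }
  base <- tibble::tibble(factor_id = c("chest_pain", "palpitations"),
                         level = "standard")
  for (extra in list(
    tibble::tibble(factor_id = "tachypnea_symptom", level = "standard"),
    tibble::tibble(factor_id = "dyspnea", level = "red_flag")
  )) {
    expect_gte(as.integer(lvl(dplyr::bind_rows(base, extra))),
               as.integer(lvl(base)))
  }
  # numeric monotonicity along the trigger direction
  def <- def_of("sbp_high")
  levels_along <- vapply(c(100, 139, 140, 159, 160, 200), function(v) {
    f <- evaluate_numeric("systolic_bp", v, def)
    if (is.null(f)) "none" else f$level
  }, character(1))
  ranks <- match(levels_along, c("none", "standard", "red_flag"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("red-flag findings and profiles are subsets of at-risk ones", {
  run <- noise_free_run()
  prof <- run$assessment$profiles
  expect_true(all(prof$level[prof$any_red_finding] == "red_flag"))
  expect_true(all(prof$n_findings[prof$level != "none"] >= 1L))
  on <- run$assessment$onsets
  has_red <- !is.na(on$onset_red_flag)
  expect_true(all(!is.na(on$onset_standard[has_red])))
  expect_true(all(on$onset_red_flag[has_red] >= on$onset_standard[has_red]))
})

test_that("patient replay is chronological, deterministic, and order-insensitive", {
  h <- scripted_harmonized(sbp = c(118, 141, 165), days = c(0L, 20L, 40L))
  r1 <- run_patient(h, "patient01")
  expect_equal(r1$onset_standard, 20L)
  expect_equal(r1$onset_red_flag, 40L)
  expect_equal(r1$profiles$level, c("none", "standard", "red_flag"))

  # shuffle encounter and event rows: internal sorting restores chronology
  h2 <- h
  h2$Visit <- h2$Visit[c(3, 1, 2), ]
  h2$Event <- h2$Event[sample.int(nrow(h2$Event)), ]
  r2 <- run_patient(h2, "patient01")
  expect_equal(r2$profiles, r1$profiles)

  all_normal <- scripted_harmonized(sbp = c(110, 112), days = c(0L, 30L))
  r3 <- run_patient(all_normal, "patient01")
  expect_true(is.na(r3$onset_standard) && is.na(r3$onset_red_flag))

  expect_error(run_patient(h, "nobody"), class = "matcvrisk_contract_error")
})

test_that("static findings are active at every encounter; variable ones are not carried forward", {
  h <- scripted_harmonized(sbp = c(141, 118, 118), days = c(0L, 20L, 40L),
                           history = "history of heart disease")
  r <- run_patient(h, "patient01")
  expect_equal(r$profiles$n_findings, c(2L, 1L, 1L))   # sbp only on day 0
  expect_equal(r$profiles$level, c("standard", "standard", "standard"))
})

test_that("baselines use the median of the first k observations and norm flags", {
  h <- scripted_harmonized(sbp = c(100, 104, 102, 150), days = c(0L, 10L, 20L, 30L))
  b <- compute_baseline(h, "patient01", k = 3)
  expect_equal(b$baseline[b$quantity == "systolic_bp"], 102)
  expect_true(attr(b, "conforming_patient"))

  high <- scripted_harmonized(sbp = c(165, 166, 167), days = c(0L, 10L, 20L))
  bh <- compute_baseline(high, "patient01", k = 3)
  expect_false(bh$conforms[bh$quantity == "systolic_bp"])
  expect_false(attr(bh, "conforming_patient"))

  # fewer than k observations: baseline undefined for that quantity
  short <- scripted_harmonized(sbp = c(100, 104), days = c(0L, 10L))
  bs <- compute_baseline(short, "patient01", k = 3)
  expect_false("systolic_bp" %in% bs$quantity)
})

test_that("disabled baseline mode equals plain catalog-threshold evaluation", {
  run <- noise_free_run()
  plain <- assess_cohort(run$harmonized, baseline_mode = FALSE)
  expect_identical(plain$profiles, run$assessment$profiles)
  expect_identical(plain$onsets, run$assessment$onsets)
})

test_that("baseline mode shifts thresholds by the baseline-to-norm-midpoint gap", {
  # baseline 100 vs norm midpoint 114.5 -> thresholds shift down 14.5
  h <- scripted_harmonized(sbp = c(100, 100, 100, 130), days = c(0L, 10L, 20L, 30L))
  off <- run_patient(h, "patient01", baseline_mode = FALSE)
  on <- run_patient(h, "patient01", baseline_mode = TRUE)
  expect_true(is.na(off$onset_standard))
  expect_equal(on$onset_standard, 30L)   # 130 >= 140 - 14.5

  # a non-conforming patient keeps unshifted thresholds
  hh <- scripted_harmonized(sbp = c(150, 150, 150, 150), days = c(0L, 5L, 10L, 15L))
  both_on <- run_patient(hh, "patient01", baseline_mode = TRUE)
  both_off <- run_patient(hh, "patient01", baseline_mode = FALSE)
  expect_equal(both_on$profiles$level, both_off$profiles$level)
})

test_that("event classification flags unknowns until the table is extended", {
  tbl <- default_classification_table()
  first <- classify_event("organ failure", tbl)
  expect_true(first$review)
  expect_true(is.na(first$class))

  tbl2 <- add_classification(tbl, "organ failure", "organ failure risk")
  second <- classify_event("organ failure", tbl2)
  expect_false(second$review)
  expect_equal(second$class, "organ failure risk")
  expect_error(add_classification(tbl2, "organ failure", "x"),
               class = "matcvrisk_config_error")

  known <- classify_event("heart rate", tbl)
  expect_false(known$review)

  # ledger counts every unclassified occurrence and shrinks after review
  ev <- tibble::tibble(event_label = c("organ failure", "organ failure",
                                       "heart rate"))
  led <- classification_ledger(ev, tbl)
  expect_equal(led$occurrences[led$label == "organ failure"], 2L)
  expect_equal(nrow(classification_ledger(ev, tbl2)), 0L)
})
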