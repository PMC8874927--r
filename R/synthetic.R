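#' Configuration for the synthetic EHR cohort generator
#'
#' Defines the statistical conditions the generator emulates: a delivery
#' cohort drawn from a visit-centric EHR, with known fractions of
#' single-visit patients, patients who delivered on their first visit,
#' planted variable-risk trajectories (a subset escalating to red-flag
#' severity), and artifact visits (year-1900 historical uploads and
#' communication-only encounters). Defaults follow the cohort composition
#' reported for the study population where stated (delivered-on-first-visit
#' 46%, single-visit 35%, red-flag 5.3%, static-risk prevalences), with the
#' remaining knobs set to conventional obstetric values; see the methods
#' vignette.
#'
#' @param n_patients Number of patients (>= 1).
#' @param date_window Two calendar dates; every delivery falls inside,
#'   endpoints inclusive.
#' @param frac_single_visit Marginal probability that a patient has exactly
#'   one included prenatal encounter (and did not deliver at it).
#' @param frac_delivery_first_visit Marginal probability that a patient's
#'   first included encounter is the delivery admission itself.
#' @param frac_with_risk Marginal probability of a planted variable-risk
#'   trajectory (rising systolic blood pressure crossing the standard
#'   threshold at a known encounter).
#' @param frac_red_flag Marginal probability that the planted trajectory
#'   escalates past the red-flag threshold; must not exceed
#'   `frac_with_risk`.
#' @param frac_artifact_visits Fraction of visits to inject as artifacts
#'   (split between 1900-registration uploads and communication-only
#'   visits) by [inject_artifacts()].
#' @param mean_visits_per_patient Mean prenatal encounter count for
#'   patients with a multi-visit course.
#' @param lead_time_mean_days Mean of the Poisson lag (days) between the
#'   planted threshold crossing and the planted clinical diagnosis.
#' @param noise_sd SD of additive observation noise on planted vital-sign
#'   trajectories; small by default so the threshold-crossing encounter is
#'   unambiguous.
#' @param gestation_days Length of the prenatal window ending at delivery.
#' @param seed Integer seed; identical configurations produce identical
#'   cohorts.
#' @return A `generator_config` object (a validated list).
#' @export
#' @examples
#' cfg <- generator_config(n_patients = 20, seed = 42)
#' cohort <- generate_cohort(cfg)
#' cohort$records
generator_config <- function(n_patients = 200,
                             date_window = c("2017-01-01", "2020-12-31"),
                             frac_single_visit = 0.35,
                             frac_delivery_first_visit = 0.46,
                             frac_with_risk = 0.16,
                             frac_red_flag = 0.053,
                             frac_artifact_visits = 0.08,
                             mean_visits_per_patient = 8,
                             lead_time_mean_days = 21,
                             noise_sd = 1.5,
                             gestation_days = 280,
                             seed = 1L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients"),
    date_window = as_date_window(date_window, "date_window"),
    frac_single_visit = check_proportion(frac_single_visit, "frac_single_visit"),
    frac_delivery_first_visit =
      check_proportion(frac_delivery_first_visit, "frac_delivery_first_visit"),
    frac_with_risk = check_proportion(frac_with_risk, "frac_with_risk"),
    frac_red_flag = check_proportion(frac_red_flag, "frac_red_flag"),
    frac_artifact_visits =
      check_proportion(frac_artifact_visits, "frac_artifact_visits"),
    mean_visits_per_patient = mean_visits_per_patient,
    lead_time_mean_days = lead_time_mean_days,
    noise_sd = noise_sd,
    gestation_days = check_count(gestation_days, "gestation_days", min = 30L),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$frac_red_flag > cfg$frac_with_risk) {
    abort("`frac_red_flag` cannot exceed `frac_with_risk`.",
          class = "matcvrisk_config_error")
  }
  if (cfg$frac_single_visit + cfg$frac_delivery_first_visit > 1) {
    abort("`frac_single_visit` + `frac_delivery_first_visit` cannot exceed 1.",
          class = "matcvrisk_config_error")
  }
  if (!is.numeric(mean_visits_per_patient) || mean_visits_per_patient <= 0) {
    abort("`mean_visits_per_patient` must be positive.",
          class = "matcvrisk_config_error")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    abort("`noise_sd` must be nonnegative.", class = "matcvrisk_config_error")
  }
  structure(cfg, class = "generator_config")
}

# name and code pools -------------------------------------------------------

.given_names <- c(
  "Amara", "Beatriz", "Carmen", "Dana", "Elena", "Fatima", "Grace", "Hannah",
  "Imani", "Jasmine", "Keisha", "Leila", "Maria", "Nadia", "Olivia", "Priya",
  "Quinn", "Rosa", "Sofia", "Tanya", "Uma", "Valerie", "Wendy", "Ximena",
  "Yara", "Zoe", "Aisha", "Brooke", "Chantal", "Destiny"
)
.family_names <- c(
  "Abbott", "Bishop", "Castillo", "Delgado", "Everett", "Fleming", "Guzman",
  "Holloway", "Ibarra", "Jennings", "Kowalski", "Lindqvist", "Moreau",
  "Nakamura", "Okafor", "Petrov", "Quintana", "Ramsey", "Sandoval", "Tran",
  "Underwood", "Vasquez", "Whitfield", "Xiong", "Yoder", "Zamora"
)

.prenatal_code_pool <- c("Z34.90", "Z34.83", "O09.299", "O09.90")
.delivery_code_pool <- c("10D00Z0", "10D00Z1", "10E0XZZ")
.target_pool <- tibble::tibble(
  label = c("preeclampsia", "eclampsia", "peripartum cardiomyopathy",
            "heart failure", "pulmonary embolism", "myocardial infarction",
            "cerebral infarction"),
  code = c("O14.93", "O15.00", "O90.3", "I50.9", "I26.99", "I21.9", "I63.9"),
  prob = c(0.85, 0.02, 0.05, 0.04, 0.02, 0.01, 0.01)
)
.static_factor_prevalence <- c(
  prepregnancy_obesity = 0.0864,       # planted via prepregnancy BMI value
  race_african_american = 0.2528,      # planted via the race field
  substance_use = 0.107,
  prepregnancy_diabetes = 0.03,
  prepregnancy_hypertension = 0.05,
  history_heart_disease = 0.02,
  history_chemotherapy = 0.005,
  history_labor_complications = 0.04
)
.static_event_labels <- c(
  substance_use = "history of substance use",
  prepregnancy_diabetes = "prepregnancy diabetes",
  prepregnancy_hypertension = "prepregnancy hypertension",
  history_heart_disease = "history of heart disease",
  history_chemotherapy = "history of chemotherapy",
  history_labor_complications = "history of complications in labor or delivery"
)

#' Synthetic zip-code urbanicity lookup
#'
#' A deliberately synthetic zip-to-urbanicity table (the real mapping is
#' census-derived and site-specific): 90 five-digit zips assigned urban,
#' suburban, or rural classes. The generator draws patient zips from this
#' pool so that geographic generalization is exercised end to end. Also
#' shipped as `inst/extdata/zip_urbanicity_synthetic.csv`.
#'
#' @return A tibble with columns `zip` and `class`.
#' @export
synthetic_urbanicity_table <- function() {
  zip <- sprintf("%05d", 30001:30090)
  tibble(zip = zip,
         class = rep(c("urban", "suburban", "rural"), each = 30L))
}

# per-patient visit-day layout ----------------------------------------------

LB_PER_KG <- 2.20462262

#' Generate a synthetic visit-centric EHR cohort with known ground truth
#'
#' Produces identifiable raw tables (persons, visits, clinical events with a
#' shared character result-value field plus a unit field, diagnoses, family
#' history) in which every patient has a documented delivery procedure
#' inside the configured window, plus a ground-truth record of every
#' planted static risk, variable-risk threshold crossing (standard and
#' red-flag, recorded from the values actually emitted), planted diagnosis
#' day, and evaluability status. Weights are emitted in pounds or kilograms
#' at random to exercise unit normalization; free-text comment events
#' deliberately embed patient names and dates to exercise de-identification.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_cohort`: a list with elements `records` (a
#'   `raw_record_set`) and `truth` (a `ground_truth` list of tibbles
#'   `patients`, `trajectories`, `artifacts`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  window_days <- as.integer(config$date_window[2] - config$date_window[1])

  person_id <- format_ids("P", seq_len(n), 5L)
  delivery_date <- config$date_window[1] +
    sample.int(window_days + 1L, n, replace = TRUE) - 1L

  u_cat <- runif(n)
  delivery_first <- u_cat < config$frac_delivery_first_visit
  single_visit <- !delivery_first &
    u_cat < config$frac_delivery_first_visit + config$frac_single_visit

  u_risk <- runif(n)
  red_planted <- u_risk < config$frac_red_flag
  risk_planted <- u_risk < config$frac_with_risk

  age_years <- sample(19:34, n, replace = TRUE)
  dob <- delivery_date - (age_years * 365L + sample(0:300, n, replace = TRUE))

  given <- sample(.given_names, n, replace = TRUE)
  family <- sample(.family_names, n, replace = TRUE)
  zip_pool <- synthetic_urbanicity_table()$zip
  zip <- sample(zip_pool, n, replace = TRUE)
  race <- character(n)
  aa <- runif(n) < .static_factor_prevalence[["race_african_american"]]
  race[aa] <- "African American"
  race[!aa] <- sample(c("White", "Asian", "Hispanic", "Other"), sum(!aa),
                      replace = TRUE, prob = c(0.55, 0.10, 0.25, 0.10))

  bmi35 <- runif(n) < .static_factor_prevalence[["prepregnancy_obesity"]]
  bmi <- round(ifelse(bmi35, runif(n, 35.2, 44), runif(n, 19, 33.5)), 1)
  hist_flags <- sapply(names(.static_event_labels), function(f) {
    runif(n) < .static_factor_prevalence[[f]]
  })

  u_birth <- runif(n)
  outcome_code <- dplyr::case_when(
    u_birth < 0.0003 ~ "Z37.59",            # triplets
    u_birth < 0.0148 ~ "Z37.2",             # twins
    u_birth < 0.0226 ~ "Z37.1",             # single stillbirth
    TRUE ~ "Z37.0"                          # single live birth
  )

  per_patient <- purrr::map(seq_len(n), function(i) {
    build_patient(
      i, config,
      person_id = person_id[i], delivery_date = delivery_date[i],
      delivery_first = delivery_first[i], single_visit = single_visit[i],
      risk_planted = risk_planted[i], red_planted = red_planted[i],
      given = given[i], family = family[i], dob = dob[i],
      bmi = bmi[i], hist_flags = hist_flags[i, , drop = TRUE],
      outcome_code = outcome_code[i]
    )
  })

  visits <- purrr::list_rbind(purrr::map(per_patient, "visits"))
  events <- purrr::list_rbind(purrr::map(per_patient, "events"))
  diagnoses <- purrr::list_rbind(purrr::map(per_patient, "diagnoses"))
  gt_rows <- purrr::list_rbind(purrr::map(per_patient, "truth"))
  traj <- purrr::list_rbind(purrr::map(per_patient, "trajectory"))

  # finalize ground truth: fold race into the static set, derive onsets
  # (a patient with any static risk is at standard risk from day 0; the
  # red-flag level is reached at the first red threshold crossing or, when
  # enough simultaneous findings accumulate, at the first encounter where
  # the distinct-finding count reaches 4)
  gt_rows <- gt_rows |>
    mutate(
      race = race,
      static_ids = dplyr::if_else(
        aa,
        dplyr::if_else(.data$static_ids == "", "race_african_american",
                       paste(.data$static_ids, "race_african_american", sep = ";")),
        .data$static_ids
      ),
      n_static = .data$n_static_wo_race + as.integer(aa),
      onset_standard_day = dplyr::case_when(
        .data$n_static >= 1L ~ 0L,
        TRUE ~ as.integer(.data$sbp_standard_day)
      ),
      onset_red_flag_day = pmin(
        as.integer(.data$sbp_red_flag_day),
        dplyr::case_when(
          .data$n_static >= 4L ~ 0L,
          .data$n_static == 3L ~ as.integer(.data$sbp_standard_day),
          TRUE ~ NA_integer_
        ),
        na.rm = TRUE
      ),
      risk_group = dplyr::case_when(
        !is.na(.data$onset_red_flag_day) ~ "red_flag",
        !is.na(.data$onset_standard_day) ~ "standard",
        TRUE ~ "none"
      ),
      exclusion_reason = dplyr::case_when(
        .data$category == "delivery_first" ~ "delivered_first_visit",
        .data$n_included_visits == 1L ~ "single_visit",
        TRUE ~ NA_character_
      ),
      evaluable = is.na(.data$exclusion_reason)
    ) |>
    select(-"n_static_wo_race")

  # temporary per-patient visit keys -> global visit ids
  visits <- visits |>
    mutate(visit_id = format_ids("V", dplyr::row_number(), 6L))
  key_map <- visits |> select("visit_key", "visit_id")
  events <- events |>
    left_join(key_map, by = "visit_key") |>
    select(-"visit_key") |>
    mutate(event_id = format_ids("E", dplyr::row_number(), 7L))
  diagnoses <- diagnoses |>
    left_join(key_map, by = "visit_key") |>
    select(-"visit_key") |>
    mutate(diagnosis_id = format_ids("D", dplyr::row_number(), 7L))
  visits <- visits |> select(-"visit_key")

  persons <- tibble(
    person_id = person_id, given_name = given, family_name = family,
    date_of_birth = dob, race = race, zip = zip
  )

  n_fh <- rpois(n, 0.8)
  family_history <- tibble(
    person_id = rep(person_id, n_fh),
    item = sample(c("family history of diabetes",
                    "family history of hypertension",
                    "family history of coronary artery disease",
                    "family history of breast cancer"),
                  sum(n_fh), replace = TRUE)
  )

  records <- raw_record_set(
    persons = persons,
    visits = visits |> select("visit_id", "person_id", "registration_datetime",
                              "visit_type"),
    events = events |> select("event_id", "visit_id", "person_id",
                              "event_label", "result_value", "result_unit",
                              "event_datetime"),
    diagnoses = diagnoses |> select("diagnosis_id", "visit_id", "person_id",
                                    "code", "code_system", "diagnosis_type",
                                    "diagnosis_datetime"),
    family_history = family_history
  )

  truth <- structure(
    list(
      patients = gt_rows,
      trajectories = traj,
      artifacts = tibble(visit_id = character(), person_id = character(),
                         kind = character())
    ),
    class = "ground_truth"
  )
  structure(list(records = records, truth = truth, config = config),
            class = "synthetic_cohort")
}

# one patient's visits, events, diagnoses and ground-truth row
build_patient <- function(i, config, person_id, delivery_date, delivery_first,
                          single_visit, risk_planted, red_planted, given,
                          family, dob, bmi, hist_flags, outcome_code) {
  gest <- config$gestation_days
  if (delivery_first) {
    days_before <- integer(0)
  } else if (single_visit) {
    days_before <- sample(30:200, 1L)
  } else {
    nv <- 2L + rpois(1L, max(config$mean_visits_per_patient - 2, 0.1))
    nv <- min(nv, 200L)
    days_before <- sort(sample(7:min(gest - 10L, 270L), nv), decreasing = TRUE)
  }
  prenatal_dates <- delivery_date - days_before

  # included encounters: prenatal visits, plus the delivery admission for
  # delivery-first patients (who present in labor, so pregnancy codes are
  # recorded at the admission)
  included_dates <- if (delivery_first) delivery_date else prenatal_dates
  n_inc <- length(included_dates)
  index_date <- min(included_dates)

  # planted systolic trajectory over included encounters
  sbp0 <- min(max(round(rnorm(1, 112, 5)), 100), 124)
  onset_idx <- red_idx <- NA_integer_
  if (risk_planted) {
    onset_idx <- if (n_inc <= 2L) n_inc else sample(2:(n_inc - 1L), 1L)
    if (red_planted) red_idx <- min(onset_idx + 1L, n_inc)
  }
  noise <- function(k) rnorm(k, 0, config$noise_sd)
  sbp <- round(sbp0 + noise(n_inc))
  if (!is.na(onset_idx)) {
    hi <- onset_idx:n_inc
    sbp[hi] <- round(148 + noise(length(hi)))
    if (!is.na(red_idx)) {
      rf <- red_idx:n_inc
      sbp[rf] <- round(167 + noise(length(rf)))
    }
  }
  hr <- round(min(max(rnorm(1, 80, 6), 65), 100) + noise(n_inc))
  rr <- pmin(pmax(round(rnorm(n_inc, 16, 1.5)), 12), 22)
  spo2 <- sample(97:100, n_inc, replace = TRUE, prob = c(0.1, 0.3, 0.4, 0.2))
  w0 <- min(max(rnorm(1, 68, 9), 45), 110)
  gest_day <- gest - as.integer(delivery_date - included_dates)
  weight_kg <- w0 + 0.045 * gest_day

  visit_key <- sprintf("%s#%d", person_id, seq_len(n_inc + !delivery_first))
  inc_types <- if (delivery_first) {
    "hospital admission"
  } else {
    sample(c("clinic appointment", "emergency department"), n_inc,
           replace = TRUE, prob = c(0.92, 0.08))
  }
  visit_dates <- c(included_dates, if (!delivery_first) delivery_date)
  visit_types <- c(inc_types, if (!delivery_first) "hospital admission")
  visit_times <- random_times(length(visit_dates))
  visits <- tibble(
    visit_key = visit_key, person_id = person_id,
    registration_datetime = as.POSIXct(paste(visit_dates, visit_times),
                                       tz = "UTC"),
    visit_type = visit_types
  )
  admission_key <- visit_key[length(visit_key)]   # delivery admission
  inc_keys <- visit_key[seq_len(n_inc)]

  # clinical events on included encounters
  ev <- list()
  add_ev <- function(key, date, label, value, unit) {
    tibble(visit_key = key, person_id = person_id, event_label = label,
           result_value = as.character(value), result_unit = unit,
           event_datetime = as.POSIXct(paste(date, random_times(length(key))),
                                       tz = "UTC"))
  }
  ev$sbp <- add_ev(inc_keys, included_dates, "systolic blood pressure", sbp, "mm Hg")
  ev$hr <- add_ev(inc_keys, included_dates, "heart rate", hr, "bpm")
  ev$rr <- add_ev(inc_keys, included_dates, "respiratory rate", rr, "breaths/min")
  ev$spo2 <- add_ev(inc_keys, included_dates, "oxygen saturation", spo2, "%")
  in_lb <- runif(n_inc) < 0.5
  wval <- ifelse(in_lb, round(weight_kg * LB_PER_KG, 1), round(weight_kg, 1))
  ev$wt <- add_ev(inc_keys, included_dates, "weight", wval,
                  ifelse(in_lb, "lb", "kg"))
  lab_pick <- runif(n_inc) < 0.6
  if (any(lab_pick)) {
    ev$hgb <- add_ev(inc_keys[lab_pick], included_dates[lab_pick], "hemoglobin",
                     round(rnorm(sum(lab_pick), 12.5, 0.8), 1), "g/dL")
  }
  misc_pick <- runif(n_inc) < 0.1
  if (any(misc_pick)) {
    ev$misc <- add_ev(inc_keys[misc_pick], included_dates[misc_pick],
                      "nausea of pregnancy", "present", "")
  }
  # a lab outside the shipped rule set: lands in the review queue
  vitd_pick <- runif(n_inc) < 0.05
  if (any(vitd_pick)) {
    ev$vitd <- add_ev(inc_keys[vitd_pick], included_dates[vitd_pick],
                      "vitamin D level",
                      round(rnorm(sum(vitd_pick), 32, 6), 1), "ng/mL")
  }
  # free-text artifacts carrying identifiers (to be stripped downstream)
  com_pick <- runif(n_inc) < 0.15
  if (any(com_pick)) {
    ev$comment <- add_ev(
      inc_keys[com_pick], included_dates[com_pick], "comment",
      sprintf("Patient %s %s seen %s; discussed plan of care", given, family,
              format(included_dates[com_pick])), ""
    )
  }
  if (runif(1) < 0.3) {
    ev$regnote <- add_ev(inc_keys[1L], included_dates[1L], "registration note",
                         sprintf("DOB %s confirmed at registration", format(dob)),
                         "")
  }
  # first-encounter history and prepregnancy measurements (static risks)
  ev$bmi <- add_ev(inc_keys[1L], included_dates[1L], "prepregnancy BMI", bmi,
                   "kg/m2")
  on_flags <- names(hist_flags)[hist_flags]
  if (length(on_flags)) {
    ev$hist <- add_ev(rep(inc_keys[1L], length(on_flags)),
                      rep(included_dates[1L], length(on_flags)),
                      unname(.static_event_labels[on_flags]), "present", "")
  }
  events <- purrr::list_rbind(ev)

  # diagnoses
  dx <- list()
  add_dx <- function(key, date, code, system, type) {
    tibble(visit_key = key, person_id = person_id, code = code,
           code_system = system, diagnosis_type = type,
           diagnosis_datetime = as.POSIXct(paste(date, random_times(length(key))),
                                           tz = "UTC"))
  }
  dx$prenatal <- add_dx(inc_keys, included_dates,
                        sample(.prenatal_code_pool, n_inc, replace = TRUE),
                        "ICD-10-CM", "encounter diagnosis")
  dx$delivery <- add_dx(admission_key, delivery_date,
                        sample(.delivery_code_pool, 1L), "ICD-10-PCS",
                        "procedure")
  dx$outcome <- add_dx(admission_key, delivery_date, outcome_code, "ICD-10-CM",
                       "discharge diagnosis")

  # realized ground truth (offsets from the index encounter); race is drawn
  # at the cohort level and folded into the static set afterwards
  offsets <- days_between(index_date, included_dates)
  std_day <- offsets[sbp >= 140][1]
  red_day <- offsets[sbp >= 160][1]
  static_ids <- c(
    names(hist_flags)[hist_flags],
    if (bmi >= 35) "prepregnancy_obesity"
  )
  n_static_wo_race <- length(static_ids)

  diagnosis_date <- as.Date(NA)
  target_label <- target_code <- NA_character_
  if (risk_planted && !is.na(std_day)) {
    pick <- sample.int(nrow(.target_pool), 1L, prob = .target_pool$prob)
    target_label <- .target_pool$label[pick]
    target_code <- .target_pool$code[pick]
    crossing_date <- index_date + std_day
    lead <- rpois(1L, config$lead_time_mean_days)
    target_date <- crossing_date + lead
    candidates <- sort(unique(c(included_dates[included_dates >= crossing_date],
                                delivery_date)))
    later <- candidates[candidates >= target_date]
    diagnosis_date <- if (length(later)) later[1] else candidates[length(candidates)]
    dx_key <- if (diagnosis_date %in% included_dates) {
      inc_keys[match(diagnosis_date, included_dates)]
    } else {
      admission_key
    }
    dx$target <- add_dx(dx_key, diagnosis_date, target_code, "ICD-10-CM",
                        "encounter diagnosis")
  }
  diagnoses <- purrr::list_rbind(dx)

  truth <- tibble(
    person_id = person_id,
    category = if (delivery_first) "delivery_first" else
      if (single_visit) "single_visit" else "multi",
    delivery_date = delivery_date,
    index_date = index_date,
    n_included_visits = n_inc,
    static_ids = paste(static_ids, collapse = ";"),
    n_static_wo_race = n_static_wo_race,
    sbp_standard_day = std_day,
    sbp_red_flag_day = red_day,
    target_label = target_label,
    target_code = target_code,
    diagnosis_day = if (is.na(diagnosis_date)) NA_integer_ else
      days_between(index_date, diagnosis_date),
    outcome_code = outcome_code
  )
  trajectory <- if (risk_planted) {
    tibble(person_id = person_id, factor_id = "sbp_high",
           quantity = "systolic_bp", standard_crossing_day = std_day,
           red_flag_crossing_day = red_day)
  } else {
    tibble(person_id = character(), factor_id = character(),
           quantity = character(), standard_crossing_day = integer(),
           red_flag_crossing_day = integer())
  }
  list(visits = visits, events = events, diagnoses = diagnoses, truth = truth,
       trajectory = trajectory)
}
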