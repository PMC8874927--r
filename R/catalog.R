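#' Maternal cardiovascular risk-factor catalog
#'
#' Builds the default catalog of risk factors and covariates used by the
#' encounter-by-encounter risk engine: symptoms and physical findings
#' (variable risks, evaluated per encounter) and medical-history items
#' (static risks, active at every encounter once present). Numeric factors
#' carry an inclusive standard threshold and, where defined, a more extreme
#' inclusive red-flag threshold; presence factors may be red-flag on
#' presence alone (dyspnea, orthopnea).
#'
#' The catalog is an ordinary tibble so sites can add, drop or re-threshold
#' factors with dplyr verbs, or maintain it as an editable YAML file via
#' [read_risk_catalog()] / [write_risk_catalog()].
#'
#' @return A tibble with one row per risk factor and columns
#'   `factor_id`, `description`, `kind` (symptom / physical_finding /
#'   history), `persistence` (variable / static), `trigger` (presence /
#'   numeric), `quantity`, `direction` (`"ge"` or `"le"`),
#'   `threshold_standard`, `threshold_red` (NA when the factor has no
#'   red-flag threshold), `red_flag_on_presence`, and `labels`, a
#'   list-column of event labels (lower case) that map onto the factor.
#' @export
#' @examples
#' risk_catalog()
risk_catalog <- function() {
  num <- function(id, desc, kind, persistence, quantity, direction, std, red, labels) {
    tibble(
      factor_id = id, description = desc, kind = kind, persistence = persistence,
      trigger = "numeric", quantity = quantity, direction = direction,
      threshold_standard = std, threshold_red = red,
      red_flag_on_presence = FALSE, labels = list(labels)
    )
  }
  pres <- function(id, desc, kind, persistence, red, labels) {
    tibble(
      factor_id = id, description = desc, kind = kind, persistence = persistence,
      trigger = "presence", quantity = NA_character_, direction = NA_character_,
      threshold_standard = NA_real_, threshold_red = NA_real_,
      red_flag_on_presence = red, labels = list(labels)
    )
  }
  bind_rows(
    # symptoms (variable)
    pres("dyspnea", "Dyspnea", "symptom", "variable", TRUE,
         c("dyspnea", "shortness of breath")),
    pres("orthopnea", "Orthopnea", "symptom", "variable", TRUE, "orthopnea"),
    pres("tachypnea_symptom", "Tachypnea (coded symptom)", "symptom", "variable",
         FALSE, "tachypnea"),
    pres("asthma_unresponsive", "Asthma unresponsive to therapy", "symptom",
         "variable", FALSE, "asthma unresponsive to therapy"),
    pres("swelling_face_hands", "Swelling in face or hands", "symptom", "variable",
         FALSE, c("swelling in face or hands", "facial swelling")),
    pres("new_worsening_headache", "New or worsening headache", "symptom",
         "variable", FALSE, "new or worsening headache"),
    pres("palpitations", "Heart palpitations", "symptom", "variable", FALSE,
         c("heart palpitations", "palpitations")),
    pres("dizziness_syncope", "Dizziness or syncope", "symptom", "variable", FALSE,
         c("dizziness", "syncope")),
    pres("chest_pain", "Chest pain", "symptom", "variable", FALSE, "chest pain"),
    # physical findings (variable)
    pres("loud_heart_murmur", "Loud heart murmur", "physical_finding", "variable",
         FALSE, "loud heart murmur"),
    pres("basilar_crackles", "Basilar crackles in lungs", "physical_finding",
         "variable", FALSE, c("basilar crackles", "basilar crackles in lungs")),
    num("heart_rate_high", "Resting heart rate >= 110 bpm (red flag >= 120)",
        "physical_finding", "variable", "heart_rate", "ge", 110, 120,
        c("heart rate", "resting heart rate", "pulse rate")),
    num("sbp_high", "Systolic blood pressure >= 140 mm Hg (red flag >= 160)",
        "physical_finding", "variable", "systolic_bp", "ge", 140, 160,
        c("systolic blood pressure", "sbp")),
    num("resp_rate_high", "Respiratory rate >= 24 /min (red flag >= 30)",
        "physical_finding", "variable", "resp_rate", "ge", 24, 30,
        c("respiratory rate", "resp rate")),
    num("spo2_low", "Oxygen saturation <= 96% (red flag <= 94%)",
        "physical_finding", "variable", "spo2", "le", 96, 94,
        c("oxygen saturation", "spo2", "pulse oximetry")),
    # medical history (static)
    num("age_40", "Aged >= 40 years", "history", "static", "age", "ge", 40,
        NA_real_, "age"),
    pres("race_african_american", "Race: African American", "history", "static",
         FALSE, "african american"),
    num("prepregnancy_obesity", "Prepregnancy obesity (BMI >= 35)", "history",
        "static", "bmi", "ge", 35, NA_real_,
        c("prepregnancy bmi", "pre-pregnancy bmi")),
    pres("prepregnancy_diabetes", "Prepregnancy diagnosis of diabetes", "history",
         "static", FALSE, c("prepregnancy diabetes", "pregestational diabetes")),
    pres("prepregnancy_hypertension", "Prepregnancy diagnosis of hypertension",
         "history", "static", FALSE,
         c("prepregnancy hypertension", "chronic hypertension")),
    pres("substance_use", "Substance use (nicotine, cocaine, alcohol, methamphetamines)",
         "history", "static", FALSE,
         c("history of substance use", "substance use")),
    pres("history_chemotherapy", "History of chemotherapy", "history", "static",
         FALSE, "history of chemotherapy"),
    pres("history_labor_complications", "History of complications in labor or delivery",
         "history", "static", FALSE,
         c("history of labor or delivery complications",
           "history of complications in labor or delivery")),
    pres("history_heart_disease", "History of heart disease", "history", "static",
         FALSE, "history of heart disease")
  )
}

#' Medically accepted reference ranges for baseline conformance
#'
#' Per-quantity accepted ranges used when individual-baseline mode is
#' enabled: a patient whose computed baseline falls outside the range for
#' any quantity is flagged as non-conforming and excluded from calibration.
#' The shipped values are conventional adult reference ranges and are
#' deliberately labelled non-authoritative; sites should supply their own.
#'
#' @return A tibble with columns `quantity`, `lower`, `upper`, `midpoint`.
#' @export
quantity_norms <- function() {
  tibble(
    quantity = c("systolic_bp", "heart_rate", "resp_rate", "spo2", "bmi"),
    lower = c(90, 60, 12, 97, 18.5),
    upper = c(139, 109, 23, 100, 34.9)
  ) |>
    mutate(midpoint = (.data$lower + .data$upper) / 2)
}

#' Target cardiovascular conditions for lead-time evaluation
#'
#' The conditions whose first recorded diagnosis anchors the provider
#' reference day when computing detection lead times: preeclampsia,
#' eclampsia, peripartum cardiomyopathy, cerebral infarction, myocardial
#' infarction, heart failure, and pulmonary embolism. Codes are matched by
#' prefix against ICD-10-CM diagnosis codes.
#'
#' @return A tibble with columns `label` and `code_prefix`.
#' @export
target_conditions <- function() {
  tibble(
    label = c("preeclampsia", "eclampsia", "peripartum cardiomyopathy",
              "cerebral infarction", "myocardial infarction", "heart failure",
              "pulmonary embolism"),
    code_prefix = c("O14", "O15", "O90.3", "I63", "I21", "I50", "I26")
  )
}

#' Read or write a risk catalog as YAML
#'
#' @param path File path of the YAML catalog.
#' @param catalog A risk catalog tibble as returned by [risk_catalog()].
#' @return `read_risk_catalog()` returns a catalog tibble;
#'   `write_risk_catalog()` returns `path` invisibly.
#' @export
read_risk_catalog <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::map_dfr(raw, function(f) {
    tibble(
      factor_id = f$factor_id,
      description = f$description %||% f$factor_id,
      kind = f$kind,
      persistence = f$persistence,
      trigger = f$trigger,
      quantity = f$quantity %||% NA_character_,
      direction = f$direction %||% NA_character_,
      threshold_standard = as.numeric(f$threshold_standard %||% NA),
      threshold_red = as.numeric(f$threshold_red %||% NA),
      red_flag_on_presence = isTRUE(f$red_flag_on_presence),
      labels = list(unlist(f$labels))
    )
  }) |>
    validate_catalog()
}

#' @rdname read_risk_catalog
#' @export
write_risk_catalog <- function(catalog, path) {
  validate_catalog(catalog)
  entries <- purrr::pmap(catalog, function(...) {
    f <- list(...)
    f$labels <- as.list(f$labels)
    f[!vapply(f, function(x) length(x) == 1L && is.na(x), logical(1))]
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

validate_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  if (anyDuplicated(catalog$factor_id)) {
    abort("Risk catalog factor ids must be unique.", class = "matcvrisk_config_error")
  }
  num <- dplyr::filter(catalog, .data$trigger == "numeric")
  if (any(is.na(num$threshold_standard))) {
    abort("Numeric risk factors require a standard threshold.",
          class = "matcvrisk_config_error")
  }
  # a red-flag threshold must be at least as extreme as standard in the
  # trigger direction
  bad <- !is.na(num$threshold_red) &
    ifelse(num$direction == "ge",
           num$threshold_red < num$threshold_standard,
           num$threshold_red > num$threshold_standard)
  if (any(bad)) {
    abort(paste0("Red-flag threshold less extreme than standard for: ",
                 paste(num$factor_id[bad], collapse = ", ")),
          class = "matcvrisk_config_error")
  }
  catalog
}

# long (factor_id, label) map used for joining events onto the catalog
catalog_label_map <- function(catalog) {
  catalog |>
    select("factor_id", "labels") |>
    tidyr::unnest_longer("labels", values_to = "label") |>
    mutate(label = tolower(.data$label))
}
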