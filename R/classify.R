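#' Classify events against an extensible classification table
#'
#' Output classification identifies records the engine cannot explain:
#' labels present in the classification table receive their class; unknown
#' labels are flagged for human review and accumulated in an error ledger.
#' Once a reviewer adds a classification (e.g. the organ-failure class
#' discovered during review), re-running reclassifies every prior
#' occurrence of that label, so the ledger shrinks as the table grows.
#'
#' @param labels Character vector of event labels to classify.
#' @param table A classification tibble with columns `label`, `class`
#'   (case-insensitive label match), e.g. [default_classification_table()].
#' @return A tibble `label`, `class` (NA when unknown), `review`
#'   (TRUE when flagged for human review).
#' @export
#' @examples
#' classify_event("organ failure", default_classification_table())
classify_event <- function(labels, table = default_classification_table()) {
  stopifnot(all(c("label", "class") %in% names(table)))
  cls <- table$class[match(tolower(labels), tolower(table$label))]
  tibble(label = labels, class = cls, review = is.na(cls))
}

#' @rdname classify_event
#' @param label,class A new label/class pair confirmed by human review.
#' @return `add_classification()` returns the extended table.
#' @export
add_classification <- function(table, label, class) {
  if (tolower(label) %in% tolower(table$label)) {
    abort(sprintf("Label `%s` is already classified.", label),
          class = "matcvrisk_config_error")
  }
  bind_rows(table, tibble(label = label, class = class))
}

#' @rdname classify_event
#' @export
default_classification_table <- function() {
  tibble(
    label = c("systolic blood pressure", "heart rate", "respiratory rate",
              "oxygen saturation", "weight", "prepregnancy bmi", "hemoglobin",
              "glucose", "dyspnea", "orthopnea", "tachypnea", "chest pain",
              "heart palpitations", "dizziness", "syncope",
              "new or worsening headache", "swelling in face or hands",
              "loud heart murmur", "basilar crackles"),
    class = c(rep("vital sign", 4L), rep("measurement", 2L), rep("lab", 2L),
              rep("symptom", 9L), rep("physical finding", 2L))
  )
}

#' Build the error ledger for a set of events
#'
#' @param events A tibble with an `event_label` column.
#' @inheritParams classify_event
#' @return A tibble of unclassified labels with occurrence counts, sorted
#'   by frequency.
#' @export
classification_ledger <- function(events, table = default_classification_table()) {
  classify_event(events$event_label, table) |>
    filter(.data$review) |>
    count(.data$label, sort = TRUE, name = "occurrences")
}
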