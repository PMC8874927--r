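#' Plot encounter-level risk timelines
#'
#' One horizontal timeline per patient (day offset on the x axis), each
#' encounter colored by its risk profile level. With more patients than
#' `max_patients`, the patients with the most encounters are shown.
#'
#' @param object A `risk_assessment`.
#' @param max_patients Number of patient timelines to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method
autoplot.risk_assessment <- function(object, max_patients = 25L, ...) {
  keep <- object$profiles |>
    count(.data$person_id, sort = TRUE) |>
    head(max_patients) |>
    pull("person_id")
  df <- object$profiles |>
    filter(.data$person_id %in% keep) |>
    mutate(level = level_factor(.data$level),
           patient = factor(substr(.data$person_id, 1L, 8L)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$day_offset, y = .data$patient,
                                   color = .data$level)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient),
                       color = "grey80", linewidth = 0.3) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::scale_color_manual(
      values = c(none = "grey65", standard = "#e6a117", red_flag = "#c5352b"),
      drop = FALSE
    ) +
    ggplot2::labs(x = "Days from index visit", y = NULL, color = "Risk level",
                  title = "Encounter-by-encounter risk profiles") +
    ggplot2::theme_minimal()
}

#' Plot the detection lead-time distribution
#'
#' Histogram of signed deltas (reference day minus onset day) over
#' evaluable patients with computable deltas; positive values mean the
#' engine flagged risk before the recorded diagnosis.
#'
#' @param object A `delta_eval`.
#' @param binwidth Histogram bin width in days.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method
autoplot.delta_eval <- function(object, binwidth = 7, ...) {
  df <- as_tibble(object) |>
    filter(.data$evaluable, !is.na(.data$delta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "#31688e",
                            color = "white", boundary = 0) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "Detection lead time (days before provider diagnosis)",
      y = "Patients",
      title = "Lead time between engine detection and recorded diagnosis"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.delta_eval
#' @export
plot_delta_distribution <- function(object, binwidth = 7, ...) {
  autoplot.delta_eval(object, binwidth = binwidth, ...)
}

#' Plot the cohort-overview report as a bar chart
#'
#' @param object A `summary_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method
autoplot.summary_report <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(pct = 100 * .data$count / .data$denominator,
           label = factor(.data$label, levels = rev(unique(.data$label))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pct, y = .data$label)) +
    ggplot2::geom_col(fill = "#31688e") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$section), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = "% of section denominator", y = NULL,
                  title = "Cohort overview") +
    ggplot2::theme_minimal()
}
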