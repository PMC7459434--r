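# ggplot2 graphics for the result types.

#' @describeIn month_roc Plot the ROC curve.
#' @param object An `sbce_roc`.
#' @param ... Unused.
#' @method autoplot sbce_roc
#' @export
autoplot.sbce_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = sprintf("Month-level ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' @describeIn km_pair Plot the observed and predicted event-time curves as
#'   step functions with censoring marks.
#' @param object An `sbce_km`.
#' @param ... Unused.
#' @method autoplot sbce_km
#' @export
autoplot.sbce_km <- function(object, ...) {
  curves <- object$curves %>%
    group_by(.data$curve) %>%
    dplyr::group_modify(~ bind_rows(
      tibble(time = 0, n_risk = NA_integer_, n_event = 0L, n_censor = 0L,
             survival = 1), .x)) %>%
    ungroup()
  p <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$time, y = .data$survival,
                                            colour = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = filter(curves, .data$n_censor > 0), shape = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months since diagnosis", y = "Event-free proportion",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold)) {
    p <- p + ggplot2::ggtitle(
      sprintf("Observed vs predicted time to event (PT %.2f)", object$threshold))
  }
  p
}

#' Plot per-threshold diagnostic metrics
#'
#' Sensitivity, specificity, PPV and NPV across the threshold grid.
#'
#' @param report An `sbce_evaluation`.
#' @return A ggplot.
#' @export
plot_threshold_metrics <- function(report) {
  long <- report$threshold_table %>%
    select("threshold", "sensitivity", "specificity", "ppv", "npv") %>%
    tidyr::pivot_longer(-"threshold", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Probability threshold", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn evaluate_sbce `autoplot()` draws the ROC curve; see also
#'   [plot_threshold_metrics()] and `autoplot()` on `$km`.
#' @param object An `sbce_evaluation`.
#' @method autoplot sbce_evaluation
#' @export
autoplot.sbce_evaluation <- function(object, ...) {
  autoplot(object$roc)
}

#' Plot one patient's monthly claim profile
#'
#' Total in-window claims per month for one patient, with the event month
#' (when present) marked — the typical pattern is a sharp rise in claims at
#' and after the event with a short workup bump just before it.
#'
#' @param panel A `month_panel`.
#' @param patient_id The patient to plot.
#' @param probabilities Optional month-level predictions (tibble
#'   `patient_id`, `month_index`, `probability`) to overlay.
#' @return A ggplot.
#' @export
plot_claims_profile <- function(panel, patient_id, probabilities = NULL) {
  w <- filter(panel$windows, .data$patient_id == .env$patient_id)
  if (nrow(w) == 0) {
    abort(sprintf("patient %s not in panel", patient_id),
          class = "recurmine_config_error")
  }
  months <- tibble(month_index = seq(w$start_month, w$end_month))
  totals <- panel$counts %>%
    filter(.data$patient_id == .env$patient_id) %>%
    group_by(.data$month_index) %>%
    summarise(claims = sum(.data$count), .groups = "drop")
  df <- left_join(months, totals, by = "month_index") %>%
    mutate(claims = tidyr::replace_na(.data$claims, 0L))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$month_index, y = .data$claims)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "Months since diagnosis", y = "Claims in month",
                  title = sprintf("Patient %s", patient_id)) +
    ggplot2::theme_minimal()
  if (!is.na(w$sbce_month)) {
    p <- p + ggplot2::geom_vline(xintercept = w$sbce_month, colour = "red",
                                 linetype = "dashed")
  }
  if (!is.null(probabilities)) {
    pr <- filter(probabilities, .data$patient_id == .env$patient_id)
    p <- p + ggplot2::geom_line(
      data = pr,
      ggplot2::aes(x = .data$month_index, y = .data$probability * max(df$claims)),
      colour = "blue")
  }
  p
}
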