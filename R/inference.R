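# Person-level inference: converting a patient's month-level probability
# series into an event call and a predicted event month, across a grid of
# probability thresholds (PT).

#' Probability-threshold grid
#'
#' The default grid runs from 0.10 to 0.75 in steps of 0.05.
#'
#' @param from,to,by Grid limits and step.
#' @return A strictly increasing numeric vector of thresholds in (0, 1).
#' @export
threshold_grid <- function(from = 0.10, to = 0.75, by = 0.05) {
  if (to < from || by <= 0) {
    abort("thresholds must be strictly increasing and lie in (0, 1)",
          class = "recurmine_config_error")
  }
  grid <- seq(from, to, by)
  check_thresholds(grid)
  grid
}

check_thresholds <- function(grid) {
  if (length(grid) == 0 || any(grid <= 0 | grid >= 1) ||
      any(diff(grid) <= 0)) {
    abort("thresholds must be strictly increasing and lie in (0, 1)",
          class = "recurmine_config_error")
  }
  invisible(grid)
}

#' Call a patient positive if any month exceeds the threshold
#'
#' Exceedance is strict (`>`): a month whose probability equals the
#' threshold exactly does not trigger a call.
#'
#' @param probs Numeric vector of month-level probabilities over the
#'   patient's valid window (nonempty).
#' @param threshold A single probability threshold.
#' @return `TRUE` if `max(probs) > threshold`.
#' @export
classify_person <- function(probs, threshold) {
  if (length(probs) == 0) {
    abort("empty probability series", class = "recurmine_contract_error")
  }
  max(probs) > threshold
}

#' Predicted event month from a probability series
#'
#' Two timing rules are provided. `"first_exceed"` (default): the earliest
#' month whose probability strictly exceeds the threshold. `"max_increase"`:
#' the month with the largest increase in probability over the preceding
#' month (earliest maximiser on ties; for a single-month series the sole
#' month is returned). `max_increase` is invariant to adding a constant to
#' the whole series.
#'
#' @param months Integer vector of month indices (sorted ascending).
#' @param probs Matching probability vector.
#' @param threshold The probability threshold; the patient must already be
#'   classified positive at this threshold.
#' @param method `"first_exceed"` or `"max_increase"`.
#' @return A single month index.
#' @export
predict_event_month <- function(months, probs,
                                threshold,
                                method = c("first_exceed", "max_increase")) {
  method <- match.arg(method)
  if (!classify_person(probs, threshold)) {
    abort("predict_event_month called for a patient not classified positive",
          class = "recurmine_contract_error")
  }
  o <- order(months)
  months <- months[o]
  probs <- probs[o]
  if (method == "first_exceed") {
    months[which(probs > threshold)[1]]
  } else {
    if (length(probs) == 1) return(months[1])
    inc <- diff(probs)
    months[which.max(inc) + 1L]
  }
}

#' Person-level calls across the threshold grid
#'
#' @param predictions Tibble of month-level predictions with columns
#'   `patient_id`, `month_index`, `probability` (one series per patient over
#'   their valid window).
#' @param thresholds Threshold grid (default [threshold_grid()]).
#' @param timing_method Timing rule, see [predict_event_month()].
#' @return A tibble with one row per (patient, threshold): `patient_id`,
#'   `threshold`, `predicted_sbce`, `predicted_month` (`NA` when negative),
#'   and a `timing_method` attribute recording the rule used.
#' @export
threshold_sweep <- function(predictions, thresholds = threshold_grid(),
                            timing_method = c("first_exceed", "max_increase")) {
  timing_method <- match.arg(timing_method)
  check_thresholds(thresholds)
  series <- predictions %>%
    arrange(.data$patient_id, .data$month_index) %>%
    group_by(.data$patient_id) %>%
    summarise(months = list(.data$month_index),
              probs = list(.data$probability), .groups = "drop")
  out <- tidyr::crossing(series, threshold = thresholds) %>%
    mutate(
      predicted_sbce = purrr::map2_lgl(.data$probs, .data$threshold,
                                       classify_person),
      predicted_month = purrr::pmap_int(
        list(.data$months, .data$probs, .data$threshold, .data$predicted_sbce),
        function(m, p, t, pos) {
          if (!pos) return(NA_integer_)
          as.integer(predict_event_month(m, p, t, timing_method))
        })
    ) %>%
    select("patient_id", "threshold", "predicted_sbce", "predicted_month") %>%
    arrange(.data$threshold, .data$patient_id)
  attr(out, "timing_method") <- timing_method
  out
}
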