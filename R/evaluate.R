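# Evaluation: month-level ROC/AUC, per-threshold person-level diagnostics,
# timing-error summaries, and observed-versus-predicted Kaplan-Meier curves.

#' Month-level ROC curve and AUC
#'
#' The curve sweeps over all distinct predicted probabilities as cutpoints;
#' the AUC is the trapezoid area, which equals the Mann-Whitney concordance
#' probability (ties counted 1/2).
#'
#' @param probs Numeric vector of predicted probabilities.
#' @param labels Binary 0/1 vector; both classes must be present.
#' @return An `sbce_roc`: list with `curve` (tibble `cutoff`, `fpr`, `tpr`)
#'   and `auc`.
#' @export
month_roc <- function(probs, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    abort("ROC needs both classes present", class = "recurmine_config_error")
  }
  o <- order(probs, decreasing = TRUE)
  p <- probs[o]
  l <- labels[o]
  n_pos <- sum(l)
  n_neg <- length(l) - n_pos
  tp <- cumsum(l)
  fp <- cumsum(1L - l)
  keep <- !duplicated(p, fromLast = TRUE)  # last row of each tied block
  curve <- tibble(cutoff = c(Inf, p[keep]),
                  fpr = c(0, fp[keep] / n_neg),
                  tpr = c(0, tp[keep] / n_pos))
  auc <- sum(diff(curve$fpr) *
               (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  structure(list(curve = curve, auc = auc), class = "sbce_roc")
}

#' @export
print.sbce_roc <- function(x, ...) {
  cat(sprintf("<sbce_roc> AUC %.3f over %d cutpoints\n",
              x$auc, nrow(x$curve) - 1L))
  invisible(x)
}

#' Diagnostic metrics from a confusion matrix
#'
#' Ratios with a zero denominator are reported as `NA`, not 0.
#'
#' @param tp,fp,tn,fn Confusion-matrix counts.
#' @return One-row tibble with the counts plus `sensitivity`, `specificity`,
#'   `ppv`, `npv`.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = rate(tp, tp + fn),
         specificity = rate(tn, tn + fp),
         ppv = rate(tp, tp + fp),
         npv = rate(tn, tn + fn))
}

#' Person-level diagnostic metrics per threshold
#'
#' @param persons Person-level calls from [threshold_sweep()] (columns
#'   `patient_id`, `threshold`, `predicted_sbce`).
#' @param truth Tibble `patient_id`, `sbce` covering exactly the same
#'   patients.
#' @return Tibble with one row per threshold: counts and
#'   sensitivity/specificity/PPV/NPV.
#' @export
person_metrics <- function(persons, truth) {
  if (!setequal(unique(persons$patient_id), truth$patient_id)) {
    abort("persons and truth cover different patients",
          class = "recurmine_config_error")
  }
  persons %>%
    inner_join(select(truth, "patient_id", "sbce"), by = "patient_id") %>%
    group_by(.data$threshold) %>%
    summarise(confusion_metrics(
      tp = sum(.data$predicted_sbce & .data$sbce),
      fp = sum(.data$predicted_sbce & !.data$sbce),
      tn = sum(!.data$predicted_sbce & !.data$sbce),
      fn = sum(!.data$predicted_sbce & .data$sbce)), .groups = "drop")
}

#' Timing-error summaries per threshold
#'
#' For each threshold, summarises `predicted_month - observed_month` over
#' the correctly predicted event patients (true positives) only. A negative
#' value means the prediction precedes the observed event.
#'
#' @param persons Person-level calls from [threshold_sweep()] (with
#'   `predicted_month`).
#' @param truth Tibble `patient_id`, `sbce`, `sbce_month`.
#' @return Tibble per threshold: `n_correct`, `mean_diff`, `median_diff`,
#'   `min_diff`, `max_diff` (all `NA` when there are no true positives).
#' @export
timing_errors <- function(persons, truth) {
  persons %>%
    inner_join(select(truth, "patient_id", "sbce", "sbce_month"),
               by = "patient_id") %>%
    group_by(.data$threshold) %>%
    summarise({
      tp <- .data$predicted_sbce & .data$sbce
      diffs <- (.data$predicted_month - .data$sbce_month)[tp]
      tibble(n_correct = sum(tp),
             mean_diff = if (length(diffs)) mean(diffs) else NA_real_,
             median_diff = if (length(diffs)) median(diffs) else NA_real_,
             min_diff = if (length(diffs)) min(diffs) else NA_real_,
             max_diff = if (length(diffs)) max(diffs) else NA_real_)
    }, .groups = "drop")
}

survfit_curve <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  s <- summary(fit, censored = TRUE)
  tibble(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
         n_censor = s$n.censor, survival = s$surv)
}

#' Observed versus predicted Kaplan-Meier curves among event patients
#'
#' Builds product-limit curves of (a) the observed event month among the
#' gold-standard event patients (all events) and (b) the predicted event
#' month at the given threshold, censoring patients for whom no event is
#' predicted at their last follow-up month.
#'
#' @param persons Person-level calls from [threshold_sweep()].
#' @param truth Tibble `patient_id`, `sbce`, `sbce_month`, `end_month` (last
#'   follow-up month) for the evaluation patients.
#' @param threshold The threshold at which to take the predicted calls.
#' @return An `sbce_km`: list with `curves` (tibble `curve` in
#'   observed/predicted, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`) and `threshold`.
#' @export
km_pair <- function(persons, truth, threshold = 0.5) {
  cases <- filter(truth, .data$sbce)
  if (nrow(cases) == 0) {
    abort("no event patients to graph", class = "recurmine_config_error")
  }
  calls <- persons %>%
    filter(abs(.data$threshold - .env$threshold) < 1e-9) %>%
    inner_join(cases, by = "patient_id")
  observed <- survfit_curve(cases$sbce_month, rep(1L, nrow(cases)))
  predicted <- survfit_curve(
    ifelse(calls$predicted_sbce, calls$predicted_month, calls$end_month),
    as.integer(calls$predicted_sbce))
  structure(
    list(curves = bind_rows(
      mutate(observed, curve = "observed", .before = 1),
      mutate(predicted, curve = "predicted", .before = 1)),
      threshold = threshold),
    class = "sbce_km")
}

#' @export
print.sbce_km <- function(x, ...) {
  cat(sprintf("<sbce_km> observed vs predicted event-time curves (PT %.2f)\n",
              x$threshold))
  invisible(x)
}

#' Cohort-level Kaplan-Meier curve of time to first event
#'
#' Product-limit estimate of the net probability of a second breast cancer
#' event from diagnosis over the whole cohort, with event-free patients
#' censored at their end of follow-up. Times are expressed in months
#' (days / 30.4375).
#'
#' @param registry Registry tibble.
#' @return An `sbce_km` with a single `cohort` curve.
#' @export
cohort_km <- function(registry) {
  time <- ifelse(registry$sbce, registry$sbce_day,
                 registry$followup_end_day) / AVG_MONTH_DAYS
  curve <- survfit_curve(time, as.integer(registry$sbce))
  structure(list(curves = mutate(curve, curve = "cohort", .before = 1),
                 threshold = NA_real_),
            class = "sbce_km")
}

#' Cumulative event probability from a Kaplan-Meier curve
#'
#' @param km An `sbce_km`.
#' @param t Time (months) at which to read off `1 - S(t)`; the curve is
#'   carried forward flat beyond its last event time.
#' @param curve Which curve to use (default the first).
#' @return A single probability.
#' @export
km_cumulative_incidence <- function(km, t, curve = km$curves$curve[1]) {
  c <- filter(km$curves, .data$curve == .env$curve, .data$time <= t)
  if (nrow(c) == 0) return(0)
  1 - c$survival[nrow(c)]
}

#' Assemble the full evaluation report
#'
#' Combines the month-level ROC/AUC, the per-threshold person-level
#' diagnostic table, the timing-error table, and the observed-versus-
#' predicted Kaplan-Meier pair at `km_threshold`.
#'
#' @param predictions Month-level predictions (tibble `patient_id`,
#'   `month_index`, `label`, `probability`), typically from
#'   [predict_months()] on the test patients.
#' @param truth Tibble `patient_id`, `sbce`, `sbce_month`, `end_month` for
#'   the same patients.
#' @param thresholds Threshold grid.
#' @param timing_method Timing rule, see [predict_event_month()].
#' @param km_threshold Threshold for the KM pair (default 0.5).
#' @return An `sbce_evaluation`: list with `auc`, `roc`, `threshold_table`,
#'   `timing_table`, `km`, `persons`, `timing_method`, `n_patients`,
#'   `n_months`.
#' @export
evaluate_sbce <- function(predictions, truth, thresholds = threshold_grid(),
                          timing_method = c("first_exceed", "max_increase"),
                          km_threshold = 0.5) {
  timing_method <- match.arg(timing_method)
  roc <- month_roc(predictions$probability, predictions$label)
  persons <- threshold_sweep(predictions, thresholds, timing_method)
  structure(
    list(auc = roc$auc, roc = roc,
         threshold_table = person_metrics(persons, truth),
         timing_table = timing_errors(persons, truth),
         km = km_pair(persons, truth, km_threshold),
         persons = persons,
         timing_method = timing_method,
         km_threshold = km_threshold,
         n_patients = nrow(truth),
         n_months = nrow(predictions)),
    class = "sbce_evaluation")
}

#' @export
print.sbce_evaluation <- function(x, ...) {
  cat(sprintf("<sbce_evaluation> %d patients, %d person-months\n",
              x$n_patients, x$n_months))
  cat(sprintf("  month-level AUC: %.3f; timing rule: %s\n",
              x$auc, x$timing_method))
  tab <- tidy(x)
  print(as.data.frame(tab), digits = 3, row.names = FALSE)
  invisible(x)
}

#' @describeIn evaluate_sbce `tidy()` returns the per-threshold table
#'   (diagnostics joined with timing summaries), values rounded to 3
#'   decimals as conventionally reported.
#' @param x An `sbce_evaluation`.
#' @param ... Unused.
#' @method tidy sbce_evaluation
#' @export
tidy.sbce_evaluation <- function(x, ...) {
  x$threshold_table %>%
    inner_join(x$timing_table, by = "threshold") %>%
    mutate(across(c("sensitivity", "specificity", "ppv", "npv"),
                  ~ round(.x, 3)))
}

#' @describeIn evaluate_sbce `glance()` returns a one-row summary.
#' @method glance sbce_evaluation
#' @export
glance.sbce_evaluation <- function(x, ...) {
  at50 <- x$threshold_table[abs(x$threshold_table$threshold - 0.5) < 1e-9, ]
  tibble(auc = x$auc,
         n_patients = x$n_patients,
         n_months = x$n_months,
         sensitivity_50 = if (nrow(at50)) at50$sensitivity else NA_real_,
         specificity_50 = if (nrow(at50)) at50$specificity else NA_real_,
         timing_method = x$timing_method)
}
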