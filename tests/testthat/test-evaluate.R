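# ROC/AUC, person-level diagnostics, timing summaries and Kaplan-Meier.

test_that("trapezoid AUC equals brute-force concordance, including ties", {
  set.seed(70)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    probs <- sample(seq(0, 1, 0.1), n, replace = TRUE) # many ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    roc <- month_roc(probs, labels)
    expect_equal(roc$auc, oracle_auc(probs, labels), tolerance = 1e-12)
  }
})

test_that("perfect separation gives AUC 1 and chance labels give about 0.5", {
  probs <- c(rep(0.9, 20), rep(0.1, 30))
  labels <- rep(c(1, 0), c(20, 30))
  expect_equal(month_roc(probs, labels)$auc, 1.0)
  set.seed(71)
  p <- runif(4000)
  l <- rbinom(4000, 1, 0.3)
  expect_lt(abs(month_roc(p, l)$auc - 0.5), 0.03)
  expect_error(month_roc(p, rep(1, 4000)), class = "recurmine_config_error")
})

test_that("undefined ratios are absent rather than zero", {
  row <- confusion_metrics(tp = 0, fp = 0, tn = 50, fn = 5)
  expect_true(is.na(row$ppv))
  expect_equal(row$specificity, 1.0)
  expect_equal(row$sensitivity, 0)
})

test_that("person metrics and timing summaries work through the sweep", {
  truth <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    sbce = c(TRUE, TRUE, FALSE, FALSE),
    sbce_month = c(8L, 10L, NA, NA),
    end_month = c(12L, 12L, 12L, 12L))
  persons <- tibble::tibble(
    patient_id = rep(c("A", "B", "C", "D"), 2),
    threshold = rep(c(0.3, 0.6), each = 4),
    predicted_sbce = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE),
    predicted_month = c(6L, 12L, 7L, NA, 8L, NA, NA, NA))
  pm <- person_metrics(persons, truth)
  expect_equal(pm$sensitivity, c(1, 0.5))
  expect_equal(pm$specificity, c(0.5, 1))
  te <- timing_errors(persons, truth)
  expect_equal(te$n_correct, c(2L, 1L))
  expect_equal(te$mean_diff, c(0, 0))     # (-2 + 2)/2 and exact hit
  expect_equal(te$min_diff, c(-2, 0))
  expect_equal(te$max_diff, c(2, 0))
  expect_error(person_metrics(persons, truth[1:3, ]),
               class = "recurmine_config_error")
  # no true positives at all -> absent statistics
  none <- persons
  none$predicted_sbce <- FALSE
  none$predicted_month <- NA_integer_
  te0 <- timing_errors(none, truth)
  expect_equal(te0$n_correct, c(0L, 0L))
  expect_true(all(is.na(te0$mean_diff)))
})

test_that("diffs of {-2, 0, 2} summarise to mean 0, median 0, min -2, max 2", {
  truth <- tibble::tibble(patient_id = c("A", "B", "C"), sbce = TRUE,
                          sbce_month = c(10L, 10L, 10L), end_month = 20L)
  persons <- tibble::tibble(patient_id = c("A", "B", "C"), threshold = 0.5,
                            predicted_sbce = TRUE,
                            predicted_month = c(8L, 10L, 12L))
  te <- timing_errors(persons, truth)
  expect_equal(te$mean_diff, 0)
  expect_equal(te$median_diff, 0)
  expect_equal(te$min_diff, -2)
  expect_equal(te$max_diff, 2)
})

test_that("product-limit estimates match the hand computation on a censored fixture", {
  # predicted events at months 5, 8, 8, 12; censored at 6 and 10:
  # S(5) = 5/6, S(8) = 5/6 * 2/4 = 5/12, S(12) = 0
  truth <- tibble::tibble(
    patient_id = sprintf("K%d", 1:6), sbce = TRUE,
    sbce_month = c(5L, 8L, 8L, 12L, 6L, 10L),
    end_month = c(5L, 8L, 8L, 12L, 6L, 10L))
  persons <- tibble::tibble(
    patient_id = truth$patient_id, threshold = 0.5,
    predicted_sbce = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    predicted_month = c(5L, 8L, 8L, 12L, NA, NA))
  km <- km_pair(persons, truth, threshold = 0.5)
  pred <- km$curves[km$curves$curve == "predicted" & km$curves$n_event > 0, ]
  expect_equal(pred$time, c(5, 8, 12))
  expect_equal(pred$survival, c(5 / 6, 5 / 12, 0), tolerance = 1e-12)
})

test_that("without censoring the KM curve equals the empirical survival function", {
  times <- c(4L, 7L, 7L, 9L, 15L)
  truth <- tibble::tibble(patient_id = sprintf("K%d", 1:5), sbce = TRUE,
                          sbce_month = times, end_month = times + 5L)
  persons <- tibble::tibble(patient_id = truth$patient_id, threshold = 0.5,
                            predicted_sbce = TRUE, predicted_month = times)
  km <- km_pair(persons, truth, 0.5)
  for (nm in c("observed", "predicted")) {
    cur <- km$curves[km$curves$curve == nm, ]
    expect_equal(cur$survival, 1 - stats::ecdf(times)(cur$time),
                 tolerance = 1e-12)
  }
  # identical predictions -> identical curves
  obs <- km$curves[km$curves$curve == "observed", -1]
  prd <- km$curves[km$curves$curve == "predicted", -1]
  expect_equal(obs, prd)
  expect_error(km_pair(persons, dplyr::mutate(truth, sbce = FALSE), 0.5),
               class = "recurmine_config_error")
})

test_that("cohort KM handles the all-censored and known-median cases", {
  flat <- make_registry(10, followup_end_day = rep(900L, 10))
  km0 <- cohort_km(flat)
  expect_equal(km_cumulative_incidence(km0, 100), 0)
  # all events, half by month 12: curve crosses 0.5 there
  n <- 20
  reg <- make_registry(n, sbce = rep(TRUE, n),
                       sbce_day = as.integer(round(
                         c(rep(10 * 30.4375, 10), rep(40 * 30.4375, 10)))),
                       followup_end_day = rep(2000L, n))
  km1 <- cohort_km(reg)
  expect_equal(km_cumulative_incidence(km1, 12), 0.5)
  expect_equal(km_cumulative_incidence(km1, 50), 1.0)
})

test_that("the evaluation report satisfies its structural invariants", {
  set.seed(75)
  n_pat <- 30
  truth <- tibble::tibble(
    patient_id = sprintf("E%02d", seq_len(n_pat)),
    sbce = rep(c(TRUE, FALSE), c(8, n_pat - 8)),
    sbce_month = c(sample(8:14, 8, TRUE), rep(NA_integer_, n_pat - 8)),
    end_month = 18L)
  preds <- tidyr::crossing(patient_id = truth$patient_id, month_index = 6:18) %>%
    dplyr::inner_join(truth, by = "patient_id") %>%
    dplyr::mutate(
      label = as.integer(!is.na(sbce_month) & month_index >= sbce_month),
      probability = pmin(pmax(label * 0.7 + runif(dplyr::n(), 0, 0.4), 0), 1)) %>%
    dplyr::select(patient_id, month_index, label, probability)
  rep <- evaluate_sbce(preds, truth)
  tab <- rep$threshold_table
  expect_true(all(tab$tp + tab$fn == sum(truth$sbce)))
  expect_true(all(diff(tab$sensitivity) <= 1e-12))
  expect_true(all(diff(tab$specificity) >= -1e-12))
  expect_true(all(rep$timing_table$n_correct <= tab$tp))
  rates <- c(tab$sensitivity, tab$specificity, tab$ppv, tab$npv)
  expect_true(all(is.na(rates) | (rates >= 0 & rates <= 1)))
  expect_gte(rep$auc, 0)
  expect_lte(rep$auc, 1)
  g <- glance(rep)
  expect_equal(g$n_patients, n_pat)
})
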