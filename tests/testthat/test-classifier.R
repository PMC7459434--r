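# Stratified splitting, tuning, fitting, prediction and importance.

fake_features <- function(df, feature_cols) {
  structure(df, feature_names = feature_cols, group_ids = character(),
            class = c("sbce_features", class(df)))
}

make_flagged_registry <- function(n_neg, n_pos) {
  tibble::tibble(patient_id = sprintf("S%04d", seq_len(n_neg + n_pos)),
                 sbce = rep(c(FALSE, TRUE), c(n_neg, n_pos)))
}

test_that("split sizes follow per-stratum rounding of the fraction", {
  reg <- make_flagged_registry(100, 20)
  plan <- split_cohort(reg, fraction = 0.8, seed = 1)
  ids <- setNames(reg$sbce, reg$patient_id)
  expect_equal(sum(!ids[plan$train_ids]), 80)
  expect_equal(sum(ids[plan$train_ids]), 16)
  expect_equal(sum(!ids[plan$test_ids]), 20)
  expect_equal(sum(ids[plan$test_ids]), 4)
})

test_that("a full-scale 80:20 split reproduces the expected test-set composition", {
  reg <- make_flagged_registry(2698, 394)
  plan <- split_cohort(reg, fraction = 0.8, seed = 9)
  ids <- setNames(reg$sbce, reg$patient_id)
  expect_equal(sum(ids[plan$train_ids]), 315)
  expect_equal(sum(ids[plan$test_ids]), 79)
  expect_equal(sum(!ids[plan$test_ids]), 540)
})

test_that("splits are deterministic, disjoint, and folds partition the train set", {
  reg <- make_flagged_registry(40, 10)
  p1 <- split_cohort(reg, seed = 11)
  p2 <- split_cohort(reg, seed = 11)
  expect_identical(p1, p2)
  expect_length(intersect(p1$train_ids, p1$test_ids), 0)
  expect_setequal(c(p1$train_ids, p1$test_ids), reg$patient_id)
  expect_setequal(p1$folds$patient_id, p1$train_ids)
  expect_equal(anyDuplicated(p1$folds$patient_id), 0)
  expect_setequal(unique(p1$folds$fold), 1:5)
  # row-order invariance of the plan
  p3 <- split_cohort(reg[sample(nrow(reg)), ], seed = 11)
  expect_setequal(p3$train_ids, p1$train_ids)
})

test_that("a stratum smaller than the fold count is an error", {
  reg <- make_flagged_registry(40, 4)
  expect_error(split_cohort(reg, seed = 1), class = "recurmine_config_error")
})

test_that("tuning returns the sole setting of a singleton grid", {
  set.seed(31)
  df <- tibble::tibble(
    patient_id = rep(sprintf("S%03d", 1:40), each = 4),
    month_index = rep(6:9, 40),
    label = rep(rep(c(0L, 1L), 20), each = 4),
    x = rnorm(160))
  feats <- fake_features(df, "x")
  plan <- split_cohort(tibble::tibble(patient_id = sprintf("S%03d", 1:40),
                                      sbce = rep(c(FALSE, TRUE), 20)),
                       seed = 2)
  tuned <- tune_sbce_model(subset_features(feats, plan$train_ids), plan,
                           grid = data.frame(max_depth = 2L, eta = 0.3),
                           nrounds_max = 20, seed = 5)
  expect_equal(tuned$params$max_depth, 2L)
  expect_equal(tuned$params$eta, 0.3)
  expect_gte(tuned$nrounds, 1)
  expect_error(tune_sbce_model(feats, plan, grid = data.frame()[0, ]),
               class = "recurmine_config_error")
})

test_that("tuning prefers deeper trees on an interaction-only (XOR) signal", {
  # label = xor(x1 > 0, x2 > 0): stumps cannot express it, depth-3 trees can
  set.seed(77)
  n_pat <- 200
  pat <- tibble::tibble(
    patient_id = sprintf("S%03d", seq_len(n_pat)),
    x1 = rep(c(-1, -1, 1, 1), n_pat / 4),
    x2 = rep(c(-1, 1, -1, 1), n_pat / 4))
  pat$sbce <- xor(pat$x1 > 0, pat$x2 > 0)
  df <- pat[rep(seq_len(n_pat), each = 3), ]
  df$month_index <- rep(6:8, n_pat)
  df$label <- as.integer(df$sbce)
  df$x1 <- df$x1 + rnorm(nrow(df), sd = 0.05)
  df$x2 <- df$x2 + rnorm(nrow(df), sd = 0.05)
  feats <- fake_features(df[, c("patient_id", "month_index", "label", "x1", "x2")],
                         c("x1", "x2"))
  plan <- split_cohort(pat[, c("patient_id", "sbce")], seed = 3)
  tuned <- tune_sbce_model(subset_features(feats, plan$train_ids), plan,
                           grid = data.frame(max_depth = c(1L, 3L), eta = 0.3),
                           nrounds_max = 40, seed = 5)
  expect_equal(tuned$params$max_depth, 3L)
  aucs <- setNames(tuned$cv$mean_auc, tuned$cv$max_depth)
  expect_gt(aucs[["3"]], aucs[["1"]])
})

test_that("fitting is reproducible and refuses single-class labels", {
  set.seed(8)
  df <- tibble::tibble(patient_id = rep(sprintf("S%03d", 1:30), each = 3),
                       month_index = rep(6:8, 30),
                       label = rep(rbinom(30, 1, 0.5), each = 3),
                       x = rnorm(90), z = rnorm(90))
  feats <- fake_features(df, c("x", "z"))
  m1 <- fit_sbce_model(feats, nrounds = 20, seed = 13)
  m2 <- fit_sbce_model(feats, nrounds = 20, seed = 13)
  expect_equal(predict_months(m1, feats)$probability,
               predict_months(m2, feats)$probability)
  bad <- feats
  bad$label <- 0L
  expect_error(fit_sbce_model(bad, nrounds = 5),
               class = "recurmine_config_error")
})

test_that("month-level permutation of labels yields chance-level discrimination", {
  set.seed(21)
  df <- tibble::tibble(patient_id = rep(sprintf("S%03d", 1:100), each = 10),
                       month_index = rep(6:15, 100),
                       label = sample(rep(c(0L, 1L), c(800, 200))),
                       x = rnorm(1000), z = rnorm(1000), w = rnorm(1000))
  feats <- fake_features(df, c("x", "z", "w"))
  reg <- tibble::tibble(patient_id = sprintf("S%03d", 1:100),
                        sbce = rep(c(FALSE, TRUE), 50))
  plan <- split_cohort(reg, seed = 6)
  m <- fit_sbce_model(subset_features(feats, plan$train_ids),
                      nrounds = 40, seed = 6)
  p <- predict_months(m, subset_features(feats, plan$test_ids))
  auc <- month_roc(p$probability, p$label)$auc
  expect_gt(auc, 0.4)
  expect_lt(auc, 0.6)
})

test_that("predictions lie in [0,1], respect row order, and check feature names", {
  set.seed(14)
  df <- tibble::tibble(patient_id = rep(sprintf("S%03d", 1:20), each = 4),
                       month_index = rep(6:9, 20),
                       label = rep(c(0L, 1L), each = 40),
                       x = rnorm(80))
  feats <- fake_features(df, "x")
  m <- fit_sbce_model(feats, nrounds = 10, seed = 2)
  p <- predict_months(m, feats)
  expect_true(all(p$probability >= 0 & p$probability <= 1))
  rev_feats <- fake_features(df[rev(seq_len(nrow(df))), ], "x")
  p_rev <- predict_months(m, rev_feats)
  merged <- dplyr::inner_join(p, p_rev, by = c("patient_id", "month_index"))
  expect_equal(merged$probability.x, merged$probability.y)
  wrong <- fake_features(dplyr::rename(df, y = "x"), "y")
  expect_error(predict_months(m, wrong), class = "recurmine_schema_error")
  # empty input -> empty output
  empty <- fake_features(df[0, ], "x")
  expect_equal(nrow(predict_months(m, empty)), 0)
})

test_that("importance ranks the planted signal first and sorts nonincreasing", {
  set.seed(9)
  n <- 400
  df <- tibble::tibble(patient_id = rep(sprintf("S%03d", 1:100), each = 4),
                       month_index = rep(6:9, 100),
                       signal = rep(c(0, 3), each = n / 2) + rnorm(n, sd = 0.3),
                       noise1 = rnorm(n), noise2 = rnorm(n))
  df$label <- rep(c(0L, 1L), each = n / 2)
  feats <- fake_features(df, c("signal", "noise1", "noise2"))
  m <- fit_sbce_model(feats, nrounds = 30, seed = 3)
  top <- feature_importance(m, top_k = 1)
  expect_equal(top$feature, "signal")
  all_imp <- feature_importance(m, top_k = 100)
  expect_equal(nrow(all_imp), 3)
  expect_true(all(diff(all_imp$importance) <= 0))
  expect_equal(tidy(m), all_imp)
})
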