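# Person-month feature matrix and post-event labels.
#
# Each in-window person-month becomes one classification row. The label is 1
# from the event month onward (the method is retrospective: the entire
# claims record, including months after the candidate event, is available at
# prediction time, so "until next occurrence" features do not leak beyond
# the method's own design).

#' Label person-months as pre- or post-event
#'
#' A month is post-event (label 1) if and only if its index is at or after
#' the patient's event month; all months of event-free patients are 0.
#' Within a patient labels are nondecreasing in month.
#'
#' @param panel A `month_panel` from [build_month_panel()].
#' @return A tibble of `patient_id`, `month_index`, `label` covering every
#'   in-window person-month.
#' @export
label_months <- function(panel) {
  w <- panel$windows
  bad <- !is.na(w$sbce_month) &
    (w$sbce_month < w$start_month | w$sbce_month > w$end_month)
  if (any(bad)) {
    abort(sprintf(
      "event month outside valid window for %s (should have been excluded upstream)",
      paste(w$patient_id[bad], collapse = ", ")),
      class = "recurmine_config_error")
  }
  w %>%
    mutate(month_index = purrr::map2(.data$start_month, .data$end_month, seq)) %>%
    select("patient_id", "month_index", "sbce_month") %>%
    tidyr::unnest("month_index") %>%
    mutate(label = as.integer(!is.na(.data$sbce_month) &
                                .data$month_index >= .data$sbce_month)) %>%
    select("patient_id", "month_index", "label")
}

#' Temporal features of one code-group count series
#'
#' Given the monthly counts of one code group over one patient's contiguous
#' valid window, computes for each month: the count in that month; the
#' number of months since the last *prior* in-window occurrence (-1 when
#' none); the number of months until the next *later* in-window occurrence
#' (-1 when none; the current month never feeds since/until); and the
#' fraction of prior in-window months containing at least one occurrence
#' (0 for the window's first month).
#'
#' @param counts Integer vector of monthly counts over the window, in month
#'   order.
#' @return A tibble with columns `count`, `since`, `until`, `frac` and one
#'   row per month.
#' @export
temporal_features <- function(counts) {
  n <- length(counts)
  occ <- counts > 0
  idx <- seq_len(n)
  last_occ <- cummax(ifelse(occ, idx, 0L))
  prior_last <- c(0L, last_occ[-n])
  since <- ifelse(prior_last == 0L, -1L, idx - prior_last)
  next_occ <- rev(cummin(rev(ifelse(occ, idx, n + 1L))))
  nxt <- c(next_occ[-1], n + 1L)
  until <- ifelse(nxt == n + 1L, -1L, nxt - idx)
  prior_occ <- c(0L, cumsum(occ)[-n])
  frac <- ifelse(idx == 1L, 0, prior_occ / (idx - 1L))
  tibble(count = as.integer(counts), since = as.integer(since),
         until = as.integer(until), frac = frac)
}

one_hot <- function(x, var) {
  x <- as.character(x)
  levels <- sort(unique(x))
  cols <- lapply(levels, function(l) as.integer(x == l))
  names(cols) <- paste0(var, "_", make.names(levels))
  as_tibble(cols)
}

#' Build the person-month feature matrix
#'
#' Assembles one row per in-window person-month with: one-hot-encoded
#' baseline registry variables (stage, grade, ER/PR status, site), months
#' since diagnosis, the patient's age in the month, and per code group the
#' four temporal features of [temporal_features()]. With `G` code groups and
#' `R` encoded registry columns the matrix has `R + 2 + 4 G` predictors.
#'
#' @param panel A `month_panel` from [build_month_panel()].
#' @param registry Registry tibble covering the panel's patients.
#' @param include_diagnosis_year Also include the diagnosis calendar year as
#'   a predictor (default `FALSE`).
#' @return An `sbce_features` tibble: `patient_id`, `month_index`, `label`,
#'   then predictors; attributes `feature_names` (ordered predictor names)
#'   and `group_ids`.
#' @export
build_feature_matrix <- function(panel, registry, include_diagnosis_year = FALSE) {
  labels <- label_months(panel)
  group_ids <- panel$groups$group_id

  grid <- labels %>%
    select("patient_id", "month_index") %>%
    tidyr::crossing(group_id = group_ids)
  long <- grid %>%
    left_join(panel$counts, by = c("patient_id", "month_index", "group_id")) %>%
    mutate(count = tidyr::replace_na(.data$count, 0L)) %>%
    arrange(.data$patient_id, .data$group_id, .data$month_index) %>%
    group_by(.data$patient_id, .data$group_id) %>%
    mutate(temporal_features(.data$count)) %>%
    ungroup()

  wide <- long %>%
    tidyr::pivot_wider(
      id_cols = c("patient_id", "month_index"),
      names_from = "group_id",
      values_from = c("count", "since", "until", "frac"),
      names_glue = "{.value}_{group_id}"
    )
  # deterministic group-major column order: all four features per group
  temporal_cols <- as.vector(t(outer(
    group_ids, c("count", "since", "until", "frac"),
    function(g, f) paste0(f, "_", g))))
  wide <- select(wide, "patient_id", "month_index", all_of(temporal_cols))

  reg_vars <- c("stage", "grade", "er_status", "pr_status", "site")
  reg_hot <- dplyr::bind_cols(
    select(registry, "patient_id", "age_at_diagnosis"),
    purrr::map2_dfc(reg_vars, reg_vars,
                    function(v, nm) one_hot(registry[[v]], nm))
  )
  if (include_diagnosis_year) {
    reg_hot$diagnosis_year <- as.numeric(registry$diagnosis_year)
  }

  out <- labels %>%
    inner_join(reg_hot, by = "patient_id") %>%
    mutate(months_since_diagnosis = .data$month_index,
           age_in_month = .data$age_at_diagnosis + .data$month_index / 12) %>%
    select(-"age_at_diagnosis") %>%
    inner_join(wide, by = c("patient_id", "month_index")) %>%
    arrange(.data$patient_id, .data$month_index)

  feature_names <- setdiff(names(out), c("patient_id", "month_index", "label"))
  structure(out,
            feature_names = feature_names,
            group_ids = group_ids,
            class = c("sbce_features", class(out)))
}

#' Restrict a feature matrix to a set of patients
#'
#' Plain row filtering would drop the stored feature metadata; this keeps
#' the `feature_names` / `group_ids` attributes intact.
#'
#' @param features An `sbce_features` tibble.
#' @param ids Patient identifiers to keep.
#' @return An `sbce_features` tibble.
#' @export
subset_features <- function(features, ids) {
  out <- features[features$patient_id %in% ids, , drop = FALSE]
  structure(out,
            feature_names = attr(features, "feature_names"),
            group_ids = attr(features, "group_ids"),
            class = class(features))
}

feature_matrix_of <- function(features) {
  fn <- attr(features, "feature_names")
  m <- as.matrix(as.data.frame(features)[, fn, drop = FALSE])
  storage.mode(m) <- "double"
  m
}
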