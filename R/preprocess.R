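# Valid-claims windows, eligibility filters, daily deduplication, the
# rare-code filter, code grouping and monthly aggregation.

AVG_MONTH_DAYS <- 30.4375

# Calendar month index of `day` (days since diagnosis) relative to each
# patient's diagnosis month; day and dx_date are parallel vectors.
month_index_calendar <- function(day, dx_date) {
  d <- dx_date + day
  12L * (as.integer(format(d, "%Y")) - as.integer(format(dx_date, "%Y"))) +
    (as.integer(format(d, "%m")) - as.integer(format(dx_date, "%m")))
}

month_index_relative <- function(day) {
  as.integer(floor(day / AVG_MONTH_DAYS))
}

month_index_of <- function(day, dx_date, bin_mode) {
  if (bin_mode == "relative") month_index_relative(day)
  else month_index_calendar(day, dx_date)
}

# First day (days since diagnosis) strictly after the 6-month anniversary.
first_valid_day <- function(dx_date, bin_mode) {
  if (bin_mode == "relative") return(rep(183L, length(dx_date)))
  anniv <- lubridate::`%m+%`(dx_date, lubridate::period(6, "months"))
  as.integer(anniv - dx_date) + 1L
}

#' Assign each patient's valid-claims window
#'
#' The analysis interval starts 6 months after the primary diagnosis and
#' runs to the end of follow-up, truncated 3 months before any non-breast
#' second primary and 1 month before any second breast cancer event. All
#' arithmetic on the truncation offsets is done in month indices. The start
#' month is the calendar month containing the 6-month anniversary (index 6);
#' claims earlier in that month than the anniversary itself are excluded at
#' day level by [build_month_panel()].
#'
#' @param registry A validated registry tibble (jittered when
#'   `bin_mode = "calendar"`; see [jitter_diagnosis_dates()]).
#' @param bin_mode `"calendar"` (default) bins by calendar month via the
#'   jittered diagnosis date; `"relative"` bins by 30.4375-day months since
#'   diagnosis and needs no jitter.
#' @return A tibble with `patient_id`, `start_month`, `end_month`,
#'   `sbce_month` (`NA` for non-event patients), `valid_from_day`, and
#'   `eligible` (`FALSE` when the window is empty, i.e.
#'   `end_month < start_month`).
#' @export
assign_valid_windows <- function(registry, bin_mode = c("calendar", "relative")) {
  bin_mode <- match.arg(bin_mode)
  dx_date <- if (bin_mode == "calendar") diagnosis_dates(registry) else
    rep(as.Date("2001-01-01"), nrow(registry))
  m_of <- function(day) {
    out <- rep(NA_integer_, length(day))
    ok <- !is.na(day)
    out[ok] <- month_index_of(day[ok], dx_date[ok], bin_mode)
    out
  }
  end_fu <- m_of(registry$followup_end_day)
  end_nb <- if ("nonbreast_primary_day" %in% names(registry))
    m_of(registry$nonbreast_primary_day) - 3L else rep(NA_integer_, nrow(registry))
  end_s2 <- if ("second_sbce_day" %in% names(registry))
    m_of(registry$second_sbce_day) - 1L else rep(NA_integer_, nrow(registry))
  end_month <- pmin(end_fu, end_nb, end_s2, na.rm = TRUE)
  tibble(
    patient_id = registry$patient_id,
    start_month = 6L,
    end_month = as.integer(end_month),
    sbce_month = m_of(registry$sbce_day),
    valid_from_day = first_valid_day(dx_date, bin_mode),
    eligible = end_month >= 6L
  )
}

#' Apply cohort eligibility filters
#'
#' Drops patients with an empty valid-claims window, patients with no valid
#' claims inside their window, event patients with no claims on or after
#' their event day (their event is invisible to a claims-based method), and
#' event patients whose event month falls outside the valid window. Nothing
#' is dropped silently: every exclusion is logged with a reason.
#'
#' @param registry Registry tibble.
#' @param windows Window tibble from [assign_valid_windows()].
#' @param claims Claims tibble (deduplication not required).
#' @param bin_mode See [assign_valid_windows()].
#' @return A list with `registry` and `windows` (retained patients, same
#'   schemas) and `exclusions`, a tibble of `patient_id`, `reason`.
#' @export
filter_eligible <- function(registry, windows, claims,
                            bin_mode = c("calendar", "relative")) {
  bin_mode <- match.arg(bin_mode)
  w <- windows
  dx_date <- if (bin_mode == "calendar") diagnosis_dates(registry) else
    rep(as.Date("2001-01-01"), nrow(registry))
  anchors <- tibble(patient_id = registry$patient_id, dx_date = dx_date)
  in_window <- claims %>%
    inner_join(anchors, by = "patient_id") %>%
    inner_join(w, by = "patient_id") %>%
    mutate(month_index = month_index_of(.data$day, .data$dx_date, bin_mode)) %>%
    filter(.data$day >= .data$valid_from_day,
           .data$month_index >= .data$start_month,
           .data$month_index <= .data$end_month) %>%
    distinct(.data$patient_id)
  post_event <- claims %>%
    inner_join(select(registry, "patient_id", "sbce_day"), by = "patient_id") %>%
    filter(!is.na(.data$sbce_day), .data$day >= .data$sbce_day) %>%
    distinct(.data$patient_id)

  reason <- rep(NA_character_, nrow(w))
  reason[!w$eligible] <- "empty_window"
  sb <- !is.na(w$sbce_month)
  reason[is.na(reason) & sb & w$sbce_month < w$start_month] <- "event_before_window"
  reason[is.na(reason) & sb & w$sbce_month > w$end_month] <- "event_after_window"
  reason[is.na(reason) & !w$patient_id %in% in_window$patient_id] <-
    "no_claims_in_window"
  reason[is.na(reason) & sb & !w$patient_id %in% post_event$patient_id] <-
    "no_post_event_claims"

  keep <- is.na(reason)
  list(
    registry = semi_join(registry, w[keep, ], by = "patient_id"),
    windows = w[keep, ],
    exclusions = tibble(patient_id = w$patient_id[!keep], reason = reason[!keep])
  )
}

#' Consolidate claims to at most one per code per day
#'
#' For each (patient, day, system, code) at most one event survives. The
#' result is independent of input order and the operation is idempotent.
#'
#' @param claims Claims tibble.
#' @return Deduplicated claims tibble, ordered by patient, day, code.
#' @export
dedupe_daily <- function(claims) {
  claims %>%
    distinct(.data$patient_id, .data$day, .data$system, .data$code,
             .data$code_class) %>%
    arrange(.data$patient_id, .data$day, .data$system, .data$code)
}

#' Drop diagnosis codes never repeated for any single patient
#'
#' A diagnosis code is retained if and only if at least one patient has it
#' on at least two separate days; retained codes keep all their events for
#' all patients. One-off diagnosis codes are mostly noise (rule-outs,
#' miscodings) and cannot support the temporal recurrence features. The rule
#' applies to diagnosis codes only by default.
#'
#' @param claims Deduplicated claims tibble (see [dedupe_daily()]).
#' @param include_procedures Also apply the rule to procedure codes
#'   (default `FALSE`).
#' @return A list with `claims` (retained events) and `dropped_codes`
#'   (tibble of `code`, `code_class`).
#' @export
filter_rare_codes <- function(claims, include_procedures = FALSE) {
  scope <- if (include_procedures) CODE_CLASSES else "diagnosis"
  in_scope <- filter(claims, .data$code_class %in% scope)
  if (nrow(in_scope) == 0) {
    return(list(claims = claims,
                dropped_codes = tibble(code = character(),
                                       code_class = character())))
  }
  reps <- in_scope %>%
    distinct(.data$code, .data$code_class, .data$patient_id, .data$day) %>%
    count(.data$code, .data$code_class, .data$patient_id) %>%
    group_by(.data$code, .data$code_class) %>%
    summarise(max_days = max(.data$n), .groups = "drop")
  dropped <- reps %>%
    filter(.data$max_days < 2) %>%
    select("code", "code_class")
  list(
    claims = anti_join(claims, dropped, by = c("code", "code_class")),
    dropped_codes = dropped
  )
}

#' Build the per-patient monthly code-group count panel
#'
#' Maps each surviving claim to its code group and calendar month, discards
#' claims outside the patient's valid window, and sums counts per
#' (patient, month, group). Codes absent from the group map are dropped
#' with a logged count (real inputs always contain codes the map does not
#' cover).
#'
#' @param claims Deduplicated, rare-filtered claims tibble.
#' @param registry Registry tibble (jittered when `bin_mode = "calendar"`).
#' @param windows Window tibble from [assign_valid_windows()].
#' @param groupmap Code-group map tibble.
#' @param bin_mode See [assign_valid_windows()].
#' @return A `month_panel` object: a list with `counts` (tibble
#'   `patient_id`, `month_index`, `group_id`, `count`), `windows` (eligible
#'   patients only), `groups` (tibble `group_id`, `code_class`, fixed
#'   ordering), and `n_unmapped` (dropped claim count).
#' @export
build_month_panel <- function(claims, registry, windows, groupmap,
                              bin_mode = c("calendar", "relative")) {
  bin_mode <- match.arg(bin_mode)
  if (nrow(groupmap) == 0) {
    abort("code-group map is empty", class = "recurmine_config_error")
  }
  mapped <- claims %>%
    inner_join(select(groupmap, "code", "group_id"), by = "code")
  n_unmapped <- nrow(claims) - nrow(mapped)

  dx_date <- if (bin_mode == "calendar") diagnosis_dates(registry) else
    rep(as.Date("2001-01-01"), nrow(registry))
  anchors <- tibble(patient_id = registry$patient_id, dx_date = dx_date)

  in_window <- mapped %>%
    inner_join(anchors, by = "patient_id") %>%
    inner_join(select(windows, "patient_id", "start_month", "end_month",
                      "valid_from_day"), by = "patient_id") %>%
    mutate(month_index = month_index_of(.data$day, .data$dx_date, bin_mode)) %>%
    filter(.data$day >= .data$valid_from_day,
           .data$month_index >= .data$start_month,
           .data$month_index <= .data$end_month)

  counts <- in_window %>%
    count(.data$patient_id, .data$month_index, .data$group_id, name = "count") %>%
    arrange(.data$patient_id, .data$month_index, .data$group_id)

  groups <- groupmap %>%
    distinct(.data$group_id, .data$code_class) %>%
    arrange(.data$code_class, .data$group_id)

  structure(
    list(counts = counts,
         windows = filter(windows, .data$eligible),
         groups = groups,
         n_unmapped = n_unmapped),
    class = "month_panel"
  )
}

#' @export
print.month_panel <- function(x, ...) {
  cat(sprintf(
    "<month_panel> %d patients, %d code groups (%d diagnosis, %d procedure)\n",
    nrow(x$windows), nrow(x$groups),
    sum(x$groups$code_class == "diagnosis"),
    sum(x$groups$code_class == "procedure")))
  cat(sprintf("  %d nonzero (patient, month, group) counts; %d unmapped claims dropped\n",
              nrow(x$counts), x$n_unmapped))
  invisible(x)
}
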