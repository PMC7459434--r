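# Synthetic cohort simulator.
#
# Generates registry records plus day-level claims histories with the
# statistical structure the detection method assumes: a discrete-time
# (monthly) event hazard modulated by baseline covariates, follow-up
# durations calibrated to realistic claim-month summaries, per-group
# monthly Poisson claim counts, and an intensity shift around the event
# month (a short pre-event diagnostic-workup bump on procedure groups and a
# geometrically decaying post-event treatment signature on the signal
# groups).

#' Simulator configuration
#'
#' Defaults encode the study conditions the package is calibrated to: a net
#' (Kaplan-Meier) cumulative event probability of 0.25 by month 168
#' (14 years), modulated upward for stage II, ER-negative, PR-negative and
#' grade 3 disease; follow-up windows whose claim-month counts average
#' about 31.5 (SD ~19) months among event-free patients; 8 diagnosis and 8
#' procedure code groups with 3 codes each; and an event signature on four
#' low-baseline signal groups (pre-event workup bump: multiplier 3 over the
#' 2 months before the event on the procedure signal groups; post-event
#' multiplier 8 decaying geometrically back toward baseline).
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed; one seed governs every draw.
#' @param sbce_cumulative_target Net cumulative event probability by
#'   `horizon_months`.
#' @param horizon_months Hazard horizon (months since diagnosis).
#' @param hazard_shape,hazard_scale Gamma-density weights giving the hazard
#'   its time profile (default peaks around month 20, as recurrence risk
#'   peaks 1-3 years after diagnosis, then declines).
#' @param hazard_multipliers Named multiplicative hazard effects
#'   (`stage_II`, `er_negative`, `pr_negative`, `grade_3`).
#' @param covariate_probs Named list of covariate distributions.
#' @param followup_mean,followup_sd,followup_min,followup_max Gamma model
#'   (months beyond the analysis start month) for the end of follow-up.
#' @param dx_rates,px_rates Baseline monthly Poisson rates per diagnosis /
#'   procedure group; the last two of each are the event-signal groups.
#' @param codes_per_group Number of distinct codes per group.
#' @param pre_window,pre_multiplier Pre-event workup bump (months before
#'   the event month; applied to procedure signal groups).
#' @param post_multiplier,post_decay Post-event intensity multiplier at the
#'   event month and its geometric decay per month
#'   (`1 + (post_multiplier - 1) * post_decay^(m - event_month)`).
#'   `pre_multiplier = post_multiplier = 1` gives a null cohort with no
#'   event signature in the claims.
#' @param second_sbce_prob,nonbreast_prob Probabilities of a second breast
#'   event (among event patients) and of a non-breast second primary.
#' @param diagnosis_years Calendar years to draw diagnoses from.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 600,
                       seed = 1,
                       sbce_cumulative_target = 0.25,
                       horizon_months = 168,
                       hazard_shape = 2,
                       hazard_scale = 20,
                       hazard_multipliers = c(stage_II = 1.8, er_negative = 1.6,
                                              pr_negative = 1.4, grade_3 = 1.3),
                       covariate_probs = list(
                         stage_II = 0.35,
                         er = c(positive = 0.80, negative = 0.15, unknown = 0.05),
                         pr = c(positive = 0.70, negative = 0.25, unknown = 0.05),
                         grade = c(`1` = 0.25, `2` = 0.45, `3` = 0.30),
                         site = c(ductal = 0.70, lobular = 0.20, other = 0.10)),
                       followup_mean = 30.5,
                       followup_sd = 19.2,
                       followup_min = 1,
                       followup_max = 153,
                       dx_rates = c(0.80, 0.50, 0.35, 0.25, 0.18, 0.14, 0.10, 0.08),
                       px_rates = c(0.60, 0.40, 0.30, 0.22, 0.15, 0.12, 0.10, 0.08),
                       codes_per_group = 3,
                       pre_window = 2,
                       pre_multiplier = 3,
                       post_multiplier = 8,
                       post_decay = 0.93,
                       second_sbce_prob = 0.08,
                       nonbreast_prob = 0.03,
                       diagnosis_years = 1993:2006) {
  cfg <- as.list(environment())
  if (any(c(dx_rates, px_rates) < 0)) {
    abort("claim rates must be nonnegative", class = "recurmine_config_error")
  }
  if (sbce_cumulative_target <= 0 || sbce_cumulative_target >= 1) {
    abort("cumulative target must be in (0, 1)", class = "recurmine_config_error")
  }
  structure(cfg, class = "sim_config")
}

# Events cannot occur before the analysis start month.
HAZARD_START_MONTH <- 7L

# Hazard time weights, normalised to mean 1 over the hazard months.
hazard_weights <- function(config) {
  m <- HAZARD_START_MONTH:config$horizon_months
  w <- stats::dgamma(m, shape = config$hazard_shape, scale = config$hazard_scale)
  w / mean(w)
}

# Joint covariate combinations with probabilities and hazard multipliers.
covariate_combos <- function(config) {
  cp <- config$covariate_probs
  hm <- config$hazard_multipliers
  combos <- expand.grid(
    stage = c("I", "II"), er = names(cp$er), pr = names(cp$pr),
    grade = names(cp$grade), stringsAsFactors = FALSE)
  combos$prob <-
    ifelse(combos$stage == "II", cp$stage_II, 1 - cp$stage_II) *
    cp$er[combos$er] * cp$pr[combos$pr] * cp$grade[combos$grade]
  combos$mult <-
    ifelse(combos$stage == "II", hm[["stage_II"]], 1) *
    ifelse(combos$er == "negative", hm[["er_negative"]], 1) *
    ifelse(combos$pr == "negative", hm[["pr_negative"]], 1) *
    ifelse(combos$grade == "3", hm[["grade_3"]], 1)
  combos
}

#' Calibrate the baseline monthly hazard
#'
#' Solves for the baseline hazard scale such that the population-averaged
#' cumulative event probability by the horizon equals the configured
#' target, averaging exactly over the joint covariate distribution.
#'
#' @param config A [sim_config()].
#' @return The baseline hazard scale (a single positive number).
#' @export
calibrate_hazard <- function(config) {
  w <- hazard_weights(config)
  combos <- covariate_combos(config)
  cum_at <- function(h0) {
    per <- vapply(combos$mult, function(r) {
      1 - prod(1 - h0 * w * r)
    }, 1.0)
    sum(combos$prob * per)
  }
  # a monthly event hazard above 0.2 is outside any meaningful regime for
  # this disease; cap the peak (highest-risk combo, peak month) there
  upper <- 0.2 / (max(w) * max(combos$mult))
  if (cum_at(upper) < config$sbce_cumulative_target) {
    abort(sprintf(
      "cumulative target %.3f unreachable under the configured hazard shape and horizon",
      config$sbce_cumulative_target), class = "recurmine_config_error")
  }
  uniroot(function(h0) cum_at(h0) - config$sbce_cumulative_target,
          c(1e-9, upper), tol = 1e-12)$root
}

# First day-since-diagnosis of calendar month `m` (clamped to >= 0) and the
# month's length, given diagnosis dates. Pure integer month arithmetic.
month_day_bounds <- function(dx_date, m) {
  y0 <- as.integer(format(dx_date, "%Y"))
  m0 <- as.integer(format(dx_date, "%m"))
  total <- y0 * 12L + (m0 - 1L) + m
  start <- as.Date(sprintf("%d-%02d-01", total %/% 12L, total %% 12L + 1L))
  total1 <- total + 1L
  nxt <- as.Date(sprintf("%d-%02d-01", total1 %/% 12L, total1 %% 12L + 1L))
  list(first = pmax(0L, as.integer(start - dx_date)),
       last = as.integer(nxt - dx_date) - 1L)
}

#' Simulate a synthetic cohort
#'
#' Draws covariates, event months from the calibrated discrete hazard,
#' follow-up ends, and per-group monthly claim counts with the event
#' signature applied, then expands counts to day-level coded claim events so
#' the full preprocessing path is exercised. Deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An `sbce_cohort`: list with `registry`, `claims`, `groupmap`
#'   (tibbles in the cohort schemas) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  h0 <- calibrate_hazard(config)
  w <- hazard_weights(config)
  n <- config$n_patients
  n_dx <- length(config$dx_rates)
  n_px <- length(config$px_rates)
  groups <- c(sprintf("dxg%02d", seq_len(n_dx)), sprintf("pxg%02d", seq_len(n_px)))
  g_class <- rep(c("diagnosis", "procedure"), c(n_dx, n_px))
  base_rate <- c(config$dx_rates, config$px_rates)
  sig_dx <- if (n_dx >= 2) groups[(n_dx - 1):n_dx] else groups[n_dx]
  sig_px <- if (n_px >= 2) groups[n_dx + ((n_px - 1):n_px)] else groups[n_dx + n_px]
  signal_groups <- c(sig_dx, sig_px)

  groupmap <- tibble(
    group_id = rep(groups, each = config$codes_per_group),
    code_class = rep(g_class, each = config$codes_per_group),
    k = rep(seq_len(config$codes_per_group), n_dx + n_px)) %>%
    mutate(code = sprintf("%s_c%d", .data$group_id, .data$k),
           system = ifelse(.data$code_class == "diagnosis", "ICD9CM",
                           ifelse(.data$k == config$codes_per_group, "HCPCS", "CPT"))) %>%
    select("code", "group_id", "code_class", "system")

  cohort <- with_seed(config$seed, {
    cp <- config$covariate_probs
    draw_cat <- function(p) sample(names(p), n, replace = TRUE, prob = p)
    registry <- tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      age_at_diagnosis = floor(runif(n, 30, 85)),
      stage = ifelse(runif(n) < cp$stage_II, "II", "I"),
      grade = draw_cat(cp$grade),
      er_status = draw_cat(cp$er),
      pr_status = draw_cat(cp$pr),
      site = draw_cat(cp$site),
      diagnosis_year = sample(config$diagnosis_years, n, replace = TRUE)
    )
    hm <- config$hazard_multipliers
    mult <- ifelse(registry$stage == "II", hm[["stage_II"]], 1) *
      ifelse(registry$er_status == "negative", hm[["er_negative"]], 1) *
      ifelse(registry$pr_status == "negative", hm[["pr_negative"]], 1) *
      ifelse(registry$grade == "3", hm[["grade_3"]], 1)

    # latent event month from the discrete hazard (NA = none by horizon)
    hmat <- pmin(outer(w * h0, mult), 0.99)        # months x patients
    cum_inc <- 1 - apply(1 - hmat, 2, cumprod)
    u <- runif(n)
    latent <- apply(cum_inc >= rep(u, each = nrow(cum_inc)), 2, function(z) {
      i <- which(z)[1]
      if (is.na(i)) NA_integer_ else HAZARD_START_MONTH + i - 1L
    })

    fu_shape <- (config$followup_mean / config$followup_sd)^2
    fu_scale <- config$followup_sd^2 / config$followup_mean
    window_len <- pmin(pmax(round(rgamma(n, shape = fu_shape, scale = fu_scale)),
                            config$followup_min), config$followup_max)
    end_month <- 6L + as.integer(window_len)

    sbce <- !is.na(latent) & latent <= end_month
    sbce_month <- ifelse(sbce, latent, NA_integer_)

    second_month <- rep(NA_integer_, n)
    has2 <- sbce & runif(n) < config$second_sbce_prob
    second_month[has2] <- sbce_month[has2] + 2L + rpois(sum(has2), 8)

    nonbreast_month <- rep(NA_integer_, n)
    hasnb <- runif(n) < config$nonbreast_prob
    nonbreast_month[hasnb] <- 10L + as.integer(floor(runif(sum(hasnb)) * 160))

    # calendar jitter: uniform day of the diagnosis year
    year_start <- as.Date(sprintf("%d-01-01", registry$diagnosis_year))
    ndays <- as.integer(as.Date(sprintf("%d-01-01", registry$diagnosis_year + 1L)) -
                          year_start)
    doy <- floor(runif(n) * ndays)
    dx_date <- year_start + doy
    registry$diagnosis_month <- as.integer(format(dx_date, "%m"))
    registry$diagnosis_dom <- as.integer(format(dx_date, "%d"))
    registry$age_at_diagnosis <- registry$age_at_diagnosis + doy / ndays

    day_in_month <- function(idx, m, frac) {
      b <- month_day_bounds(dx_date[idx], m)
      b$first + pmin(floor(frac * (b$last - b$first + 1L)),
                     b$last - b$first)
    }
    sbce_day <- rep(NA_integer_, n)
    sbce_day[sbce] <- as.integer(day_in_month(sbce, sbce_month[sbce],
                                              runif(sum(sbce))))
    second_day <- rep(NA_integer_, n)
    second_day[has2] <- as.integer(day_in_month(has2, second_month[has2], 0.5))
    nonbreast_day <- rep(NA_integer_, n)
    nonbreast_day[hasnb] <- as.integer(day_in_month(hasnb,
                                                    nonbreast_month[hasnb], 0.5))
    fu_bounds <- month_day_bounds(dx_date, end_month)
    registry$sbce <- sbce
    registry$sbce_day <- sbce_day
    registry$second_sbce_day <- second_day
    registry$nonbreast_primary_day <- nonbreast_day
    registry$followup_end_day <- fu_bounds$last

    # monthly counts: long grid of (patient, month, group)
    n_months <- end_month + 1L
    pid_m <- rep(seq_len(n), n_months)
    month_m <- sequence(n_months) - 1L
    ncell <- length(pid_m)
    gidx <- rep(seq_along(groups), times = ncell)
    pid <- rep(pid_m, each = length(groups))
    month <- rep(month_m, each = length(groups))

    rate <- base_rate[gidx]
    ev <- sbce_month[pid]
    is_sig <- groups[gidx] %in% signal_groups
    is_sig_px <- groups[gidx] %in% sig_px
    pre <- !is.na(ev) & is_sig_px & month >= ev - config$pre_window & month < ev
    post <- !is.na(ev) & is_sig & month >= ev
    rate[pre] <- rate[pre] * config$pre_multiplier
    rate[post] <- rate[post] *
      (1 + (config$post_multiplier - 1) * config$post_decay^(month[post] - ev[post]))
    counts <- rpois(length(rate), rate)

    nz <- counts > 0L
    cell_pid <- pid[nz]
    cell_month <- month[nz]
    cell_gidx <- gidx[nz]
    cell_n <- counts[nz]
    ev_pid <- rep.int(cell_pid, cell_n)
    ev_month <- rep.int(cell_month, cell_n)
    ev_gidx <- rep.int(cell_gidx, cell_n)
    b <- month_day_bounds(dx_date[ev_pid], ev_month)
    span <- b$last - b$first + 1L
    ev_day <- b$first + pmin(as.integer(floor(runif(length(ev_pid)) * span)),
                             span - 1L)
    ev_code_k <- 1L + as.integer(floor(runif(length(ev_pid)) * config$codes_per_group))
    claims <- tibble(
      patient_id = registry$patient_id[ev_pid],
      day = ev_day,
      group_id = groups[ev_gidx],
      code = sprintf("%s_c%d", groups[ev_gidx], ev_code_k),
      code_class = g_class[ev_gidx],
      system = ifelse(g_class[ev_gidx] == "diagnosis", "ICD9CM",
                      ifelse(ev_code_k == config$codes_per_group, "HCPCS", "CPT"))
    ) %>%
      select("patient_id", "day", "system", "code", "code_class") %>%
      arrange(.data$patient_id, .data$day, .data$code)
    list(registry = registry, claims = claims)
  })

  structure(list(registry = cohort$registry,
                 claims = cohort$claims,
                 groupmap = select(groupmap, "code", "group_id", "code_class"),
                 signal_groups = signal_groups,
                 config = config),
            class = "sbce_cohort")
}

#' @export
print.sbce_cohort <- function(x, ...) {
  cat(sprintf("<sbce_cohort> %d patients (%d with an event), %d claim lines\n",
              nrow(x$registry), sum(x$registry$sbce), nrow(x$claims)))
  invisible(x)
}

#' Summarise a cohort the way study cohorts are reported
#'
#' Reports, per event stratum, the number of patients and the distribution
#' of claim-months (months in the valid window with at least one valid
#' claim): mean, median, SD, minimum and maximum; plus the event fraction
#' and unique code counts per class.
#'
#' @param registry Registry tibble (jittered when `bin_mode = "calendar"`).
#' @param claims Claims tibble.
#' @param bin_mode See [assign_valid_windows()].
#' @return List with `strata` (tibble, one row per stratum), `sbce_fraction`
#'   and `codes` (tibble of unique code counts by class).
#' @export
describe_cohort <- function(registry, claims, bin_mode = c("calendar", "relative")) {
  bin_mode <- match.arg(bin_mode)
  empty <- list(
    strata = tibble(stratum = character(), n = integer(),
                    mean_claim_months = numeric(), median_claim_months = numeric(),
                    sd_claim_months = numeric(), min_claim_months = numeric(),
                    max_claim_months = numeric()),
    sbce_fraction = NA_real_,
    codes = tibble(code_class = character(), n_codes = integer()))
  if (nrow(registry) == 0) return(empty)
  windows <- assign_valid_windows(registry, bin_mode)
  dx_date <- if (bin_mode == "calendar") diagnosis_dates(registry) else
    rep(as.Date("2001-01-01"), nrow(registry))
  anchors <- tibble(patient_id = registry$patient_id, dx_date = dx_date)
  claim_months <- claims %>%
    inner_join(anchors, by = "patient_id") %>%
    inner_join(windows, by = "patient_id") %>%
    mutate(month_index = month_index_of(.data$day, .data$dx_date, bin_mode)) %>%
    filter(.data$day >= .data$valid_from_day,
           .data$month_index >= .data$start_month,
           .data$month_index <= .data$end_month) %>%
    distinct(.data$patient_id, .data$month_index) %>%
    count(.data$patient_id, name = "claim_months")
  per_patient <- registry %>%
    select("patient_id", "sbce") %>%
    left_join(claim_months, by = "patient_id") %>%
    mutate(claim_months = tidyr::replace_na(.data$claim_months, 0L))
  strata <- per_patient %>%
    mutate(stratum = ifelse(.data$sbce, "sbce", "non_sbce")) %>%
    group_by(.data$stratum) %>%
    summarise(n = n(),
              mean_claim_months = mean(.data$claim_months),
              median_claim_months = median(.data$claim_months),
              sd_claim_months = stats::sd(.data$claim_months),
              min_claim_months = min(.data$claim_months),
              max_claim_months = max(.data$claim_months),
              .groups = "drop")
  list(strata = strata,
       sbce_fraction = mean(registry$sbce),
       codes = claims %>% distinct(.data$code, .data$code_class) %>%
         count(.data$code_class, name = "n_codes"))
}
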