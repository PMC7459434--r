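# Valid windows, eligibility filters, deduplication, the rare-code filter
# and monthly aggregation.

test_that("window spans month 6 to the follow-up month when nothing competes", {
  reg <- make_registry(1, followup_end_day = 1000L)
  w_rel <- assign_valid_windows(reg, bin_mode = "relative")
  expect_equal(w_rel$start_month, 6L)
  expect_equal(w_rel$end_month, floor(1000 / 30.4375)) # 32
  w_cal <- assign_valid_windows(reg, bin_mode = "calendar")
  expect_equal(w_cal$start_month, 6L)
  # diagnosis 2001-01-15 + 1000 days = 2003-10-11 -> month index 33
  expect_equal(w_cal$end_month, 33L)
  expect_true(w_cal$eligible)
})

test_that("a non-breast second primary truncates follow-up by 3 months", {
  # day 1220 falls in relative month 40; follow-up would otherwise end at 60
  reg <- make_registry(1, followup_end_day = 1830L,
                       nonbreast_primary_day = 1220L)
  w <- assign_valid_windows(reg, bin_mode = "relative")
  expect_equal(w$end_month, 37L)
})

test_that("a second breast event truncates follow-up by 1 month", {
  # day 915 falls in relative month 30
  reg <- make_registry(1, sbce = TRUE, sbce_day = 500L,
                       followup_end_day = 1830L, second_sbce_day = 915L)
  w <- assign_valid_windows(reg, bin_mode = "relative")
  expect_equal(w$end_month, 29L)
  expect_equal(w$sbce_month, floor(500 / 30.4375))
})

test_that("empty windows are flagged ineligible", {
  reg <- make_registry(1, followup_end_day = 100L) # month 3 < start 6
  w <- assign_valid_windows(reg, bin_mode = "relative")
  expect_false(w$eligible)
})

test_that("eligibility filtering logs a reason per dropped patient", {
  reg <- make_registry(
    3, sbce = c(TRUE, FALSE, FALSE),
    sbce_day = c(600L, NA, NA),
    followup_end_day = c(1000L, 1000L, 100L))
  w <- assign_valid_windows(reg, bin_mode = "relative")
  claims <- dplyr::bind_rows(
    make_claims("T001", day = c(200, 300, 500)),   # none on/after sbce_day 600
    make_claims("T002", day = c(10, 50, 150))      # all before window start
  )
  kept <- filter_eligible(reg, w, claims, bin_mode = "relative")
  expect_equal(nrow(kept$registry), 0)
  reasons <- setNames(kept$exclusions$reason, kept$exclusions$patient_id)
  expect_equal(reasons[["T001"]], "no_post_event_claims")
  expect_equal(reasons[["T002"]], "no_claims_in_window")
  expect_equal(reasons[["T003"]], "empty_window")
  # parsed + rejected = input row count: nothing vanishes silently
  expect_equal(nrow(kept$registry) + nrow(kept$exclusions), nrow(reg))
})

test_that("a single claim at the window boundary retains the patient", {
  reg <- make_registry(1, followup_end_day = 1000L)
  claims <- make_claims("T001", day = 190) # relative month 6, after day 183
  kept <- filter_eligible(reg, assign_valid_windows(reg, "relative"),
                          claims, bin_mode = "relative")
  expect_equal(kept$registry$patient_id, "T001")
  expect_equal(nrow(kept$exclusions), 0)
})

test_that("daily deduplication keeps one event per code-day and is idempotent", {
  claims <- dplyr::bind_rows(
    make_claims(rep("T001", 2), day = c(100, 100)),            # same code twice
    make_claims("T001", day = 101),                            # next day
    make_claims(rep("T001", 3), day = rep(120, 3),
                code = c("D001", "D002", "P001"),
                system = c("ICD9CM", "ICD9CM", "CPT"),
                code_class = c("diagnosis", "diagnosis", "procedure"))
  )
  once <- dedupe_daily(claims)
  expect_equal(sum(once$day == 100), 1)
  expect_equal(sum(once$day %in% c(100, 101)), 2)
  expect_equal(sum(once$day == 120), 3)
  expect_equal(dedupe_daily(once), once)
  # order independence
  shuffled <- claims[rev(seq_len(nrow(claims))), ]
  expect_equal(dedupe_daily(shuffled), once)
})

test_that("rare-code filter needs two days within a single patient", {
  # D001 held once each by 5 different patients -> dropped
  spread <- make_claims(sprintf("T%03d", 1:5), day = 200 + 1:5)
  # D002 on two days by one patient -> retained everywhere, incl. T009
  repeated <- dplyr::bind_rows(
    make_claims(rep("T001", 2), day = c(300, 320), code = "D002"),
    make_claims("T009", day = 400, code = "D002"))
  out <- filter_rare_codes(dplyr::bind_rows(spread, repeated))
  expect_equal(out$dropped_codes$code, "D001")
  expect_equal(sum(out$claims$code == "D002"), 3)
  expect_equal(sum(out$claims$code == "D001"), 0)
})

test_that("rare-code rule leaves procedure codes alone by default", {
  px <- make_claims("T001", day = 500, code = "P001",
                    system = "CPT", code_class = "procedure")
  out <- filter_rare_codes(px)
  expect_equal(nrow(out$claims), 1)
  expect_equal(nrow(out$dropped_codes), 0)
  # but drops them when the rule is extended
  out2 <- filter_rare_codes(px, include_procedures = TRUE)
  expect_equal(nrow(out2$claims), 0)
})

test_that("month panel sums grouped codes per calendar month", {
  reg <- make_registry(1, followup_end_day = 1000L)
  w <- assign_valid_windows(reg, bin_mode = "relative")
  # D001 and D002 both map to gd1; days 400 and 410 are both month 13
  claims <- make_claims(rep("T001", 3), day = c(400, 410, 170),
                        code = c("D001", "D002", "D001"))
  panel <- build_month_panel(claims, reg, w, tiny_groupmap(),
                             bin_mode = "relative")
  expect_equal(panel$counts$count, 2L)
  expect_equal(panel$counts$group_id, "gd1")
  expect_equal(panel$counts$month_index, 13L)
  # the day-170 claim precedes the window start and is not counted
  expect_equal(sum(panel$counts$count), 2L)
})

test_that("panel counts conserve in-window mapped claims and ignore order", {
  reg <- make_registry(2, followup_end_day = c(1000L, 800L))
  w <- assign_valid_windows(reg, bin_mode = "relative")
  set.seed(99)
  claims <- make_claims(
    sample(rep(c("T001", "T002"), 15)), day = sample(184:780, 30),
    code = sample(c("D001", "D002", "D003", "ZZZ"), 30, replace = TRUE))
  panel <- build_month_panel(claims, reg, w, tiny_groupmap(),
                             bin_mode = "relative")
  n_mapped_in_window <- sum(claims$code != "ZZZ")
  expect_equal(sum(panel$counts$count), n_mapped_in_window)
  expect_equal(panel$n_unmapped, sum(claims$code == "ZZZ"))
  shuffled <- claims[sample(nrow(claims)), ]
  panel2 <- build_month_panel(shuffled, reg, w, tiny_groupmap(),
                              bin_mode = "relative")
  expect_equal(panel2$counts, panel$counts)
})

test_that("an empty group map is a configuration error", {
  reg <- make_registry(1)
  w <- assign_valid_windows(reg, bin_mode = "relative")
  expect_error(
    build_month_panel(make_claims("T001", 200), reg, w,
                      tiny_groupmap()[0, ], bin_mode = "relative"),
    class = "recurmine_config_error")
})
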