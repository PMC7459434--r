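# Cohort data model: registry records, claim events, code-group maps.
#
# All dates are stored as integer days since the primary diagnosis (day 0),
# matching the deidentified source data model. Calendar placement exists only
# through a synthetic "jitter" (a randomly generated month and day of
# diagnosis within the diagnosis year) used solely to bin claims into
# calendar months.

REGISTRY_REQUIRED <- c(
  "patient_id", "age_at_diagnosis", "stage", "grade", "er_status",
  "pr_status", "site", "sbce", "sbce_day", "followup_end_day"
)
REGISTRY_OPTIONAL <- c(
  "diagnosis_day", "second_sbce_day", "nonbreast_primary_day",
  "diagnosis_year", "diagnosis_month", "diagnosis_dom"
)
CLAIMS_REQUIRED <- c("patient_id", "day", "system", "code", "code_class")
GROUPMAP_REQUIRED <- c("code", "group_id", "code_class")

CLAIM_SYSTEMS <- c("ICD9CM", "CPT", "HCPCS")
CODE_CLASSES <- c("diagnosis", "procedure")
HR_LEVELS <- c("positive", "negative", "unknown")

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "recurmine_schema_error")
  }
  invisible(df)
}

raise_row_problems <- function(problems, what) {
  if (nrow(problems) == 0) return(invisible(NULL))
  shown <- head(problems, 10)
  msg <- paste0(
    sprintf("%d validation error%s in %s:\n", nrow(problems),
            if (nrow(problems) > 1) "s" else "", what),
    paste(sprintf("  row %d [%s]: %s", shown$row, shown$patient_id,
                  shown$problem), collapse = "\n"),
    if (nrow(problems) > 10) sprintf("\n  ... and %d more", nrow(problems) - 10) else ""
  )
  abort(msg, class = "recurmine_validation_error", problems = problems)
}

#' Validate a registry table
#'
#' Checks the per-row invariants of a registry table: an event day must be
#' present if and only if the event indicator is set, event days must follow
#' the diagnosis day, a second event must follow the first, and the
#' end-of-enrollment day must not precede diagnosis.
#'
#' @param registry A data frame of registry records (see [read_registry()]
#'   for the schema).
#' @return A tibble of problems with columns `row`, `patient_id`, `problem`;
#'   zero rows when the table is valid.
#' @export
validate_registry <- function(registry) {
  check_columns(registry, REGISTRY_REQUIRED, "registry")
  r <- registry
  problem <- function(bad, msg) {
    tibble(row = which(bad), patient_id = as.character(r$patient_id[bad]),
           problem = msg)
  }
  dx <- if ("diagnosis_day" %in% names(r)) r$diagnosis_day else 0L
  probs <- bind_rows(
    problem(r$sbce & is.na(r$sbce_day), "sbce is true but sbce_day is missing"),
    problem(!r$sbce & !is.na(r$sbce_day), "sbce_day present but sbce is false"),
    problem(!is.na(r$sbce_day) & r$sbce_day <= dx,
            "sbce_day must be after the diagnosis day"),
    problem(r$followup_end_day < dx,
            "followup_end_day precedes the diagnosis day"),
    problem(!r$stage %in% c("I", "II"), "stage must be I or II"),
    problem(!r$er_status %in% HR_LEVELS, "invalid er_status"),
    problem(!r$pr_status %in% HR_LEVELS, "invalid pr_status"),
    problem(is.na(r$age_at_diagnosis) | r$age_at_diagnosis < 18,
            "age_at_diagnosis must be >= 18")
  )
  if ("second_sbce_day" %in% names(r)) {
    bad <- !is.na(r$second_sbce_day) & !is.na(r$sbce_day) &
      r$second_sbce_day <= r$sbce_day
    probs <- bind_rows(probs, problem(bad, "second_sbce_day must follow sbce_day"))
  }
  if (anyDuplicated(r$patient_id)) {
    dup <- duplicated(r$patient_id)
    probs <- bind_rows(probs, problem(dup, "duplicate patient_id"))
  }
  arrange(probs, .data$row)
}

#' Validate a claims table
#'
#' @param claims A data frame of claim events (see [read_claims()]).
#' @return A tibble of problems (`row`, `patient_id`, `problem`).
#' @export
validate_claims <- function(claims) {
  check_columns(claims, CLAIMS_REQUIRED, "claims")
  cl <- claims
  problem <- function(bad, msg) {
    tibble(row = which(bad), patient_id = as.character(cl$patient_id[bad]),
           problem = msg)
  }
  probs <- bind_rows(
    problem(is.na(cl$day) | cl$day < 0, "day must be a nonnegative integer"),
    problem(!cl$system %in% CLAIM_SYSTEMS,
            sprintf("unsupported coding system (expected %s)",
                    paste(CLAIM_SYSTEMS, collapse = "/"))),
    problem(!cl$code_class %in% CODE_CLASSES,
            "code_class must be diagnosis or procedure"),
    problem(is.na(cl$code) | cl$code == "", "code must be nonempty"),
    problem(cl$system == "ICD9CM" & cl$code_class != "diagnosis",
            "ICD9CM codes must be diagnosis class"),
    problem(cl$system %in% c("CPT", "HCPCS") & cl$code_class != "procedure",
            "CPT/HCPCS codes must be procedure class")
  )
  arrange(probs, .data$row)
}

#' Validate a code-group map
#'
#' @param groupmap A data frame with columns `code`, `group_id`, `code_class`.
#' @return A tibble of problems (`row`, `patient_id` is `NA`, `problem`).
#' @export
validate_code_groups <- function(groupmap) {
  check_columns(groupmap, GROUPMAP_REQUIRED, "code-group map")
  g <- groupmap
  problem <- function(bad, msg) {
    tibble(row = which(bad), patient_id = NA_character_, problem = msg)
  }
  probs <- bind_rows(
    problem(duplicated(g$code), "code maps to more than one group"),
    problem(!g$code_class %in% CODE_CLASSES,
            "code_class must be diagnosis or procedure")
  )
  # a group must not mix code classes
  mixed <- g %>%
    distinct(.data$group_id, .data$code_class) %>%
    count(.data$group_id) %>%
    filter(.data$n > 1) %>%
    pull(.data$group_id)
  if (length(mixed) > 0) {
    bad <- g$group_id %in% mixed
    probs <- bind_rows(probs, problem(bad, "group mixes diagnosis and procedure codes"))
  }
  arrange(probs, .data$row)
}

#' Read a registry file
#'
#' Reads a one-row-per-patient registry CSV. Required columns:
#' `patient_id`, `age_at_diagnosis` (years), `stage` (I/II), `grade`,
#' `er_status`, `pr_status` (positive/negative/unknown), `site`,
#' `sbce` (logical gold-standard indicator), `sbce_day` (days since
#' diagnosis, empty when `sbce` is false), `followup_end_day`. Optional:
#' `second_sbce_day`, `nonbreast_primary_day`, `diagnosis_year`,
#' `diagnosis_month`, `diagnosis_dom` (the jittered calendar anchor, see
#' [jitter_diagnosis_dates()]).
#'
#' Rows violating the registry invariants raise a validation error listing
#' each offending row; nothing is silently dropped.
#'
#' @param path Path to a CSV file.
#' @return A tibble of registry records.
#' @export
read_registry <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(raw, REGISTRY_REQUIRED, sprintf("registry file '%s'", path))
  r <- as_tibble(raw) %>%
    mutate(
      patient_id = as.character(.data$patient_id),
      sbce = as.logical(.data$sbce),
      across(all_of(intersect(
        c("sbce_day", "second_sbce_day", "nonbreast_primary_day",
          "followup_end_day", "diagnosis_day", "diagnosis_year",
          "diagnosis_month", "diagnosis_dom"), names(raw))),
        as.integer),
      age_at_diagnosis = as.numeric(.data$age_at_diagnosis),
      across(all_of(c("stage", "grade", "er_status", "pr_status", "site")),
             as.character)
    )
  raise_row_problems(validate_registry(r), sprintf("registry file '%s'", path))
  r
}

#' Read a claims file
#'
#' Reads a one-row-per-claim-line CSV with columns `patient_id`, `day`
#' (integer days since diagnosis), `system` (ICD9CM/CPT/HCPCS), `code`,
#' `code_class` (diagnosis/procedure). Invalid rows raise a validation
#' error naming the patient and line.
#'
#' @param path Path to a CSV file.
#' @return A tibble of claim events.
#' @export
read_claims <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = list(code = "character"))
  check_columns(raw, CLAIMS_REQUIRED, sprintf("claims file '%s'", path))
  cl <- as_tibble(raw) %>%
    mutate(patient_id = as.character(.data$patient_id),
           day = as.integer(.data$day),
           code = as.character(.data$code))
  raise_row_problems(validate_claims(cl), sprintf("claims file '%s'", path))
  cl
}

#' Read a code-group map
#'
#' Reads a CSV mapping each code to a code group, with columns `code`,
#' `group_id`, `code_class`. Code groups aggregate codes that capture the
#' same clinical condition or procedure type; the analysis operates on
#' monthly counts per group, not per raw code.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per code.
#' @export
read_code_groups <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = list(code = "character"))
  check_columns(raw, GROUPMAP_REQUIRED, sprintf("group map '%s'", path))
  g <- as_tibble(raw) %>%
    mutate(code = as.character(.data$code),
           group_id = as.character(.data$group_id))
  raise_row_problems(validate_code_groups(g), sprintf("group map '%s'", path))
  g
}

#' Write cohort tables
#'
#' Writers matching [read_registry()], [read_claims()] and
#' [read_code_groups()]; a write followed by a read reproduces identical
#' field values.
#'
#' @param x The table to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_registry
#' @export
write_claims <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_registry
#' @export
write_code_groups <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Assign a random calendar diagnosis date within each diagnosis year
#'
#' The deidentified data model stores all dates as days since diagnosis, so
#' patients have no calendar anchor. To allow claims to be summarised by
#' calendar month (and age/time expressed as real numbers), each patient is
#' augmented with a randomly generated month and day of diagnosis, drawn
#' uniformly over the days of the diagnosis year, and `age_at_diagnosis` is
#' re-expressed as a fractional year consistent with the jittered day of
#' year.
#'
#' @param registry A registry tibble. If a `diagnosis_year` column is
#'   absent, the (arbitrary, non-leap) year 2001 is used: only month
#'   boundaries matter downstream.
#' @param seed Integer seed; the jitter is deterministic given the seed.
#' @return The registry with `diagnosis_year`, `diagnosis_month` and
#'   `diagnosis_dom` (day of month) filled in and fractional ages.
#' @export
jitter_diagnosis_dates <- function(registry, seed) {
  n <- nrow(registry)
  if (!"diagnosis_year" %in% names(registry) ||
      all(is.na(registry[["diagnosis_year"]]))) {
    registry$diagnosis_year <- 2001L
  }
  with_seed(seed, {
    year_start <- as.Date(sprintf("%d-01-01", registry$diagnosis_year))
    ndays <- as.integer(as.Date(sprintf("%d-01-01", registry$diagnosis_year + 1L)) -
                          year_start)
    doy <- floor(runif(n) * ndays)  # 0-based day of year
    date <- year_start + doy
    registry$diagnosis_month <- as.integer(format(date, "%m"))
    registry$diagnosis_dom <- as.integer(format(date, "%d"))
    frac <- doy / ndays
    registry$age_at_diagnosis <- floor(registry$age_at_diagnosis) + frac
  })
  registry
}

# Evaluate `code` with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Diagnosis anchor dates for calendar-month binning; requires the jitter.
diagnosis_dates <- function(registry) {
  if (!all(c("diagnosis_year", "diagnosis_month", "diagnosis_dom") %in%
           names(registry)) ||
      anyNA(registry$diagnosis_month) || anyNA(registry$diagnosis_dom)) {
    abort(paste0(
      "calendar-month binning needs jittered diagnosis dates; ",
      "call jitter_diagnosis_dates() first or use bin_mode = \"relative\""),
      class = "recurmine_config_error")
  }
  as.Date(sprintf("%d-%02d-%02d", registry$diagnosis_year,
                  registry$diagnosis_month, registry$diagnosis_dom))
}
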