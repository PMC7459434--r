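# Shared fixtures and independent oracles, all built in code.

# A small hand-built registry with explicit calendar anchors (diagnosis on
# the 15th of January 2001 unless stated), so month arithmetic is exact.
make_registry <- function(n = 3, sbce = rep(FALSE, n), sbce_day = rep(NA_integer_, n),
                          followup_end_day = rep(1000L, n),
                          second_sbce_day = rep(NA_integer_, n),
                          nonbreast_primary_day = rep(NA_integer_, n)) {
  tibble::tibble(
    patient_id = sprintf("T%03d", seq_len(n)),
    age_at_diagnosis = 60 + seq_len(n) / 10,
    stage = rep_len(c("I", "II"), n),
    grade = rep_len(c("1", "2", "3"), n),
    er_status = rep_len(c("positive", "negative"), n),
    pr_status = rep_len(c("positive", "unknown"), n),
    site = "ductal",
    sbce = sbce,
    sbce_day = as.integer(sbce_day),
    second_sbce_day = as.integer(second_sbce_day),
    nonbreast_primary_day = as.integer(nonbreast_primary_day),
    followup_end_day = as.integer(followup_end_day),
    diagnosis_year = 2001L,
    diagnosis_month = 1L,
    diagnosis_dom = 15L
  )
}

make_claims <- function(patient_id, day, code = "D001",
                        system = "ICD9CM", code_class = "diagnosis") {
  tibble::tibble(patient_id = patient_id, day = as.integer(day),
                 system = system, code = code, code_class = code_class)
}

tiny_groupmap <- function() {
  tibble::tibble(
    code = c("D001", "D002", "D003", "P001", "P002"),
    group_id = c("gd1", "gd1", "gd2", "gp1", "gp2"),
    code_class = c("diagnosis", "diagnosis", "diagnosis",
                   "procedure", "procedure")
  )
}

# Build a month_panel object directly from windows and counts.
make_panel <- function(windows, counts, groups = NULL) {
  if (is.null(groups)) {
    groups <- tibble::tibble(group_id = sort(unique(counts$group_id)),
                             code_class = "diagnosis")
  }
  if (!"eligible" %in% names(windows)) windows$eligible <- TRUE
  if (!"sbce_month" %in% names(windows)) windows$sbce_month <- NA_integer_
  structure(list(counts = counts, windows = windows, groups = groups,
                 n_unmapped = 0L),
            class = "month_panel")
}

# Independent O(window^2) rescan oracle for the temporal features.
oracle_temporal <- function(counts) {
  n <- length(counts)
  out <- data.frame(count = as.integer(counts), since = -1L, until = -1L,
                    frac = 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      for (j in (i - 1):1) {
        if (counts[j] > 0) { out$since[i] <- i - j; break }
      }
      out$frac[i] <- mean(counts[1:(i - 1)] > 0)
    }
    if (i < n) {
      for (j in (i + 1):n) {
        if (counts[j] > 0) { out$until[i] <- j - i; break }
      }
    }
  }
  out
}

# Brute-force pairwise Mann-Whitney concordance (ties count 1/2).
oracle_auc <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# A random small panel for property tests: <= 8 patients, <= 24 months,
# <= 5 groups, sparse counts.
random_panel <- function() {
  n_pat <- sample(1:8, 1)
  n_grp <- sample(1:5, 1)
  groups <- sprintf("g%02d", seq_len(n_grp))
  windows <- tibble::tibble(
    patient_id = sprintf("R%02d", seq_len(n_pat)),
    start_month = 6L,
    end_month = 6L + sample(0:23, n_pat, replace = TRUE),
    sbce_month = NA_integer_,
    eligible = TRUE
  )
  counts <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
    months <- windows$start_month[i]:windows$end_month[i]
    cells <- expand.grid(month_index = months, group_id = groups,
                         stringsAsFactors = FALSE)
    cells$patient_id <- windows$patient_id[i]
    cells$count <- stats::rpois(nrow(cells), 0.4)
    cells[cells$count > 0, c("patient_id", "month_index", "group_id", "count")]
  }))
  make_panel(windows, tibble::as_tibble(counts),
             tibble::tibble(group_id = groups, code_class = "diagnosis"))
}

# Registry whose panel/labels pair with random_panel-style windows.
registry_for_windows <- function(windows) {
  n <- nrow(windows)
  tibble::tibble(
    patient_id = windows$patient_id,
    age_at_diagnosis = 55,
    stage = "I", grade = "2", er_status = "positive",
    pr_status = "positive", site = "ductal",
    sbce = !is.na(windows$sbce_month),
    sbce_day = NA_integer_,
    followup_end_day = 5000L,
    diagnosis_year = 2001L, diagnosis_month = 1L, diagnosis_dom = 1L
  )
}
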