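---
title: "Mining medical claims for second breast cancer events: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining medical claims for second breast cancer events: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(recurmine)
library(dplyr)
```

## The problem

Population-based cancer registries record primary diagnoses and first-course
treatment but generally not recurrences. For breast cancer, a *second breast
cancer event* (SBCE) — a recurrence of the original tumour or a new breast
primary — is a key outcome that registries cannot afford to abstract from
charts for every case. Administrative claims (coded diagnoses and
procedures) are available at population scale, and the utilisation pattern
around an SBCE is distinctive: a short burst of diagnostic workup (biopsies,
imaging), then a sustained treatment signature (secondary-malignancy
diagnosis codes, chemotherapy, tumour markers) that decays over time.

`recurmine` implements a retrospective surveillance method for this setting.
The person-level time-to-event question ("did this patient have an SBCE, and
when?") is recast as a binary classification of each follow-up month as
pre- versus post-event (the event month counts as post). A gradient-boosted
tree ensemble scores every person-month; person-level calls and event-month
estimates are read off the monthly probability series with a probability
threshold (PT). Because the intended consumer is a registry looking
backwards at a complete claims history — not a clinician predicting the
future — features may use the entire record, including months after the
candidate event.

## Data model

All dates are integer *days since the primary diagnosis* (day 0), the
deidentified form in which linked registry-claims data are typically
released. Because claims are summarised by calendar month, each patient is
augmented with a random calendar anchor: a month and day of diagnosis drawn
uniformly over the diagnosis year (`jitter_diagnosis_dates()`), with age
re-expressed as a fractional year consistent with the jittered day. The
jitter is used *only* for calendar-month binning; a `bin_mode = "relative"`
path bins by 30.4375-day months for users who prefer to skip it.

The valid-claims window starts six months after diagnosis — the first six
months are dominated by primary treatment, which is uninformative about
recurrence — and ends at the end of enrollment, truncated 3 months before
any non-breast second primary and 1 month before any second SBCE (month
arithmetic is done in month indices, matching the panel's resolution). We
take the window's first month to be the calendar month *containing* the
six-month anniversary (index 6), and enforce "after six months" at day
level: claims earlier in that month than the anniversary are invalid, so
month 6 is a partial month. Patients with an empty window, no valid claims,
or an event invisible to claims (no claims on or after the event day) are
excluded, each with a logged reason — exclusions are an audited outcome,
never a silent drop.

Claims are consolidated so each code occurs at most once per patient-day
(repeat lines on one day are billing artefacts, not clinical signal), and
diagnosis codes that never occur on two separate days for any single
patient are dropped: a code that no patient ever repeats cannot support the
temporal features below and is mostly rule-out noise. The rule is read
literally as applying to diagnosis codes only; a switch extends it to
procedures. We apply it to the deduplicated claims before window
truncation, so a code's "two days" may include pre-window evidence — the
alternative (post-truncation) would make a code's inclusion depend on the
censoring configuration, which we find less defensible. Surviving claims
are mapped to user-supplied code groups (clinically equivalent codes pooled
together; unmapped codes are dropped with a logged count) and summed per
patient, calendar month and group.

## Features and labels

For patient $i$, month $m$ and code group $g$, with the window
$[s_i, e_i]$:

* `count`: the group's claim count in month $m$;
* `since`: $m - \max\{m' < m : c_{g}(m') > 0\}$, months since the last
  *prior* in-window occurrence, $-1$ if none;
* `until`: $\min\{m' > m : c_{g}(m') > 0\} - m$, months until the next
  *later* occurrence, $-1$ if none (the current month never feeds
  since/until — its information is already in `count`);
* `frac`: the fraction of prior in-window months (zero-claim months
  included in the denominator) with at least one occurrence; defined as 0
  in the window's first month, because $-1$ is reserved for since/until.

Baseline registry variables (stage, grade, ER/PR status, site; one-hot
encoded since the learner needs numeric inputs and the categories are
unordered), months since diagnosis, and the patient's age in the month
complete the row. With $G$ groups and $R$ encoded registry columns each row
has $R + 2 + 4G$ predictors. The label is 1 from the event month onward and
0 otherwise; all months of event-free patients are 0.

The `until` and `frac` features are what make the person-month framing
powerful: a month just before the event "sees" the imminent workup
(`until` small for biopsy/imaging groups), and a month well after it
carries a durable elevated `frac` for treatment groups even if that
specific month is quiet.

## Classifier

The learner is a gradient-boosted tree ensemble (the `xgboost` library,
binary logistic objective). Patients — never person-months — are split
80:20 into training and test sets, separately within the event and
event-free strata so the test set preserves prevalence (train stratum size
is `round(0.8 n)`). Training patients are assigned to five stratified
cross-validation folds, again at patient level: months of one patient never
straddle folds, which would otherwise leak within-patient structure into
validation scores. The grid (tree depth {3, 6} x learning rate {0.1, 0.3}
by default) is scored by mean out-of-fold month-level AUC with early
stopping choosing the round count; AUC is also the selection criterion
because it is the headline month-level metric. All randomness funnels
through one recorded seed with fixed per-stage offsets, so a run is exactly
reproducible. Feature importance is reported as frequency of use across the
ensemble's trees (the share of splits using each feature), ties broken by
stored feature order.

## Person-level inference

For each threshold in a grid (0.10 to 0.75 in steps of 0.05 by default) a
patient is called positive if *any* monthly probability strictly exceeds
the threshold. Exceedance is strict deliberately: tree ensembles emit
repeated probability values, and a tie at exactly PT should not trigger a
call. Two timing rules are provided:

* `first_exceed` (default): the earliest month whose probability exceeds
  PT;
* `max_increase`: the month of the largest probability increase between
  adjacent months (earliest maximiser on ties; a single-month series
  returns its sole month). This changepoint-style rule is invariant to
  adding a constant to the series.

Both rules are legitimate readings of the method; outputs record which rule
produced them. We default to `first_exceed` as the more explicit
definition.

## Evaluation

`evaluate_sbce()` produces: the month-level ROC over all distinct
probability cutpoints with trapezoid AUC (equal to the Mann-Whitney
concordance, ties counted 1/2 — the test suite verifies this against an
$O(n^2)$ pairwise oracle); a per-threshold table of person-level
sensitivity, specificity, PPV and NPV (zero-denominator ratios are
reported as absent, not zero; displayed values are rounded to 3 decimals,
internal values are not); timing-error summaries (mean, median, min, max of
predicted minus observed event month over true positives only — negative
means the prediction precedes the observed event); and a Kaplan-Meier pair
comparing observed event times among gold-standard cases with predicted
times, censoring non-predicted cases at their last follow-up month.
Survival curves use the standard product-limit estimator with events
processed before censorings at tied times.

## The simulator

Restricted clinical cohorts cannot ship with a package, so `sim_config()` /
`simulate_cohort()` generate cohorts with the statistical structure the
method assumes. Design choices, with their rationale:

* **Discrete monthly hazard.** The whole pipeline is monthly, so the event
  month is drawn from a discrete hazard over months 7-168. The hazard's
  time profile is a gamma density (shape 2, scale 20) peaking around month
  20 — recurrence risk in early-stage breast cancer peaks one to three
  years after diagnosis and declines thereafter. The baseline level is
  *calibrated*, not asserted: `calibrate_hazard()` solves for the scale at
  which the population-average cumulative incidence at month 168 equals
  the target (0.25 by default), averaging exactly over the joint covariate
  distribution.
* **Covariate effects.** Stage II, ER-negative, PR-negative and grade 3
  disease multiply the hazard (1.8, 1.6, 1.4, 1.3), reflecting the
  direction of established prognostic factors; prevalences (35% stage II,
  15% ER-, 25% PR-, 30% grade 3) are typical of an early-stage cohort.
  ER/PR are drawn independently, which understates their real correlation;
  this only mildly widens the hazard-multiplier distribution.
* **Follow-up.** The window length beyond month 6 is gamma with mean 30.5
  and SD 19.2 months (clamped to [1, 153] so no window outlasts month
  159). With the default claim rates nearly every window month contains a
  claim, so event-free patients average about 31.5 claim-months. No
  separate follow-up model is fitted for event patients: patients followed
  longer are more likely to have an observable event, and this selection
  alone reproduces their longer histories (about 43-45 claim-months) —
  an emergent check on the design rather than a tuned input.
* **Claims.** 8 diagnosis and 8 procedure groups (3 codes each) with
  baseline monthly Poisson rates from 0.8 down to 0.08. The last two
  groups of each class — the rarest in background — are the event-signal
  groups (mimicking secondary-malignancy diagnoses and biopsy/imaging
  procedures). From the event month the signal rates are multiplied by
  $1 + 7 \cdot 0.93^{m - m_{\text{event}}}$ (8 at the event, decaying
  geometrically toward baseline, echoing how post-event claim signatures
  fade); the two months before the event multiply the procedure signal
  groups by 3 (diagnostic workup). Setting both multipliers to 1 gives a
  *null* cohort: claims carry no event information whatsoever.
* **Expansion to days.** Monthly counts are expanded to uniformly placed
  day-level coded events, so the generator's output enters the pipeline
  through exactly the same CSV schemas, deduplication and binning as real
  data.

What the simulator does *not* emulate: real ICD-9-CM/CPT semantics, payer
switching and coverage gaps, coding-system drift over calendar time,
correlated comorbidity bursts, and gold-standard misclassification. Passing
tests on simulated cohorts therefore demonstrate that the machinery
recovers the signal it is designed for — not that the method attains any
particular accuracy on real claims.

## What the default cohort shows — and two honest caveats

With the default configuration (600 patients; about 13% observed events,
matching what a 0.25-by-14-years hazard yields under these follow-up
lengths) the full pipeline reaches month-level AUC above 0.99 and
person-level sensitivity and specificity near or above 0.9 at PT 0.5; the
test suite asserts AUC ≥ 0.95 and sensitivity/specificity ≥ 0.85. Problem
sizes in the suite (600-patient end-to-end runs, a 3000-patient registry
for the Kaplan-Meier calibration check, 100 small random panels for the
feature oracle) are chosen to make each property measurable with
comfortable Monte-Carlo margins while keeping a full run quick.

Two behaviours deserve explicit notice.

**Timing is right-skewed by about half a month.** Predicted event months
cluster at 0 and +1 months. This is intrinsic to the generator, not a
defect of the timing rule: a single signal-group occurrence in the event
month is weak evidence (background produces one somewhere in roughly 30%
of pre-event months), so the probability series often crosses PT = 0.5 one
month late, exactly as the Bayes-optimal rule would. Median timing error
is therefore 0 or 1 depending on the seed. Real cohorts show the opposite
skew (predictions *preceding* the charted event, because workup precedes
the chart-abstracted event date); reproducing that would require the
pre-event bump to be partially indistinguishable from the post-event
signature.

**Person-month classification has structural temporal confounding.** On the
*null* cohort the person-level guard holds — at PT ≥ 0.5 essentially no
patient is called positive, so there is no artifactual person-level
detection. But the month-level AUC on the null cohort is about 0.65-0.80
depending on the seed, not 0.5, and this is not feature leakage: post-event
months can only occur late in long follow-up windows, and patients with
observed events have longer windows by selection, so months-since-diagnosis
*alone* scores about 0.7 on null data (permuting labels at patient level drops the model to
chance, confirming the features themselves carry no event information).
Month-level AUC on any cohort — simulated or real — therefore mixes event
signal with this structural time trend, and null-cohort month-level AUC is
the wrong yardstick for leakage; the person-level guard is the right one.

## Known limitations

* The code-group map is an external interface; the shipped map generator
  produces synthetic groups, and real analyses must supply their own.
* No prospective mode: features use the full record by design, so
  probabilities must not be read as real-time recurrence risk.
* No confidence intervals on evaluation metrics, and no coarse-grouping
  analysis path.
* Fractional age is derived from the jittered diagnosis date, so it can
  differ from the (unavailable) true fractional age by up to a year.
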