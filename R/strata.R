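#' The six grade/relatedness strata
#'
#' The biomarker panel crosses three grade classes (any grade; low grade,
#' CTCAE grade 1-2; high grade, grade 3 or higher) with two relatedness
#' filters (all events; treatment-related events only, i.e. attribution
#' definite, probable, or possible). The six combinations are the row
#' blocks of the 24-biomarker panel and are kept in a fixed display order.
#'
#' @return A tibble with columns `stratum` (factor, 6 levels), `grade_class`
#'   (`"any"`, `"low"`, `"high"`) and `related_only` (logical).
#' @examples
#' ae_strata()
#' @export
ae_strata <- function() {
  tibble(
    stratum = factor(stratum_levels(), levels = stratum_levels()),
    grade_class = rep(c("any", "low", "high"), each = 2),
    related_only = rep(c(FALSE, TRUE), times = 3)
  )
}

stratum_levels <- function() {
  c("any_grade", "related_any_grade",
    "low_grade", "related_low_grade",
    "high_grade", "related_high_grade")
}

#' The four per-stratum measurements
#'
#' Within each stratum a patient's events are summarised four ways:
#' `occurrence` (0/1, any qualifying event), `n_unique` (number of distinct
#' AE terms), `n_events` (number of event episodes, counting recurrences),
#' and `duration` (sum of episode durations in days, counting recurrences).
#'
#' @return Character vector of the four measurement names, in display order.
#' @examples
#' ae_measurements()
#' @export
ae_measurements <- function() {
  c("occurrence", "n_unique", "n_events", "duration")
}

measurement_levels <- ae_measurements

#' The five CTCAE attribution categories
#'
#' @return Character vector: definite, probable, possible, unlikely,
#'   unrelated. The first three constitute "treatment related".
#' @export
ae_attributions <- function() {
  c("definite", "probable", "possible", "unlikely", "unrelated")
}

related_attributions <- function() c("definite", "probable", "possible")

#' Classify events by grade class and treatment relatedness
#'
#' Adds the two derived columns every stratum filter is built from:
#' `grade_class` is `"low"` for grade 1-2 and `"high"` for grade 3-5;
#' `related` is `TRUE` when attribution is definite, probable, or possible.
#' Every event is exactly one of low/high; "any grade" is their union.
#'
#' @param events A data frame of AE events with `grade` and `attribution`
#'   columns (e.g. the `events` element of an [ae_cohort()]).
#' @return The input tibble with `grade_class` and `related` appended.
#' @examples
#' classify_events(patient_fixture("B")$events)[, c("term", "grade",
#'   "attribution", "grade_class", "related")]
#' @export
classify_events <- function(events) {
  events <- as_tibble(events)
  mutate(
    events,
    grade_class = ifelse(.data$grade >= 3, "high", "low"),
    related = .data$attribution %in% related_attributions()
  )
}
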