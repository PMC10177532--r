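as_ae_cohort <- function(x) {
  if (inherits(x, "ae_cohort")) return(x)
  if (is.data.frame(x)) return(ae_cohort(x))
  abort("expected an ae_cohort or an AE event data frame")
}

#' Filter AE events by scope and landmark window
#'
#' Applies the early-AE landmark rule — an event belongs to the window iff
#' its *onset* is at or before `landmark_day` — and an optional scope
#' restriction to one toxicity category or one AE term. Window membership
#' is by onset only: an event starting on day 28 and resolving on day 90
#' is an early event, and by default its full duration counts. Setting
#' `truncate_at_landmark = TRUE` instead clips durations at the landmark
#' (a sensitivity option for users worried about post-landmark exposure).
#'
#' @param cohort An [ae_cohort()] (or event data frame).
#' @param landmark_day Integer day (>= 0) closing the window, or `NULL`
#'   for the full study period. The default early window in this framework
#'   is day 30.
#' @param truncate_at_landmark Clip durations at the landmark day?
#' @param category,term Optional scope restriction (at most one of the
#'   two). An unknown name yields an empty result with a warning.
#' @return Event tibble with `duration`, `grade_class`, `related` added.
#' @examples
#' filter_events(patient_fixture("B"), landmark_day = 30)
#' @export
filter_events <- function(cohort, landmark_day = NULL,
                          truncate_at_landmark = FALSE,
                          category = NULL, term = NULL) {
  cohort <- as_ae_cohort(cohort)
  if (!is.null(category) && !is.null(term)) {
    abort("give at most one of `category` and `term`")
  }
  if (!is.null(landmark_day) && landmark_day < 0) {
    abort("`landmark_day` must be >= 0 (or NULL for the full period)")
  }
  ev <- classify_events(cohort$events)
  if (!is.null(category)) {
    if (!category %in% ev$category) {
      warn(paste0("category '", category, "' not present in the cohort"))
    }
    ev <- filter(ev, .data$category == !!category)
  }
  if (!is.null(term)) {
    if (!term %in% ev$term) {
      warn(paste0("term '", term, "' not present in the cohort"))
    }
    ev <- filter(ev, .data$term == !!term)
  }
  if (!is.null(landmark_day)) {
    ev <- filter(ev, .data$onset_day <= landmark_day)
  }
  cutoff <- cohort$data_cutoff_day
  if (!is.null(landmark_day) && truncate_at_landmark) {
    ev <- mutate(ev, resolution_day = pmin(.data$resolution_day,
                                           as.integer(landmark_day)))
    cutoff <- min(cutoff, as.integer(landmark_day))
  }
  event_durations(ev, cutoff)
}

# Shared stratum x measurement aggregation. `ev` must carry scope_name,
# patient_id, term, duration, grade_class, related.
derive_core <- function(ev, scopes, patients, scope_level) {
  strata <- ae_strata()
  per_stratum <- pmap(strata, function(stratum, grade_class, related_only) {
    keep <- (grade_class == "any" | ev$grade_class == grade_class) &
      (!related_only | ev$related) &
      ev$scope_name %in% scopes
    sub <- ev[keep, , drop = FALSE]
    out <- summarise(
      group_by(sub, .data$scope_name, .data$patient_id),
      n_unique = dplyr::n_distinct(.data$term),
      n_events = dplyr::n(),
      duration = sum(.data$duration),
      .groups = "drop"
    )
    mutate(out, stratum = as.character(stratum))
  })
  long <- bind_rows(per_stratum)
  long <- complete(
    long,
    scope_name = scopes,
    patient_id = patients,
    stratum = stratum_levels(),
    fill = list(n_unique = 0, n_events = 0, duration = 0)
  )
  long <- mutate(long, occurrence = as.numeric(.data$n_events > 0))
  long <- pivot_longer(long,
                       cols = c("occurrence", "n_unique", "n_events",
                                "duration"),
                       names_to = "measurement", values_to = "value")
  long <- mutate(
    long,
    scope_level = scope_level,
    stratum = factor(.data$stratum, levels = stratum_levels()),
    measurement = factor(.data$measurement, levels = measurement_levels()),
    value = as.numeric(.data$value)
  )
  long <- select(long, "scope_level", "scope_name", "patient_id",
                 "stratum", "measurement", "value")
  arrange(long, .data$scope_name, .data$patient_id, .data$stratum,
          .data$measurement)
}

#' Derive the 24 AE biomarkers per patient
#'
#' For one AE scope (everything, one toxicity category, or one term) and
#' one window, computes for every patient the full 6-strata x
#' 4-measurement panel: events are first filtered at the event level by
#' grade class and (optionally) treatment relatedness, then summarised as
#' occurrence (0/1), number of distinct terms, number of episodes, and
#' total duration in days. A patient with no qualifying events gets all 24
#' values 0. Unique counts use the terms *remaining after* stratum
#' filtering, so a term whose only high-grade episode falls outside a
#' stratum does not count there.
#'
#' @inheritParams filter_events
#' @return A tibble with columns `scope_level`, `scope_name`,
#'   `patient_id`, `stratum`, `measurement`, `value` — 24 rows per
#'   patient.
#' @examples
#' derive_biomarkers(patient_fixture("A")) |>
#'   tidyr::pivot_wider(names_from = measurement, values_from = value)
#' derive_biomarkers(patient_fixture("A"), landmark_day = 30)
#' @export
derive_biomarkers <- function(cohort, landmark_day = NULL,
                              truncate_at_landmark = FALSE,
                              category = NULL, term = NULL) {
  cohort <- as_ae_cohort(cohort)
  ev <- filter_events(cohort, landmark_day = landmark_day,
                      truncate_at_landmark = truncate_at_landmark,
                      category = category, term = term)
  scope_level <- if (!is.null(term)) "term"
    else if (!is.null(category)) "category" else "overall"
  scope_name <- term %||% category %||% "overall"
  ev$scope_name <- scope_name
  derive_core(ev, scopes = scope_name, patients = cohort$patients,
              scope_level = scope_level)
}

#' Derive biomarker matrices for every scope at one AE data level
#'
#' The three AE data levels are: `"overall"` (all events pooled into one
#' scope), `"category"` (one scope per toxicity category / system-organ
#' class), and `"term"` (one scope per individual AE term). Every scope's
#' matrix has one row-set per patient in the cohort, zeros included, so
#' absence of an AE is carried as information rather than missingness.
#'
#' @inheritParams filter_events
#' @param level AE data level.
#' @param scopes Optional character vector of scope names to derive
#'   (categories or terms). Defaults to the distinct names in the cohort's
#'   full event table (so a scope seen only after the landmark still
#'   appears, with zeros). Supplying a catalog here lets a discovery run
#'   cover scopes with no observed events at all.
#' @return A long tibble (`scope_level`, `scope_name`, `patient_id`,
#'   `stratum`, `measurement`, `value`), with attributes `landmark_day`
#'   and `truncate_at_landmark`.
#' @examples
#' derive_matrix(ab_fixture_cohort(), level = "category")
#' @export
derive_matrix <- function(cohort, level = c("overall", "category", "term"),
                          landmark_day = NULL, truncate_at_landmark = FALSE,
                          scopes = NULL) {
  cohort <- as_ae_cohort(cohort)
  level <- match.arg(level)
  ev <- filter_events(cohort, landmark_day = landmark_day,
                      truncate_at_landmark = truncate_at_landmark)
  ev$scope_name <- switch(level,
    overall = rep("overall", nrow(ev)),
    category = ev$category,
    term = ev$term
  )
  if (is.null(scopes)) {
    scopes <- switch(level,
      overall = "overall",
      category = sort(unique(cohort$events$category)),
      term = sort(unique(cohort$events$term))
    )
  }
  out <- derive_core(ev, scopes = scopes, patients = cohort$patients,
                     scope_level = level)
  attr(out, "landmark_day") <- landmark_day
  attr(out, "truncate_at_landmark") <- truncate_at_landmark
  out
}

#' Canonical names of the 24 biomarkers
#'
#' @return Character vector `"<stratum>.<measurement>"` in panel order.
#' @examples
#' biomarker_names()
#' @export
biomarker_names <- function() {
  as.vector(t(outer(stratum_levels(), measurement_levels(), paste,
                    sep = ".")))
}

#' Pivot a long biomarker table to one row per patient
#'
#' @param biomarkers Long tibble from [derive_matrix()] or
#'   [derive_biomarkers()], restricted to a single scope.
#' @return Tibble with `patient_id` plus the 24 `"<stratum>.<measurement>"`
#'   columns in panel order.
#' @export
biomarker_wide <- function(biomarkers) {
  if (dplyr::n_distinct(biomarkers$scope_name) > 1) {
    abort("biomarker_wide() expects a single scope; filter first")
  }
  wide <- pivot_wider(
    mutate(biomarkers,
           name = paste(.data$stratum, .data$measurement, sep = ".")),
    id_cols = "patient_id", names_from = "name", values_from = "value"
  )
  select(wide, "patient_id", dplyr::all_of(biomarker_names()))
}

#' Export biomarker matrices as tidy CSV
#'
#' @param biomarkers Long biomarker tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_biomarkers <- function(biomarkers, path) {
  out <- mutate(
    biomarkers,
    landmark_day = attr(biomarkers, "landmark_day") %||% NA_integer_,
    truncate_at_landmark = attr(biomarkers, "truncate_at_landmark") %||% FALSE
  )
  write_csv(out, path, progress = FALSE)
  invisible(path)
}
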