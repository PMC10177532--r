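# Brute-force recomputation of the 24 biomarkers, written independently of
# the package's vectorised derivation: explicit event-by-event loops over
# every (stratum, measurement) pair.
brute_biomarkers <- function(events) {
  rel <- c("definite", "probable", "possible")
  keep_fun <- list(
    any_grade = function(g, a) TRUE,
    related_any_grade = function(g, a) a %in% rel,
    low_grade = function(g, a) g <= 2,
    related_low_grade = function(g, a) g <= 2 && a %in% rel,
    high_grade = function(g, a) g >= 3,
    related_high_grade = function(g, a) g >= 3 && a %in% rel
  )
  out <- numeric(0)
  for (s in names(keep_fun)) {
    terms <- character(0)
    n_events <- 0
    total_dur <- 0
    for (i in seq_len(nrow(events))) {
      g <- events$grade[i]
      a <- events$attribution[i]
      if (keep_fun[[s]](g, a)) {
        n_events <- n_events + 1
        terms <- union(terms, events$term[i])
        total_dur <- total_dur +
          (events$resolution_day[i] - events$onset_day[i] + 1)
      }
    }
    out[paste0(s, ".occurrence")] <- as.numeric(n_events > 0)
    out[paste0(s, ".n_unique")] <- length(terms)
    out[paste0(s, ".n_events")] <- n_events
    out[paste0(s, ".duration")] <- total_dur
  }
  out[biomarker_names()]
}

# Random resolved event streams for property tests (independent of the
# package's simulator).
random_events <- function(n_events, patient_id = "P1", n_terms = 5,
                          n_categories = 3, max_day = 150) {
  terms <- paste0("Term ", seq_len(n_terms))
  cats <- paste0("Category ", rep_len(seq_len(n_categories), n_terms))
  idx <- sample.int(n_terms, n_events, replace = TRUE)
  onset <- sample(0:max_day, n_events, replace = TRUE)
  dur <- sample(1:90, n_events, replace = TRUE)
  tibble::tibble(
    patient_id = patient_id,
    term = terms[idx],
    category = cats[idx],
    onset_day = as.integer(onset),
    resolution_day = as.integer(onset + dur - 1L),
    grade = sample(1:5, n_events, replace = TRUE,
                   prob = c(0.4, 0.25, 0.2, 0.1, 0.05)),
    attribution = sample(ae_attributions(), n_events, replace = TRUE)
  )
}

random_cohort <- function(n_patients, mean_events = 4, ...) {
  ev <- purrr::map(seq_len(n_patients), function(i) {
    n <- stats::rpois(1, mean_events)
    if (n == 0) return(NULL)
    random_events(n, patient_id = sprintf("P%03d", i), ...)
  })
  ae_cohort(dplyr::bind_rows(ev),
            patients = sprintf("P%03d", seq_len(n_patients)))
}

# wide named vector of one patient's biomarkers from the package
pkg_biomarkers <- function(cohort, ...) {
  wide <- biomarker_wide(derive_biomarkers(cohort, ...))
  v <- as.numeric(wide[1, biomarker_names()])
  names(v) <- biomarker_names()
  v
}

bm_value <- function(bm, stratum, measurement, patient = NULL) {
  rows <- bm$stratum == stratum & bm$measurement == measurement
  if (!is.null(patient)) rows <- rows & bm$patient_id == patient
  bm$value[rows]
}

stratum_levels_for_test <- function() {
  c("any_grade", "related_any_grade", "low_grade", "related_low_grade",
    "high_grade", "related_high_grade")
}
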