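#' Worked-example patients A and B
#'
#' Two hand-built single-patient cohorts used throughout the documentation
#' and tests. Patient A has 7 low-grade event episodes over 6 unique terms
#' in 4 toxicity categories, all with onset after day 30, including a
#' recurrent weight-loss event whose first episode is treatment related
#' (grade 1) and second is not (grade 2). Patient B has 5 episodes over 4
#' unique terms, including recurrent fatigue (a non-related grade 1
#' episode of 57 days followed by a related grade 2 episode of 169 days)
#' and a 4-day grade 3 diarrhea; exactly fatigue and diarrhea start at or
#' before day 30.
#'
#' Per-term durations not printed as totals were resolved as follows: the
#' 168-day weight-loss total is split 92 days (grade 1, related) + 76 days
#' (grade 2, unrelated) so that the related any-grade duration sums to 344
#' days; onset days are chosen consistent with the qualitative timeline
#' (Patient A all after day 30; Patient B fatigue episode 1 at day 10 and
#' diarrhea at day 20).
#'
#' @param which `"A"` or `"B"`.
#' @return A one-patient [ae_cohort()].
#' @examples
#' derive_biomarkers(patient_fixture("A"))
#' @export
patient_fixture <- function(which = c("A", "B")) {
  which <- match.arg(which)
  gi <- "Gastrointestinal disorders"
  if (which == "A") {
    events <- tribble(
      ~patient_id, ~term, ~category, ~onset_day, ~resolution_day, ~grade, ~attribution,
      "Patient-A", "Vomiting",       gi,                                  40L,  40L, 1L, "unrelated",
      "Patient-A", "Nausea",         gi,                                  41L,  41L, 1L, "unlikely",
      "Patient-A", "Abdominal pain", gi,                                  50L,  78L, 1L, "unrelated",
      "Patient-A", "Dysgeusia",      "Nervous system disorders",          35L,  98L, 1L, "possible",
      "Patient-A", "Anorexia",       "Metabolism and nutrition disorders", 45L, 232L, 2L, "probable",
      "Patient-A", "Weight loss",    "Investigations",                     60L, 151L, 1L, "possible",
      "Patient-A", "Weight loss",    "Investigations",                    152L, 227L, 2L, "unrelated"
    )
  } else {
    events <- tribble(
      ~patient_id, ~term, ~category, ~onset_day, ~resolution_day, ~grade, ~attribution,
      "Patient-B", "Fatigue",              "General disorders and administration site conditions", 10L,  66L, 1L, "unrelated",
      "Patient-B", "Fatigue",              "General disorders and administration site conditions", 70L, 238L, 2L, "probable",
      "Patient-B", "Creatinine increased", "Investigations",                                        40L, 221L, 1L, "unrelated",
      "Patient-B", "Dyspnea",              "Respiratory, thoracic and mediastinal disorders",       35L, 199L, 2L, "unrelated",
      "Patient-B", "Diarrhea",             gi,                                                      20L,  23L, 3L, "unrelated"
    )
  }
  ae_cohort(events, data_cutoff_day = 365L)
}

#' Combined two-patient worked-example cohort
#'
#' Patients A and B of [patient_fixture()] as one cohort (12 events,
#' 10 unique patient-term pairs of which 2 recur).
#'
#' @return An [ae_cohort()] with 2 patients.
#' @export
ab_fixture_cohort <- function() {
  a <- patient_fixture("A")
  b <- patient_fixture("B")
  ae_cohort(bind_rows(a$events, b$events),
            patients = c(a$patients, b$patients),
            data_cutoff_day = 365L)
}

#' Synthetic clinical rows for the worked-example patients
#'
#' The source figures give no survival or response data for patients A and
#' B, so these two rows are synthetic placeholders that make the combined
#' fixture runnable end to end (I/O and validation examples only; no
#' printed value depends on them).
#'
#' @return A clinical tibble with two rows.
#' @export
fixture_clinical <- function() {
  tribble(
    ~patient_id, ~pfs_months, ~pfs_event, ~os_months, ~os_event, ~best_response, ~dot_months,
    "Patient-A", 5.7, 1L, 10.4, 1L, "SD", 6.0,
    "Patient-B", 1.5, 1L,  2.7, 1L, "PD", 1.0
  )
}
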