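test_that("Patient A reproduces the overall-level worked-example panel", {
  v <- pkg_biomarkers(patient_fixture("A"))
  expect_equal(v[["any_grade.occurrence"]], 1)
  expect_equal(v[["any_grade.n_unique"]], 6)
  expect_equal(v[["any_grade.n_events"]], 7)
  expect_equal(v[["any_grade.duration"]], 451)
  # all events are low grade, so the low-grade block mirrors any-grade
  expect_equal(v[["low_grade.n_unique"]], 6)
  expect_equal(v[["low_grade.n_events"]], 7)
  expect_equal(v[["low_grade.duration"]], 451)
  expect_equal(v[["related_any_grade.n_unique"]], 3)
  expect_equal(v[["related_any_grade.duration"]], 344)
  expect_equal(v[["related_low_grade.duration"]], 344)
  expect_equal(unname(v[c("high_grade.occurrence", "high_grade.n_unique",
                          "high_grade.n_events", "high_grade.duration",
                          "related_high_grade.occurrence",
                          "related_high_grade.n_unique",
                          "related_high_grade.n_events",
                          "related_high_grade.duration")]),
               rep(0, 8))
})

test_that("Patient B reproduces the overall-level worked-example panel", {
  v <- pkg_biomarkers(patient_fixture("B"))
  expect_equal(v[["any_grade.n_unique"]], 4)
  expect_equal(v[["any_grade.n_events"]], 5)
  expect_equal(v[["low_grade.n_unique"]], 3)
  expect_equal(v[["low_grade.n_events"]], 4)
  expect_equal(v[["high_grade.occurrence"]], 1)
  expect_equal(v[["high_grade.n_unique"]], 1)
  expect_equal(v[["high_grade.duration"]], 4)
  # only the grade-2 fatigue episode is treatment related
  expect_equal(v[["related_any_grade.n_unique"]], 1)
  expect_equal(v[["related_any_grade.duration"]], 169)
  expect_equal(v[["related_low_grade.duration"]], 169)
  expect_equal(v[["related_high_grade.occurrence"]], 0)
})

test_that("category and term scopes reproduce the worked-example values", {
  gi <- pkg_biomarkers(patient_fixture("A"),
                       category = "Gastrointestinal disorders")
  expect_equal(gi[["any_grade.n_unique"]], 3)
  expect_equal(gi[["any_grade.n_events"]], 3)
  expect_equal(gi[["any_grade.duration"]], 31)

  wl <- pkg_biomarkers(patient_fixture("A"), term = "Weight loss")
  expect_equal(wl[["any_grade.n_unique"]], 1)
  expect_equal(wl[["any_grade.n_events"]], 2)
  expect_equal(wl[["any_grade.duration"]], 168)

  # per-term durations as printed
  durs <- vapply(c("Vomiting", "Nausea", "Dysgeusia", "Abdominal pain",
                   "Anorexia"),
                 function(tm) pkg_biomarkers(patient_fixture("A"),
                                             term = tm)[["any_grade.duration"]],
                 numeric(1))
  expect_equal(unname(durs), c(1, 1, 64, 29, 188))
})

test_that("the day-30 landmark keeps early onsets only", {
  # Patient A: every onset is after day 30 -> empty early window
  expect_equal(nrow(filter_events(patient_fixture("A"), landmark_day = 30)), 0)
  a30 <- pkg_biomarkers(patient_fixture("A"), landmark_day = 30)
  expect_equal(unname(a30), rep(0, 24))

  # Patient B: exactly fatigue (episode 1) and diarrhea start early
  early <- filter_events(patient_fixture("B"), landmark_day = 30)
  expect_setequal(early$term, c("Fatigue", "Diarrhea"))
  b30 <- pkg_biomarkers(patient_fixture("B"), landmark_day = 30)
  expect_equal(b30[["any_grade.n_unique"]], 2)
  expect_equal(b30[["any_grade.n_events"]], 2)
  # window membership is by onset; full durations count by default
  expect_equal(b30[["any_grade.duration"]], 57 + 4)

  # no landmark is the identity
  expect_equal(nrow(filter_events(patient_fixture("B"))), 5)
})

test_that("durations can optionally be truncated at the landmark", {
  ev <- tibble::tibble(
    patient_id = "P1", term = "Fatigue", category = "General",
    onset_day = 28L, resolution_day = 90L, grade = 1L,
    attribution = "possible")
  coh <- ae_cohort(ev, data_cutoff_day = 120L)
  full <- filter_events(coh, landmark_day = 30)
  expect_equal(full$duration, 63)
  clipped <- filter_events(coh, landmark_day = 30,
                           truncate_at_landmark = TRUE)
  expect_equal(clipped$duration, 3) # days 28, 29, 30
})

test_that("derive_matrix covers every patient at every scope, zeros included", {
  coh <- ab_fixture_cohort()
  overall <- derive_matrix(coh, "overall")
  expect_equal(nrow(overall), 2 * 24)

  by_cat <- derive_matrix(coh, "category")
  # union of distinct category strings across both patients
  expect_equal(dplyr::n_distinct(by_cat$scope_name), 6)
  expect_equal(nrow(by_cat), 6 * 2 * 24)
  # Patient B has no event in A-only categories: zero rows must exist
  zero <- bm_value(by_cat[by_cat$scope_name == "Nervous system disorders", ],
                   "any_grade", "n_events", patient = "Patient-B")
  expect_equal(zero, 0)

  # an explicit scope catalog may include never-observed scopes
  by_term <- derive_matrix(coh, "term",
                           scopes = c("Fatigue", "Never seen term"))
  expect_equal(sum(by_term$scope_name == "Never seen term"), 2 * 24)
  expect_true(all(by_term$value[by_term$scope_name == "Never seen term"] == 0))
})

test_that("unknown scope names warn and yield empty results, not errors", {
  expect_warning(out <- filter_events(patient_fixture("A"),
                                      category = "No such category"),
                 "not present")
  expect_equal(nrow(out), 0)
})

test_that("vectorised derivation matches the brute-force oracle", {
  set.seed(2024)
  for (rep in 1:60) {
    ev <- random_events(sample(0:12, 1))
    coh <- ae_cohort(ev, patients = "P1", data_cutoff_day = 400L)
    expect_equal(pkg_biomarkers(coh), brute_biomarkers(ev))
  }
})

test_that("panel invariants hold on random cohorts", {
  set.seed(77)
  for (rep in 1:10) {
    coh <- random_cohort(12)
    for (lev in c("overall", "category", "term")) {
      bm <- derive_matrix(coh, lev)
      wide <- tidyr::pivot_wider(
        bm, names_from = c("stratum", "measurement"),
        values_from = "value", names_sep = ".")
      for (m in c("n_unique", "n_events", "duration")) {
        if (m != "n_unique") {
          # any = low + high for counts and durations
          expect_equal(wide[[paste0("any_grade.", m)]],
                       wide[[paste0("low_grade.", m)]] +
                         wide[[paste0("high_grade.", m)]])
        }
        # related-only never exceeds all-events
        expect_true(all(wide[[paste0("related_any_grade.", m)]] <=
                          wide[[paste0("any_grade.", m)]]))
      }
      # occurrence is the indicator of a positive event count
      expect_equal(wide$any_grade.occurrence,
                   as.numeric(wide$any_grade.n_events > 0))
      expect_equal(wide$any_grade.occurrence,
                   pmax(wide$low_grade.occurrence,
                        wide$high_grade.occurrence))
      # unique <= events <= duration (every episode lasts >= 1 day)
      expect_true(all(wide$any_grade.n_unique <= wide$any_grade.n_events))
      expect_true(all(wide$any_grade.n_events <= wide$any_grade.duration))
    }
  }
})

test_that("scope levels aggregate consistently and landmarks are monotone", {
  set.seed(99)
  for (rep in 1:6) {
    coh <- random_cohort(10)
    tot <- function(bm) {
      sub <- bm[bm$measurement == "n_events", ]
      as.numeric(tapply(sub$value, sub$stratum, sum))
    }
    overall <- derive_matrix(coh, "overall")
    expect_equal(tot(derive_matrix(coh, "category")), tot(overall))
    expect_equal(tot(derive_matrix(coh, "term")), tot(overall))

    d1 <- derive_matrix(coh, "overall", landmark_day = 30)
    d2 <- derive_matrix(coh, "overall", landmark_day = 75)
    expect_true(all(d1$value <= d2$value))
    expect_true(all(d2$value <=
                      derive_matrix(coh, "overall")$value))
  }
})

test_that("unique counts use terms remaining after stratum filtering", {
  # one term whose only high-grade episode must not leak into low-grade
  ev <- tibble::tibble(
    patient_id = "P1",
    term = c("Diarrhea", "Fatigue"),
    category = "X",
    onset_day = c(0L, 0L), resolution_day = c(1L, 1L),
    grade = c(3L, 1L), attribution = c("possible", "unrelated"))
  v <- pkg_biomarkers(ae_cohort(ev))
  expect_equal(v[["low_grade.n_unique"]], 1)
  expect_equal(v[["related_low_grade.n_unique"]], 0)
  expect_equal(v[["related_high_grade.n_unique"]], 1)
})
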