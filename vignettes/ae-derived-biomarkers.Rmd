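---
title: "AE-derived biomarkers: model, conventions, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AE-derived biomarkers: model, conventions, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Adverse events (AEs) in oncology trials are recorded per episode under
CTCAE: a term (one of ~837), a toxicity category (one of 26 system-organ
classes), an onset and resolution time, a severity grade 1–5, and an
attribution to treatment (definite, probable, possible, unlikely,
unrelated). Standard safety reporting collapses all of this to each
patient's worst grade per term, which discards duration, recurrence, and
changes of grade or relatedness over time — exactly the features that
carry information about treatment effect. aemark turns the raw episode
stream into a fixed panel of per-patient biomarkers and screens them
against clinical outcomes.

## The 24-biomarker panel

Six strata are formed by crossing three grade classes — any grade, low
grade (1–2), high grade (3+) — with two relatedness filters (all events;
treatment-related only, i.e. attribution in {definite, probable,
possible}). Within each stratum, events are filtered *at the episode
level* and then summarised four ways:

* **occurrence** — 0/1, any qualifying episode;
* **n_unique** — number of distinct AE terms among the qualifying
  episodes;
* **n_events** — number of qualifying episodes, recurrences counted;
* **duration** — sum of episode durations in days, recurrences counted.

This yields 24 values per patient per scope, where a scope is the whole
AE stream ("overall"), one toxicity category, or one individual term.
Patients with no qualifying events get an all-zero panel: absence of
toxicity is information, not missingness, so every derived matrix has a
row-set for every cohort patient.

Two semantic points are worth stating because they are easy to get
wrong:

* **Unique counts are stratum-local.** A term whose only high-grade
  episode is filtered out of the low-grade stratum does not count as a
  unique term there. This is forced by the worked example in which a
  patient's only treatment-related episode is the second, grade-2
  episode of a recurring event: the related stratum has unique count 1.
* **Recurrence is term identity.** Two episodes of the same term string
  within a patient are a recurrence regardless of grade or attribution
  changes between episodes.

These definitions make the panel internally consistent, and the test
suite checks the resulting algebra on random cohorts: for counts and
durations, any = low + high and related ≤ all; occurrence is the
indicator of a positive event count; unique ≤ events ≤ duration; and
counts aggregate exactly across scope levels (overall = Σ categories =
Σ terms).

## Day and duration conventions

Days are integer offsets from the first treatment dose (day 0).
Durations are inclusive of both endpoints, `resolution − onset + 1`, so
a same-day episode lasts 1 day. The inclusive convention is the only one
that reproduces the printed one-day vomiting/nausea episodes in the
worked example together with its duration totals; recorded datasets may
follow the exclusive convention, in which case durations should be
shifted on ingest (the column mapping in `read_ae_table()` leaves room
for this). Unresolved episodes are censored at the cohort's data-cutoff
day with a warning; they still count for occurrence and frequency.

## Early windows and guarantee-time bias

A patient who stays on treatment longer mechanically accrues more AEs
and also tends to live longer, so naive whole-course AE summaries are
biased toward "toxicity predicts survival" (guarantee-time bias). The
package's predictor construction is therefore landmarked: an episode
belongs to the early window iff its *onset* is at or before the landmark
day (default 30, roughly the dose-limiting-toxicity window). Membership
is by onset only — an episode starting on day 28 and resolving on day 90
is early, and by default its full duration counts. For users who regard
post-landmark exposure as a residual leak, `truncate_at_landmark = TRUE`
clips durations at the landmark; both behaviours are first-class because
the right choice is a genuine judgement call about how much
post-landmark information a "day-30 biomarker" may legitimately carry.
The landmark day itself is configurable to support sensitivity analyses
(e.g. 2–6 weeks).

## The discovery battery

Each biomarker of each scope is screened against four outcomes:

* **PFS, OS** — univariate Cox proportional hazards, Efron tie
  handling, Wald 95% CI and two-sided Wald p. Covariates enter in raw
  units (per event, per day) so hazard ratios retain their clinical
  reading. Under monotone likelihood (perfect separation) the HR is
  reported as unbounded (0 or Inf) with a log-rank p for the sign,
  rather than a meaningless finite estimate.
* **Disease control** — Welch two-sample t-test of the biomarker mean
  in DC (CR+PR+SD) vs PD; NE patients are excluded from this comparison
  only. Welch rather than pooled because duration-type biomarkers
  rarely share a variance across response groups.
* **Duration of treatment** — Pearson correlation with a two-sided t
  approximation; Spearman is available as an option for users who
  prefer a rank association (the skew of duration data argues either
  way; the linear-correlation default keeps the effect size on the
  familiar r scale).

A scope is modelled only if at least `min_patients_with_event` patients
(default 3) have any event in it; below that floor all 96 of its rows
are emitted with a skip status instead of being dropped, so the results
table always has exactly 96 × (number of scopes) rows and absences are
auditable. Screening uses unadjusted p < 0.05, matching the battery's
role as a hypothesis generator; a Benjamini–Hochberg column is attached
per outcome for reference but deliberately not used for filtering.
Tests within a scope are correlated by construction (any = low + high;
counts and durations share events), so global significance counts
should be read as descriptive, not as a family-wise inference.

## The synthetic cohort generator

`simulate_cohort()` exists so the whole pipeline can be exercised and
calibrated without any external data. Per patient and per catalog term
it draws Poisson episode counts (rate per 30 days scaled to the study
length) plus binomial recurrence re-draws, uniform onsets, catalog
grade and attribution mixes, and log-normal durations floored at 1 day
— right-skewed spans from days to months, like real AE records.
Episodes running past the data cutoff are left unresolved. The default
catalog is a compact immunotherapy-trial mix (fatigue, GI and skin
events, endocrine and laboratory toxicities) with grade mass
concentrated at 1–2.

Outcomes are drawn *after* the AE stream: the generator derives each
patient's true early biomarkers at the configured landmark and feeds
them through exponential proportional-hazards models (PFS, OS, DOT) and
a logistic response model via user-specified effect links. With no
links it is a global null in which AEs and outcomes are independent, so
guarantee-time bias is absent by construction; a `guarantee_bias` mode
deletes episodes with onset after death to let users reproduce the bias
on purpose. Coupling outcomes to the *true* generated biomarkers makes
recovery tests sharp — a recovered HR can be compared directly with the
planted one.

What the generator does not emulate: term–term dependence within a
patient (episodes are independent across terms), seasonal or
cycle-locked onset patterns, informative censoring, or the exact
marginals of any particular trial. Passing tests therefore demonstrate
correctness and calibration of the machinery, not performance claims
about any specific clinical dataset.

## Worked-example fixtures

The two built-in single-patient cohorts reproduce every printed value
of the worked example that defines the panel semantics (episode counts,
unique counts, durations by scope, and the early-window contents). Two
quantities the example leaves implicit were fixed once as package
constants: the recurring weight-loss term's 168-day total is split
92 days (grade 1, related) + 76 days (grade 2, unrelated), the unique
split consistent with the 344-day related total; and onset days are
chosen to match the qualitative timeline (all of Patient A's onsets
after day 30; Patient B's first fatigue episode and diarrhea at or
before day 30). Patient B's published any-grade/low-grade duration
totals are internally inconsistent with the per-episode durations given
alongside them (572/568 vs sums of 577/573); the fixtures follow the
per-episode durations, and the conflicting totals are asserted nowhere.

## Numerical and degenerate-input choices

* Constant covariates and scopes with under-threshold support produce
  typed skip rows, never NA-crashes; two constant equal response groups
  give effect 0, p 1.
* A Cox coefficient past ±15 (or a convergence warning) is treated as
  monotone likelihood and reported as unbounded.
* Ties in survival times use Efron's approximation, the better default
  for the heavily tied short times of small trials.
* Row order of the results table is fully deterministic (scope level,
  scope name, stratum, measurement, outcome), so repeated runs are
  byte-comparable.

## Problem sizes used by the test suite

The suite validates calibration at sizes chosen to be comfortable on a
laptop: parameter recovery uses 100 replicate cohorts of n = 400 with a
planted log-HR of −0.69 on early low-grade occurrence; null calibration
pools ~13,000 modelled tests from one 200-patient cohort with a
120-term catalog; the arity check runs a 50-patient cohort against an
800-term catalog (76,800 result rows); oracle equivalence loops a
brute-force reimplementation over 1,000 random small patients. The
binomial interval used in the null-calibration check assumes
independent tests, which the panel's internal correlation violates
mildly; the many quasi-independent term scopes keep the effective test
count high enough for the check to be meaningful.

## Known limitations

* No time-varying-covariate Cox model and no competing-risks analysis;
  the landmark design is the bias control offered.
* AE terms and categories are taken as given strings — no MedDRA
  normalisation or fuzzy matching.
* The univariate screen ignores the panel's collinearity; any
  multivariable follow-up is out of scope.
* Monte-Carlo-based tests are seeded and deterministic, but their
  thresholds are statistical statements, not proofs.
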