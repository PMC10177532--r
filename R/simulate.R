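#' Default AE term catalog for simulation
#'
#' A compact catalog modelled on what a phase-I immunotherapy trial in
#' advanced NSCLC typically records: mostly low-grade constitutional,
#' gastrointestinal, skin, and laboratory events, a few terms capable of
#' high grades, log-normal durations spanning days to months, and modest
#' recurrence. Rates are events per patient per 30 days on study.
#'
#' @return A tibble with columns `term`, `category`, `rate_per_30d`,
#'   `grade_probs` (list, length-5 each), `attribution_probs` (list,
#'   length-5, order of [ae_attributions()]), `duration_meanlog`,
#'   `duration_sdlog`, `recurrence_prob`.
#' @export
default_term_catalog <- function() {
  row <- function(term, category, rate, gp, ap, mlog, slog, rec) {
    tibble(term = term, category = category, rate_per_30d = rate,
           grade_probs = list(gp), attribution_probs = list(ap),
           duration_meanlog = mlog, duration_sdlog = slog,
           recurrence_prob = rec)
  }
  gi <- "Gastrointestinal disorders"
  gen <- "General disorders and administration site conditions"
  inv <- "Investigations"
  resp <- "Respiratory, thoracic and mediastinal disorders"
  skin <- "Skin and subcutaneous tissue disorders"
  met <- "Metabolism and nutrition disorders"
  low <- c(0.60, 0.30, 0.07, 0.02, 0.01)         # grade mix, low-skewed
  mid <- c(0.45, 0.30, 0.17, 0.06, 0.02)
  rel <- c(0.05, 0.20, 0.35, 0.15, 0.25)         # mostly possibly-related
  unrel <- c(0.01, 0.05, 0.14, 0.25, 0.55)
  bind_rows(
    row("Fatigue", gen, 0.30, low, rel, log(21), 0.9, 0.20),
    row("Nausea", gi, 0.22, low, rel, log(7), 0.9, 0.20),
    row("Diarrhea", gi, 0.15, mid, rel, log(4), 0.8, 0.15),
    row("Vomiting", gi, 0.10, mid, rel, log(2), 0.8, 0.15),
    row("Constipation", gi, 0.12, low, unrel, log(10), 0.9, 0.10),
    row("Anorexia", met, 0.15, low, rel, log(30), 1.0, 0.10),
    row("Dysgeusia", "Nervous system disorders", 0.08, low, rel,
        log(45), 0.8, 0.05),
    row("Headache", "Nervous system disorders", 0.10, low, unrel,
        log(3), 0.8, 0.20),
    row("Dyspnea", resp, 0.12, mid, unrel, log(30), 1.0, 0.10),
    row("Cough", resp, 0.12, low, unrel, log(21), 1.0, 0.10),
    row("Rash maculo-papular", skin, 0.10, low, rel, log(18), 0.9, 0.10),
    row("Pruritus", skin, 0.08, low, rel, log(14), 0.9, 0.10),
    row("Hypothyroidism", "Endocrine disorders", 0.03, low, rel,
        log(90), 0.6, 0.02),
    row("Anemia", "Blood and lymphatic system disorders", 0.12, mid,
        unrel, log(30), 0.9, 0.15),
    row("Platelet count decreased", inv, 0.08, mid, rel, log(7), 0.7, 0.15),
    row("Creatinine increased", inv, 0.06, low, unrel, log(40), 1.0, 0.05),
    row("Alanine aminotransferase increased", inv, 0.06, low, rel,
        log(20), 0.8, 0.10),
    row("Weight loss", inv, 0.08, low, rel, log(60), 0.8, 0.15)
  )
}

#' Build a generic term catalog of arbitrary size
#'
#' Convenience constructor for large simulated batteries (e.g. an
#' 800-term discovery run). Terms are named `"AE term 001"`, ... and
#' spread round-robin over `n_categories` generic toxicity categories.
#'
#' @param n_terms Number of terms.
#' @param rate_per_30d Per-term event rate per 30 days (recycled).
#' @param grade_probs,attribution_probs Length-5 probability vectors.
#' @param duration_meanlog,duration_sdlog Log-normal duration parameters
#'   (days).
#' @param recurrence_prob Per-episode probability of one extra recurrence.
#' @param n_categories Number of toxicity categories to spread terms over.
#' @return A catalog tibble as in [default_term_catalog()].
#' @export
make_term_catalog <- function(n_terms, rate_per_30d = 0.05,
                              grade_probs = c(0.45, 0.30, 0.15, 0.07, 0.03),
                              attribution_probs = c(0.05, 0.20, 0.30,
                                                    0.20, 0.25),
                              duration_meanlog = log(14),
                              duration_sdlog = 1,
                              recurrence_prob = 0.15,
                              n_categories = 26) {
  stopifnot(n_terms >= 1, all(grade_probs >= 0),
            abs(sum(grade_probs) - 1) < 1e-8,
            abs(sum(attribution_probs) - 1) < 1e-8)
  idx <- seq_len(n_terms)
  tibble(
    term = paste0("AE term ", str_pad(idx, width = 3, pad = "0")),
    category = paste0("Toxicity category ",
                      str_pad((idx - 1) %% n_categories + 1, width = 2,
                              pad = "0")),
    rate_per_30d = rep_len(rate_per_30d, n_terms),
    grade_probs = rep(list(grade_probs), n_terms),
    attribution_probs = rep(list(attribution_probs), n_terms),
    duration_meanlog = rep_len(duration_meanlog, n_terms),
    duration_sdlog = rep_len(duration_sdlog, n_terms),
    recurrence_prob = rep_len(recurrence_prob, n_terms)
  )
}

#' Declare a link from a biomarker to an outcome
#'
#' @param stratum One of the six stratum names (see [ae_strata()]).
#' @param measurement One of the four measurement names.
#' @param outcome `"PFS"`, `"OS"`, `"DOT"` (strength = log hazard ratio
#'   per biomarker unit; negative improves the outcome) or `"DC"`
#'   (strength = log odds of disease control per unit).
#' @param strength Numeric link strength.
#' @return One-row effect-link tibble.
#' @examples
#' effect_link("related_low_grade", "occurrence", "PFS", log(0.5))
#' @export
effect_link <- function(stratum, measurement, outcome, strength) {
  stopifnot(stratum %in% stratum_levels(),
            measurement %in% measurement_levels(),
            outcome %in% c("PFS", "OS", "DC", "DOT"))
  tibble(stratum = stratum, measurement = measurement, outcome = outcome,
         strength = strength)
}

#' Simulation configuration
#'
#' Bundles everything [simulate_cohort()] needs: cohort size, the AE term
#' catalog (rates, grade and attribution mixes, log-normal durations,
#' recurrence), the landmark day at which the generator computes the true
#' early biomarkers, proportional-hazards links from those biomarkers to
#' the outcomes, and baseline rates. With no effect links the generator
#' is a global null: AEs and outcomes are drawn independently. Outcomes
#' are drawn *after* the AE stream, so guarantee-time bias is absent by
#' construction; `guarantee_bias = TRUE` switches on a demonstration mode
#' that deletes AE episodes with onset after the patient's death.
#'
#' @param n_patients Number of patients.
#' @param terms Term catalog tibble ([default_term_catalog()] or
#'   [make_term_catalog()]).
#' @param landmark_day Day closing the early window used for the true
#'   linear predictors (default 30).
#' @param data_cutoff_day Study length in days (default 365).
#' @param effect_links Tibble of [effect_link()] rows, or `NULL` for a
#'   null generator.
#' @param pfs_rate,os_rate,dot_rate Baseline exponential rates per month.
#' @param censor_rate Exponential censoring rate per month (0 = admin
#'   censoring at the data cutoff only).
#' @param response_intercept Log odds of disease control at zero
#'   biomarker burden.
#' @param ne_prob Probability a patient is not evaluable for response.
#' @param guarantee_bias Demonstration mode (see above).
#' @param seed Default seed for [simulate_cohort()].
#' @return An `ae_sim_config` list.
#' @export
sim_config <- function(n_patients,
                       terms = default_term_catalog(),
                       landmark_day = 30,
                       data_cutoff_day = 365,
                       effect_links = NULL,
                       pfs_rate = 0.25, os_rate = 0.12, dot_rate = 0.30,
                       censor_rate = 0.02,
                       response_intercept = 0,
                       ne_prob = 0.05,
                       guarantee_bias = FALSE,
                       seed = NULL) {
  stopifnot(n_patients >= 0, landmark_day >= 0, data_cutoff_day > 0,
            pfs_rate > 0, os_rate > 0, dot_rate > 0, censor_rate >= 0,
            ne_prob >= 0, ne_prob <= 1)
  for (gp in terms$grade_probs) {
    stopifnot(length(gp) == 5, all(gp >= 0), abs(sum(gp) - 1) < 1e-6)
  }
  for (ap in terms$attribution_probs) {
    stopifnot(length(ap) == 5, all(ap >= 0), abs(sum(ap) - 1) < 1e-6)
  }
  stopifnot(all(terms$rate_per_30d > 0),
            all(terms$recurrence_prob >= 0 & terms$recurrence_prob <= 1))
  if (!is.null(effect_links)) {
    stopifnot(all(c("stratum", "measurement", "outcome", "strength")
                  %in% names(effect_links)))
  }
  structure(
    list(n_patients = as.integer(n_patients), terms = terms,
         landmark_day = as.integer(landmark_day),
         data_cutoff_day = as.integer(data_cutoff_day),
         effect_links = effect_links,
         pfs_rate = pfs_rate, os_rate = os_rate, dot_rate = dot_rate,
         censor_rate = censor_rate,
         response_intercept = response_intercept, ne_prob = ne_prob,
         guarantee_bias = guarantee_bias, seed = seed),
    class = "ae_sim_config"
  )
}

empty_clinical <- function() {
  tibble(patient_id = character(), pfs_months = numeric(),
         pfs_event = integer(), os_months = numeric(),
         os_event = integer(), best_response = character(),
         dot_months = numeric())
}

#' Simulate an AE cohort with linked clinical outcomes
#'
#' Per patient and catalog term, episode counts are Poisson
#' (`rate_per_30d` scaled to the study length) plus binomial recurrence
#' re-draws of the same term; onsets are uniform over the study; grades,
#' attributions, and log-normal durations (floored at 1 day) are drawn
#' from the catalog; episodes running past the data cutoff are left
#' unresolved. The generator then derives each patient's *true* early
#' biomarkers at the configured landmark and draws PFS, OS, and DOT from
#' exponential proportional-hazards models whose linear predictors apply
#' the configured effect links, response from a logistic model, and
#' censoring from an independent exponential plus administrative cutoff.
#'
#' @param config An [sim_config()] object.
#' @param seed Integer seed; defaults to `config$seed`. The draw is fully
#'   reproducible given the seed.
#' @return An `ae_sim` list: `cohort` ([ae_cohort()]), `clinical`
#'   (tibble), and `truth` (effect links, per-patient linear predictors,
#'   the config, and an `infeasible` flag set when survival is so short
#'   that the whole cohort dies before the landmark).
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 20, seed = 1))
#' sim$cohort
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "ae_sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_patients
  cutoff <- config$data_cutoff_day
  patients <- if (n > 0) sprintf("SIM-%04d", seq_len(n)) else character()
  if (n == 0) {
    cohort <- ae_cohort(
      tibble(patient_id = character(), term = character(),
             category = character(), onset_day = integer(),
             resolution_day = integer(), grade = integer(),
             attribution = character()),
      patients = character(), data_cutoff_day = cutoff)
    return(structure(list(cohort = cohort, clinical = empty_clinical(),
                          truth = list(effect_links = config$effect_links,
                                       config = config,
                                       infeasible = FALSE)),
                     class = "ae_sim"))
  }

  gen_term <- function(i) {
    trow <- config$terms[i, ]
    n0 <- rpois(n, trow$rate_per_30d * (cutoff + 1) / 30)
    extra <- rbinom(n, n0, trow$recurrence_prob)
    cnt <- n0 + extra
    tot <- sum(cnt)
    if (tot == 0) return(NULL)
    onset <- sample.int(cutoff + 1L, tot, replace = TRUE) - 1L
    dur <- pmax(1L, as.integer(round(rlnorm(tot, trow$duration_meanlog,
                                            trow$duration_sdlog))))
    res <- onset + dur - 1L
    tibble(
      patient_id = rep(patients, cnt),
      term = trow$term,
      category = trow$category,
      onset_day = onset,
      resolution_day = ifelse(res > cutoff, NA_integer_, res),
      grade = sample.int(5L, tot, replace = TRUE,
                         prob = trow$grade_probs[[1]]),
      attribution = sample(ae_attributions(), tot, replace = TRUE,
                           prob = trow$attribution_probs[[1]])
    )
  }
  events <- list_rbind(map(seq_len(nrow(config$terms)), gen_term))
  if (is.null(events) || nrow(events) == 0) {
    events <- tibble(patient_id = character(), term = character(),
                     category = character(), onset_day = integer(),
                     resolution_day = integer(), grade = integer(),
                     attribution = character())
  }
  cohort <- ae_cohort(events, patients = patients,
                      data_cutoff_day = cutoff)

  # true early biomarkers drive the outcome models
  bm <- suppressWarnings(
    derive_matrix(cohort, "overall", landmark_day = config$landmark_day))
  wide <- biomarker_wide(bm)
  wide <- wide[match(patients, wide$patient_id), ]
  lp_for <- function(outcome) {
    links <- config$effect_links
    lp <- rep(0, n)
    if (is.null(links)) return(lp)
    links <- links[links$outcome == outcome, , drop = FALSE]
    for (k in seq_len(nrow(links))) {
      col <- paste(links$stratum[k], links$measurement[k], sep = ".")
      lp <- lp + links$strength[k] * wide[[col]]
    }
    lp
  }
  lp <- tibble(patient_id = patients, PFS = lp_for("PFS"),
               OS = lp_for("OS"), DC = lp_for("DC"), DOT = lp_for("DOT"))

  months_admin <- cutoff / 30.4375
  draw_surv <- function(base_rate, lp_out) {
    t_true <- rexp(n, rate = base_rate * exp(lp_out))
    cens <- if (config$censor_rate > 0) rexp(n, config$censor_rate)
            else rep(Inf, n)
    cens <- pmin(cens, months_admin)
    tibble(time = round(pmin(t_true, cens), 4),
           event = as.integer(t_true <= cens))
  }
  pfs <- draw_surv(config$pfs_rate, lp$PFS)
  os <- draw_surv(config$os_rate, lp$OS)
  dot <- round(pmin(rexp(n, config$dot_rate * exp(lp$DOT)), months_admin), 4)
  p_dc <- plogis(config$response_intercept + lp$DC)
  dc <- rbinom(n, 1, p_dc) == 1
  ne <- runif(n) < config$ne_prob
  best_response <- ifelse(
    ne, "NE",
    ifelse(dc,
           sample(c("CR", "PR", "SD"), n, replace = TRUE,
                  prob = c(0.08, 0.12, 0.80)),
           "PD"))
  clinical <- tibble(
    patient_id = patients,
    pfs_months = pfs$time, pfs_event = pfs$event,
    os_months = os$time, os_event = os$event,
    best_response = best_response,
    dot_months = dot
  )

  infeasible <- max(os$time) * 30.4375 < config$landmark_day
  if (infeasible) {
    warn("all simulated patients die before the landmark day; config looks infeasible")
  }
  if (config$guarantee_bias) {
    keep <- cohort$events$onset_day <=
      os$time[match(cohort$events$patient_id, patients)] * 30.4375
    cohort <- ae_cohort(cohort$events[keep, , drop = FALSE],
                        patients = patients, data_cutoff_day = cutoff)
  }
  structure(
    list(cohort = cohort, clinical = clinical,
         truth = list(effect_links = config$effect_links,
                      linear_predictors = lp, config = config,
                      infeasible = infeasible)),
    class = "ae_sim"
  )
}

#' @export
print.ae_sim <- function(x, ...) {
  cat("<ae_sim> ", length(x$cohort$patients), " patients, ",
      nrow(x$cohort$events), " AE events, ",
      if (is.null(x$truth$effect_links)) "null generator"
      else paste0(nrow(x$truth$effect_links), " effect link(s)"),
      "\n", sep = "")
  invisible(x)
}

#' Descriptive snapshot of an AE cohort
#'
#' Marginal summaries used to check that a simulated cohort hits its
#' configured mix: events per patient, the high-grade and
#' treatment-related fractions, mean episode duration, and the fraction
#' of patient-term pairs that recur (>= 2 episodes of the same term in
#' the same patient).
#'
#' @param cohort An [ae_cohort()].
#' @return One-row tibble of summaries (zeros for an empty cohort).
#' @examples
#' cohort_snapshot_stats(ab_fixture_cohort())
#' @export
cohort_snapshot_stats <- function(cohort) {
  cohort <- as_ae_cohort(cohort)
  ev <- cohort$events
  if (nrow(ev) == 0) {
    return(tibble(n_patients = length(cohort$patients), n_events = 0L,
                  events_per_patient = 0, high_grade_fraction = 0,
                  related_fraction = 0, mean_duration = 0,
                  recurrence_fraction = 0))
  }
  ev <- suppressWarnings(event_durations(classify_events(ev),
                                         cohort$data_cutoff_day))
  pairs <- count(ev, .data$patient_id, .data$term)
  tibble(
    n_patients = length(cohort$patients),
    n_events = nrow(ev),
    events_per_patient = nrow(ev) / max(length(cohort$patients), 1),
    high_grade_fraction = mean(ev$grade_class == "high"),
    related_fraction = mean(ev$related),
    mean_duration = mean(ev$duration),
    recurrence_fraction = mean(pairs$n >= 2)
  )
}

#' Write a simulated dataset to disk
#'
#' Writes the standard AE CSV, the clinical CSV, and the generating truth
#' as JSON into a directory.
#'
#' @param sim An `ae_sim` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_ae_table(sim$cohort, file.path(dir, "ae_events.csv"))
  write_csv(sim$clinical, file.path(dir, "clinical.csv"), progress = FALSE)
  truth <- list(
    effect_links = sim$truth$effect_links %||%
      tibble(stratum = character(), measurement = character(),
             outcome = character(), strength = numeric()),
    infeasible = sim$truth$infeasible,
    n_patients = length(sim$cohort$patients),
    landmark_day = sim$truth$config$landmark_day,
    data_cutoff_day = sim$truth$config$data_cutoff_day,
    seed = sim$truth$config$seed
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
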