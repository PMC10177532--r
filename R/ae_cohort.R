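ae_event_columns <- function() {
  c("patient_id", "term", "category", "onset_day", "resolution_day",
    "grade", "attribution")
}

#' Construct an AE cohort
#'
#' An `ae_cohort` bundles an event table (one row per AE episode) with the
#' patient universe and a data-cutoff day. The patient set is kept
#' separately from the events because patients with zero recorded events
#' are informative (their biomarkers are all zero) and must stay in every
#' derived matrix.
#'
#' Days are integer offsets from the first treatment dose (day 0). An
#' episode's duration is inclusive of both endpoints:
#' `resolution_day - onset_day + 1`, so a same-day event lasts 1 day.
#' Unresolved episodes carry `resolution_day = NA` and are censored at
#' `data_cutoff_day` when durations are computed.
#'
#' @param events Data frame with columns `patient_id`, `term`, `category`,
#'   `onset_day`, `resolution_day`, `grade`, `attribution`.
#' @param patients Character vector of patient ids; defaults to the ids
#'   present in `events`. May be a superset of those.
#' @param data_cutoff_day Integer day used to censor unresolved events;
#'   defaults to the largest day seen in the data.
#' @return An object of class `ae_cohort`: a list with elements `events`
#'   (tibble, input row order preserved), `patients`, `data_cutoff_day`.
#' @examples
#' coh <- patient_fixture("A")
#' coh
#' @export
ae_cohort <- function(events, patients = NULL, data_cutoff_day = NULL) {
  events <- as_tibble(events)
  missing_cols <- setdiff(ae_event_columns(), names(events))
  if (length(missing_cols) > 0) {
    abort(paste0("events is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  events <- mutate(
    events,
    patient_id = as.character(.data$patient_id),
    term = as.character(.data$term),
    category = as.character(.data$category),
    onset_day = as.integer(.data$onset_day),
    resolution_day = as.integer(.data$resolution_day),
    grade = as.integer(.data$grade),
    attribution = str_to_lower(str_trim(as.character(.data$attribution)))
  )
  patients <- as.character(patients %||% unique(events$patient_id))
  stray <- setdiff(unique(events$patient_id), patients)
  if (length(stray) > 0) {
    abort(paste0("events reference patient ids outside `patients`: ",
                 paste(head(stray, 5), collapse = ", ")))
  }
  if (is.null(data_cutoff_day)) {
    data_cutoff_day <- max(c(events$onset_day, events$resolution_day, 0L),
                           na.rm = TRUE)
  }
  structure(
    list(events = events, patients = patients,
         data_cutoff_day = as.integer(data_cutoff_day)),
    class = "ae_cohort"
  )
}

#' @export
print.ae_cohort <- function(x, ...) {
  cat("<ae_cohort> ", length(x$patients), " patients, ",
      nrow(x$events), " AE events (",
      dplyr::n_distinct(x$events$term), " terms, ",
      dplyr::n_distinct(x$events$category), " categories), data cutoff day ",
      x$data_cutoff_day, "\n", sep = "")
  invisible(x)
}

#' Event durations in days
#'
#' Inclusive-day durations; unresolved events (NA resolution) are censored
#' at the cohort data-cutoff day with a warning.
#'
#' @param events Event tibble.
#' @param data_cutoff_day Censoring day for unresolved events.
#' @return The events with a `duration` column (days, always >= 1).
#' @export
event_durations <- function(events, data_cutoff_day) {
  events <- as_tibble(events)
  unresolved <- is.na(events$resolution_day)
  if (any(unresolved)) {
    warn(paste0(sum(unresolved), " unresolved event(s) censored at day ",
                data_cutoff_day))
  }
  mutate(
    events,
    duration = ifelse(is.na(.data$resolution_day),
                      data_cutoff_day - .data$onset_day + 1L,
                      .data$resolution_day - .data$onset_day + 1L)
  )
}

check_ae_rows <- function(events) {
  errs <- list()
  add <- function(rows, rule, msg) {
    if (length(rows) > 0) {
      errs[[length(errs) + 1]] <<- tibble(row = as.integer(rows), rule = rule,
                                          message = msg)
    }
  }
  add(which(is.na(events$onset_day)), "onset_day", "onset day is missing or not an integer")
  add(which(events$onset_day < 0), "onset_day", "onset day is negative")
  add(which(!is.na(events$resolution_day) &
              events$resolution_day < events$onset_day),
      "resolution_day", "resolution before onset")
  add(which(is.na(events$grade) | !events$grade %in% 1:5),
      "grade", "grade must be an integer in 1..5")
  add(which(!events$attribution %in% ae_attributions()),
      "attribution",
      paste0("attribution must be one of: ",
             paste(ae_attributions(), collapse = ", ")))
  if (length(errs) == 0) {
    tibble(row = integer(), rule = character(), message = character())
  } else {
    bind_rows(errs)
  }
}

#' Read an AE event table from CSV
#'
#' Reads one row per AE episode. Two day conventions are supported:
#' integer day offsets (`onset_day`, `resolution_day`; first dose = day 0)
#' or calendar dates (`onset_date`, `resolution_date`) together with a
#' per-patient treatment start date, which are converted to day offsets.
#' Reading a file already in day-offset mode is the identity on all values.
#'
#' @param path CSV file with a header row.
#' @param col_map Optional named character vector renaming file columns to
#'   the standard names, e.g. `c(patient_id = "SUBJID", term = "AETERM")`.
#'   Names are the standard names, values the file's column names.
#' @param treatment_start Optional data frame (or CSV path) with columns
#'   `patient_id` and `treatment_start_date`; required in date mode.
#' @param data_cutoff_day Passed to [ae_cohort()].
#' @return An [ae_cohort()]. Unresolved events (empty resolution field)
#'   carry `resolution_day = NA`.
#' @export
read_ae_table <- function(path, col_map = NULL, treatment_start = NULL,
                          data_cutoff_day = NULL) {
  raw <- read_csv(path, col_types = cols(.default = "c"),
                  trim_ws = TRUE, progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!src %in% names(raw)) {
        abort(paste0("column mapping refers to missing column '", src, "'"))
      }
      names(raw)[names(raw) == src] <- std
    }
  }
  date_mode <- "onset_date" %in% names(raw)
  needed <- c("patient_id", "term", "category", "grade", "attribution",
              if (date_mode) c("onset_date", "resolution_date")
              else c("onset_day", "resolution_day"))
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("AE table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) {
    return(ae_cohort(
      tibble(patient_id = character(), term = character(),
             category = character(), onset_day = integer(),
             resolution_day = integer(), grade = integer(),
             attribution = character()),
      patients = character(),
      data_cutoff_day = data_cutoff_day %||% 0L
    ))
  }
  if (date_mode) {
    if (is.null(treatment_start)) {
      abort("date-mode AE table requires `treatment_start`")
    }
    if (is.character(treatment_start)) {
      treatment_start <- read_csv(treatment_start,
                                  col_types = cols(.default = "c"),
                                  progress = FALSE)
    }
    ts <- setNames(as.Date(treatment_start$treatment_start_date),
                   as.character(treatment_start$patient_id))
    no_start <- setdiff(unique(raw$patient_id), names(ts))
    if (length(no_start) > 0) {
      abort(paste0("no treatment start date for patient(s): ",
                   paste(head(no_start, 5), collapse = ", ")))
    }
    start <- ts[raw$patient_id]
    raw$onset_day <- as.integer(as.Date(raw$onset_date) - start)
    raw$resolution_day <- ifelse(
      is.na(raw$resolution_date) | raw$resolution_date == "",
      NA_integer_,
      as.integer(as.Date(raw$resolution_date) - start)
    )
  }
  grade_num <- suppressWarnings(as.integer(raw$grade))
  bad_grade <- which(!is.na(raw$grade) & raw$grade != "" & is.na(grade_num))
  if (length(bad_grade) > 0) {
    abort(paste0("unparsable grade at data row(s): ",
                 paste(head(bad_grade, 5), collapse = ", ")))
  }
  onset_num <- suppressWarnings(as.integer(raw$onset_day))
  res_chr <- as.character(raw$resolution_day)
  res_num <- suppressWarnings(
    ifelse(is.na(res_chr) | res_chr %in% c("", "NA", "unresolved", "ongoing"),
           NA_integer_, as.integer(res_chr))
  )
  events <- tibble(
    patient_id = as.character(raw$patient_id),
    term = as.character(raw$term),
    category = as.character(raw$category),
    onset_day = onset_num,
    resolution_day = res_num,
    grade = grade_num,
    attribution = str_to_lower(str_trim(as.character(raw$attribution)))
  )
  errs <- check_ae_rows(events)
  if (nrow(errs) > 0) {
    abort(paste0(
      "invalid AE rows:\n",
      paste0("  row ", errs$row, " [", errs$rule, "]: ", errs$message,
             collapse = "\n")
    ))
  }
  ae_cohort(events, data_cutoff_day = data_cutoff_day)
}

#' Write an AE cohort back to CSV (day-offset mode)
#'
#' @param cohort An [ae_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ae_table <- function(cohort, path) {
  write_csv(cohort$events, path, progress = FALSE)
  invisible(path)
}

#' Read a clinical outcomes table from CSV
#'
#' One row per patient with progression-free survival (PFS) and overall
#' survival (OS) times in months plus 0/1 event flags, RECIST best
#' response, and duration of treatment (DOT) in months. Best responses are
#' normalised to upper case; `NE` (not evaluable) patients are retained
#' for the survival and DOT analyses but excluded from the disease-control
#' comparison downstream.
#'
#' @param path CSV with header columns `patient_id`, `pfs_months`,
#'   `pfs_event`, `os_months`, `os_event`, `best_response`, `dot_months`.
#' @return A tibble, one row per patient.
#' @export
read_clinical_table <- function(path) {
  raw <- read_csv(path, col_types = cols(.default = "c"),
                  trim_ws = TRUE, progress = FALSE)
  needed <- c("patient_id", "pfs_months", "pfs_event", "os_months",
              "os_event", "best_response", "dot_months")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("clinical table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  clin <- tibble(
    patient_id = as.character(raw$patient_id),
    pfs_months = as.numeric(raw$pfs_months),
    pfs_event = as.integer(raw$pfs_event),
    os_months = as.numeric(raw$os_months),
    os_event = as.integer(raw$os_event),
    best_response = str_to_upper(str_trim(raw$best_response)),
    dot_months = as.numeric(raw$dot_months)
  )
  dup <- clin$patient_id[duplicated(clin$patient_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate patient_id in clinical table: ",
                 paste(unique(dup), collapse = ", ")))
  }
  neg <- with(clin, which(pfs_months < 0 | os_months < 0 | dot_months < 0))
  if (length(neg) > 0) {
    abort(paste0("negative times at data row(s): ",
                 paste(head(neg, 5), collapse = ", ")))
  }
  bad_resp <- which(!clin$best_response %in% c("CR", "PR", "SD", "PD", "NE"))
  if (length(bad_resp) > 0) {
    abort(paste0("unparsable best_response at data row(s): ",
                 paste(head(bad_resp, 5), collapse = ", ")))
  }
  bad_flag <- which(!clin$pfs_event %in% 0:1 | !clin$os_event %in% 0:1)
  if (length(bad_flag) > 0) {
    abort(paste0("event flags must be 0/1; bad data row(s): ",
                 paste(head(bad_flag, 5), collapse = ", ")))
  }
  if (any(clin$pfs_months > clin$os_months)) {
    warn("some patients have pfs_months > os_months; kept as recorded")
  }
  clin
}

#' Map best response to the disease-control grouping
#'
#' Disease control (DC) is CR + PR + SD; progressive disease (PD) stands
#' alone; NE (not evaluable) yields `NA` and is excluded from response
#' analyses.
#'
#' @param best_response Character vector of RECIST best responses.
#' @return Character vector of `"DC"`, `"PD"`, or `NA`.
#' @examples
#' response_group(c("CR", "SD", "PD", "NE"))
#' @export
response_group <- function(best_response) {
  x <- str_to_upper(str_trim(as.character(best_response)))
  dplyr::case_when(
    x %in% c("CR", "PR", "SD") ~ "DC",
    x == "PD" ~ "PD",
    TRUE ~ NA_character_
  )
}

#' Validate an AE cohort against a clinical table
#'
#' Collects domain violations as error rows (grade outside 1..5, unknown
#' attribution, resolution before onset, negative onset) and cross-check
#' findings as warnings (patients present in only one of the two tables,
#' unresolved events). The cohort is acceptable iff there are no errors.
#'
#' @param cohort An [ae_cohort()].
#' @param clinical Optional clinical tibble from [read_clinical_table()].
#' @return An `ae_validation` object: list with `errors` (tibble: row,
#'   rule, message), `warnings` (character), and counts `n_patients`,
#'   `n_events`, `n_terms`, `n_categories`.
#' @examples
#' validate_cohort(patient_fixture("A"))
#' @export
validate_cohort <- function(cohort, clinical = NULL) {
  errors <- check_ae_rows(cohort$events)
  warnings <- character()
  unresolved <- sum(is.na(cohort$events$resolution_day))
  if (unresolved > 0) {
    warnings <- c(warnings, paste0(
      unresolved, " unresolved event(s) will be censored at day ",
      cohort$data_cutoff_day))
  }
  if (!is.null(clinical)) {
    only_ae <- setdiff(cohort$patients, clinical$patient_id)
    only_clin <- setdiff(clinical$patient_id, cohort$patients)
    if (length(only_ae) > 0) {
      warnings <- c(warnings, paste0(
        length(only_ae), " patient(s) with AE rows but no clinical row: ",
        paste(head(only_ae, 5), collapse = ", ")))
    }
    if (length(only_clin) > 0) {
      warnings <- c(warnings, paste0(
        length(only_clin),
        " patient(s) with a clinical row but no AE rows ",
        "(kept; biomarkers will be zero): ",
        paste(head(only_clin, 5), collapse = ", ")))
    }
  }
  structure(
    list(
      errors = errors,
      warnings = warnings,
      n_patients = length(cohort$patients),
      n_events = nrow(cohort$events),
      n_terms = dplyr::n_distinct(cohort$events$term),
      n_categories = dplyr::n_distinct(cohort$events$category)
    ),
    class = "ae_validation"
  )
}

#' @export
print.ae_validation <- function(x, ...) {
  cat("<ae_validation> ", x$n_patients, " patients, ", x$n_events,
      " events, ", x$n_terms, " terms, ", x$n_categories, " categories\n",
      sep = "")
  if (nrow(x$errors) == 0) {
    cat("  errors: none (cohort accepted)\n")
  } else {
    cat("  errors: ", nrow(x$errors), "\n", sep = "")
    for (i in seq_len(min(nrow(x$errors), 10))) {
      cat("    row ", x$errors$row[i], " [", x$errors$rule[i], "]: ",
          x$errors$message[i], "\n", sep = "")
    }
  }
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}
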