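result_skip <- function(status, effect_kind, n_used) {
  tibble(effect_kind = effect_kind, effect = NA_real_, ci_low = NA_real_,
         ci_high = NA_real_, p_value = NA_real_, n_used = as.integer(n_used),
         status = status)
}

#' Univariate Cox proportional-hazards screen
#'
#' Fits a single-covariate Cox model (Efron tie handling) and reports the
#' hazard ratio per unit of the covariate with a Wald 95% CI and two-sided
#' Wald p. Covariates are entered in raw units (per event, per day), so
#' the HR keeps its natural clinical reading. Under monotone likelihood
#' (e.g. perfect separation) the HR is unbounded: the fit is reported with
#' an infinite (or zero) effect, no CI, and a log-rank p for the sign of
#' the association.
#'
#' @param x Numeric biomarker values, one per patient.
#' @param time Survival time in months.
#' @param event 0/1 event indicator (1 = event observed).
#' @return One-row tibble: `effect_kind = "hazard_ratio"`, `effect`,
#'   `ci_low`, `ci_high`, `p_value`, `n_used`, `status`. `status` is
#'   `"skipped_constant"` for a constant covariate and `"skipped_sparse"`
#'   with fewer than 2 observed events.
#' @examples
#' clin <- simulate_cohort(sim_config(n_patients = 80, seed = 7))$clinical
#' cox_univariate(rnorm(80), clin$pfs_months, clin$pfs_event)
#' @export
cox_univariate <- function(x, time, event) {
  stopifnot(length(x) == length(time), length(x) == length(event))
  ok <- complete.cases(x, time, event)
  x <- x[ok]; time <- time[ok]; event <- event[ok]
  if (length(x) == 0 || diff(range(x)) == 0) {
    return(result_skip("skipped_constant", "hazard_ratio", length(x)))
  }
  if (sum(event) < 2) {
    return(result_skip("skipped_sparse", "hazard_ratio", length(x)))
  }
  diverged <- FALSE
  fit <- withCallingHandlers(
    coxph(Surv(time, event) ~ x, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|not converge|beta may be infinite",
                conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(diag(fit$var))[1]
  if (diverged || !is.finite(beta) || abs(beta) > 15) {
    # monotone likelihood: report the direction with a log-rank p instead
    grp <- x > min(x)
    sd <- survdiff(Surv(time, event) ~ grp)
    p <- 1 - pchisq(sd$chisq, length(sd$n) - 1)
    warn("Cox likelihood is monotone; hazard ratio unbounded, log-rank p reported")
    return(tibble(effect_kind = "hazard_ratio",
                  effect = if (beta > 0) Inf else 0,
                  ci_low = NA_real_, ci_high = NA_real_,
                  p_value = p, n_used = length(x), status = "ok"))
  }
  z <- beta / se
  tibble(
    effect_kind = "hazard_ratio",
    effect = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    n_used = length(x),
    status = "ok"
  )
}

#' Kaplan-Meier curves and log-rank test for an occurrence split
#'
#' Splits patients by a 0/1 occurrence indicator, computes product-limit
#' survival estimates, per-group medians, the two-group log-rank test, and
#' an at-risk table at regular time ticks.
#'
#' @param occurrence 0/1 per patient (e.g. an occurrence biomarker).
#' @param time,event Survival time (months) and 0/1 event flag.
#' @param labels Group labels for occurrence 0 and 1.
#' @param tick_every Spacing of at-risk table ticks, in months.
#' @return A `km_summary` object; see [tidy.km_summary()] and
#'   [glance.km_summary()]. The log-rank p is `NA` when only one group is
#'   present; a group whose curve never crosses 0.5 has median `NA`.
#' @examples
#' km <- km_logrank(c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1),
#'                  c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), rep(1, 10))
#' glance(km)
#' @export
km_logrank <- function(occurrence, time, event,
                       labels = c("without AE", "with AE"),
                       tick_every = 5) {
  stopifnot(length(occurrence) == length(time),
            length(time) == length(event))
  ok <- complete.cases(occurrence, time, event)
  grp <- factor(ifelse(occurrence[ok] > 0, labels[2], labels[1]),
                levels = labels)
  grp <- droplevels(grp)
  time <- time[ok]; event <- event[ok]
  dat <- data.frame(time = time, event = event, grp = grp)
  fit <- survfit(Surv(time, event) ~ grp, data = dat)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list("all", names(tab)))
  medians <- setNames(as.numeric(tab[, "median"]),
                      sub("^grp=", "", rownames(tab)))
  if (nlevels(grp) == 2) {
    sd <- survdiff(Surv(time, event) ~ grp, data = dat)
    chisq <- sd$chisq
    p <- 1 - pchisq(chisq, 1)
  } else {
    chisq <- NA_real_
    p <- NA_real_
  }
  ticks <- seq(0, ceiling(max(time)), by = tick_every)
  sm <- summary(fit, times = ticks, extend = TRUE)
  strata <- if (is.null(sm$strata)) rep(levels(grp)[1], length(sm$time))
            else sub("^grp=", "", as.character(sm$strata))
  at_risk <- tibble(group = strata, time = sm$time, n_risk = sm$n.risk)
  structure(
    list(fit = fit, data = dat, medians = medians,
         logrank_chisq = chisq, logrank_p = p, at_risk = at_risk,
         n = table(grp)),
    class = "km_summary"
  )
}

#' @describeIn km_logrank Per-group medians and sizes as a tibble.
#' @param x A `km_summary`.
#' @param ... Unused.
#' @method tidy km_summary
#' @export
tidy.km_summary <- function(x, ...) {
  tibble(group = names(x$medians),
         n = as.integer(x$n[names(x$medians)]),
         median = as.numeric(x$medians))
}

#' @describeIn km_logrank One-row log-rank summary.
#' @method glance km_summary
#' @export
glance.km_summary <- function(x, ...) {
  tibble(statistic = x$logrank_chisq, df = 1, p_value = x$logrank_p,
         n = sum(x$n))
}

#' @export
print.km_summary <- function(x, ...) {
  cat("<km_summary> groups:",
      paste0(names(x$medians), " (n=", as.integer(x$n[names(x$medians)]),
             ", median=", signif(x$medians, 3), ")", collapse = ", "),
      "\n  log-rank p =", format.pval(x$logrank_p, digits = 3), "\n")
  invisible(x)
}

#' Welch t-test of a biomarker between disease control and progression
#'
#' Compares mean biomarker values between the disease-control (DC = CR +
#' PR + SD) and progressive-disease (PD) groups. The effect is
#' `mean(DC) - mean(PD)`, so positive values mean more/longer AEs among
#' controlled patients. Unequal variances are assumed (Welch), since
#' duration-type biomarkers rarely share a variance across groups. NE
#' patients must already be excluded (their group is `NA`, which is
#' dropped here).
#'
#' @param x Numeric biomarker values.
#' @param response `"DC"`/`"PD"` per patient (see [response_group()]).
#' @return One-row tibble with `effect_kind = "mean_difference"`.
#'   Fewer than 2 patients in either group gives `status =
#'   "skipped_sparse"`; two identical constant groups give effect 0,
#'   p 1.
#' @export
ttest_response <- function(x, response) {
  stopifnot(length(x) == length(response))
  keep <- !is.na(response) & response %in% c("DC", "PD") & !is.na(x)
  x <- x[keep]; response <- response[keep]
  x_dc <- x[response == "DC"]; x_pd <- x[response == "PD"]
  if (length(x_dc) < 2 || length(x_pd) < 2) {
    return(result_skip("skipped_sparse", "mean_difference", length(x)))
  }
  eff <- mean(x_dc) - mean(x_pd)
  if (stats::sd(x_dc) == 0 && stats::sd(x_pd) == 0) {
    return(tibble(effect_kind = "mean_difference", effect = eff,
                  ci_low = eff, ci_high = eff,
                  p_value = if (eff == 0) 1 else 0,
                  n_used = length(x), status = "ok"))
  }
  tt <- t.test(x_dc, x_pd, var.equal = FALSE)
  tibble(
    effect_kind = "mean_difference",
    effect = eff,
    ci_low = tt$conf.int[1],
    ci_high = tt$conf.int[2],
    p_value = tt$p.value,
    n_used = length(x),
    status = "ok"
  )
}

#' Correlation of a biomarker with duration of treatment
#'
#' Pearson correlation (default) of a biomarker with treatment duration,
#' two-sided p from the t approximation. Spearman is available for users
#' who prefer a rank association for skewed duration data.
#'
#' @param x Numeric biomarker values.
#' @param dot Duration of treatment in months.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return One-row tibble with `effect_kind = "pearson_r"` (or
#'   `"spearman_rho"`). Needs `n >= 3` and non-constant inputs, else a
#'   skip-status row.
#' @export
pearson_dot <- function(x, dot, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  kind <- if (method == "pearson") "pearson_r" else "spearman_rho"
  stopifnot(length(x) == length(dot))
  ok <- complete.cases(x, dot)
  x <- x[ok]; dot <- dot[ok]
  if (length(x) < 3) {
    return(result_skip("skipped_sparse", kind, length(x)))
  }
  if (diff(range(x)) == 0 || diff(range(dot)) == 0) {
    return(result_skip("skipped_constant", kind, length(x)))
  }
  ct <- suppressWarnings(cor.test(x, dot, method = method))
  tibble(
    effect_kind = kind,
    effect = unname(ct$estimate),
    ci_low = if (!is.null(ct$conf.int)) ct$conf.int[1] else NA_real_,
    ci_high = if (!is.null(ct$conf.int)) ct$conf.int[2] else NA_real_,
    p_value = ct$p.value,
    n_used = length(x),
    status = "ok"
  )
}

outcome_levels <- function() c("PFS", "OS", "DC_vs_PD", "DOT")

skip_scope_rows <- function(n_used) {
  crossing(
    stratum = factor(stratum_levels(), levels = stratum_levels()),
    measurement = factor(measurement_levels(),
                         levels = measurement_levels()),
    outcome = factor(outcome_levels(), levels = outcome_levels())
  ) |>
    mutate(
      effect_kind = dplyr::case_when(
        outcome %in% c("PFS", "OS") ~ "hazard_ratio",
        outcome == "DC_vs_PD" ~ "mean_difference",
        TRUE ~ "pearson_r"
      ),
      effect = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      p_value = NA_real_, n_used = as.integer(n_used),
      status = "skipped_sparse"
    )
}

#' Run the global discovery battery
#'
#' Evaluates every biomarker of every scope against the four clinical
#' outcomes: Cox models for PFS and OS, a Welch t-test of DC vs PD, and
#' correlation with duration of treatment — 24 biomarkers x 4 outcomes =
#' 96 result rows per scope, skip-status rows included, so the row count
#' is exactly `96 * n_scopes`. Scopes in which fewer than
#' `min_patients_with_event` patients have any event are not modelled
#' (all 96 rows get `status = "skipped_sparse"`); sparse individual AEs
#' are the norm, so this floor defaults to 3 patients.
#'
#' Only patients present in both the biomarker table and the clinical
#' table are used; the intersection is reported via a message.
#'
#' @param biomarkers Long biomarker tibble from [derive_matrix()]
#'   (several levels may be row-bound first).
#' @param clinical Clinical tibble as from [read_clinical_table()].
#' @param min_patients_with_event Minimum number of patients with at
#'   least one any-grade event for a scope to be modelled.
#' @param alpha Significance threshold recorded in the provenance and
#'   used by downstream summaries.
#' @param dot_method Correlation method for DOT, `"pearson"` or
#'   `"spearman"`.
#' @return An `ae_results` tibble: one row per (scope, stratum,
#'   measurement, outcome), deterministically ordered, with a
#'   `provenance` attribute recording the options.
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 40, seed = 11))
#' bm <- derive_matrix(sim$cohort, "overall", landmark_day = 30)
#' res <- run_discovery(bm, sim$clinical)
#' glance(res)
#' @export
run_discovery <- function(biomarkers, clinical,
                          min_patients_with_event = 3, alpha = 0.05,
                          dot_method = c("pearson", "spearman")) {
  dot_method <- match.arg(dot_method)
  patients <- intersect(unique(biomarkers$patient_id), clinical$patient_id)
  if (length(patients) == 0) {
    abort("no patients shared between the biomarker and clinical tables")
  }
  dropped <- dplyr::n_distinct(biomarkers$patient_id) +
    nrow(clinical) - 2 * length(patients)
  inform(paste0("discovery over ", length(patients), " patients (",
                dropped, " unmatched id(s) dropped)"))
  clin <- clinical[match(patients, clinical$patient_id), ]
  clin$response <- response_group(clin$best_response)
  bm <- filter(biomarkers, .data$patient_id %in% patients)
  scope_tbl <- distinct(bm, .data$scope_level, .data$scope_name)
  scope_tbl <- arrange(scope_tbl, .data$scope_level, .data$scope_name)
  by_scope <- split(bm, paste(bm$scope_level, bm$scope_name, sep = "\r"),
                    drop = TRUE)

  one_scope <- function(level, name) {
    sub <- by_scope[[paste(level, name, sep = "\r")]]
    wide <- biomarker_wide(sub)
    wide <- wide[match(patients, wide$patient_id), ]
    n_with_event <- sum(wide[["any_grade.n_events"]] > 0)
    if (n_with_event < min_patients_with_event) {
      rows <- skip_scope_rows(length(patients))
    } else {
      rows <- map(biomarker_names(), function(bn) {
        x <- wide[[bn]]
        parts <- strsplit(bn, ".", fixed = TRUE)[[1]]
        out <- bind_rows(
          cox_univariate(x, clin$pfs_months, clin$pfs_event),
          cox_univariate(x, clin$os_months, clin$os_event),
          ttest_response(x, clin$response),
          pearson_dot(x, clin$dot_months, method = dot_method)
        )
        out$outcome <- factor(outcome_levels(), levels = outcome_levels())
        out$stratum <- factor(parts[1], levels = stratum_levels())
        out$measurement <- factor(parts[2], levels = measurement_levels())
        out
      })
      rows <- list_rbind(rows)
    }
    rows$scope_level <- level
    rows$scope_name <- name
    rows
  }

  res <- list_rbind(pmap(list(scope_tbl$scope_level, scope_tbl$scope_name),
                         one_scope))
  res <- select(res, "scope_level", "scope_name", "stratum", "measurement",
                "outcome", "effect_kind", "effect", "ci_low", "ci_high",
                "p_value", "n_used", "status")
  res <- arrange(res, .data$scope_level, .data$scope_name, .data$stratum,
                 .data$measurement, .data$outcome)
  attr(res, "provenance") <- list(
    landmark_day = attr(biomarkers, "landmark_day"),
    truncate_at_landmark = attr(biomarkers, "truncate_at_landmark"),
    alpha = alpha,
    min_patients_with_event = min_patients_with_event,
    dot_method = dot_method,
    n_patients = length(patients),
    n_scopes = nrow(scope_tbl),
    package_version = as.character(packageVersion("aemark"))
  )
  class(res) <- c("ae_results", class(res))
  res
}

#' @export
print.ae_results <- function(x, ...) {
  pv <- attr(x, "provenance")
  cat("<ae_results> ", nrow(x), " rows over ", pv$n_scopes, " scope(s), ",
      pv$n_patients, " patients",
      if (!is.null(pv$landmark_day)) paste0(", landmark day ",
                                            pv$landmark_day),
      "\n", sep = "")
  NextMethod()
}

#' @describeIn run_discovery Results as a plain tibble.
#' @param x An `ae_results` object.
#' @param ... Unused.
#' @method tidy ae_results
#' @export
tidy.ae_results <- function(x, ...) {
  out <- x
  attr(out, "provenance") <- NULL
  class(out) <- setdiff(class(out), "ae_results")
  as_tibble(out)
}

#' @describeIn run_discovery One-row run summary (test counts, how many
#'   significant at the recorded alpha).
#' @method glance ae_results
#' @export
glance.ae_results <- function(x, ...) {
  pv <- attr(x, "provenance")
  alpha <- pv$alpha %||% 0.05
  tibble(
    n_rows = nrow(x),
    n_scopes = pv$n_scopes,
    n_patients = pv$n_patients,
    n_ok = sum(x$status == "ok"),
    n_skipped_sparse = sum(x$status == "skipped_sparse"),
    n_skipped_constant = sum(x$status == "skipped_constant"),
    n_significant = sum(x$status == "ok" & x$p_value < alpha, na.rm = TRUE),
    alpha = alpha
  )
}

#' Filter and annotate significant discovery results
#'
#' Keeps modelled rows with `p < alpha` and annotates the direction of
#' each association: hazard ratios below 1 read "improved" (longer
#' survival with more AE burden), positive DC - PD differences read
#' "higher in DC", positive correlations read "longer DOT". A
#' Benjamini-Hochberg adjusted p (computed per outcome over all modelled
#' rows) is attached for reference but — deliberately — not used for
#' filtering: the battery is a screening tool and the unadjusted p < 0.05
#' rule is its screening convention.
#'
#' @param results An `ae_results` table.
#' @param alpha Screening threshold in (0, 1).
#' @return Tibble of significant rows, ordered by p, with `direction` and
#'   `p_adj` columns.
#' @export
summarize_significant <- function(results, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  ok <- filter(results, .data$status == "ok", !is.na(.data$p_value))
  ok <- mutate(group_by(ok, .data$outcome),
               p_adj = p.adjust(.data$p_value, method = "BH"))
  ok <- ungroup(ok)
  sig <- filter(ok, .data$p_value < alpha)
  sig <- mutate(
    sig,
    direction = dplyr::case_when(
      effect_kind == "hazard_ratio" & effect < 1 ~ "improved survival",
      effect_kind == "hazard_ratio" ~ "worse survival",
      effect_kind == "mean_difference" & effect > 0 ~ "higher in DC",
      effect_kind == "mean_difference" ~ "higher in PD",
      effect > 0 ~ "longer DOT",
      TRUE ~ "shorter DOT"
    )
  )
  sig <- arrange(sig, .data$p_value)
  attr(sig, "provenance") <- NULL
  class(sig) <- setdiff(class(sig), "ae_results")
  as_tibble(sig)
}
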