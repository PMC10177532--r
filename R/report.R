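fmt_num <- function(x, digits = 3) {
  ifelse(is.finite(x), formatC(x, digits = digits, format = "g"),
         as.character(x))
}

#' Render a Markdown discovery report
#'
#' Writes the concise human-readable summary of a discovery run: a
#' provenance block (landmark, alpha, sparseness floor, cohort size,
#' package version), then one section per AE data level listing every
#' significant biomarker with its direction, effect size, and p value.
#' The body contains no timestamps, so regenerating the report from the
#' same inputs is byte-identical.
#'
#' @param results An `ae_results` table from [run_discovery()].
#' @param alpha Significance threshold for inclusion.
#' @param path Optional file to write to.
#' @param title Report title.
#' @param figures Optional named list of figure file paths to embed
#'   (name = caption), e.g. written beforehand with [ggplot2::ggsave()].
#' @return Character vector of Markdown lines, invisibly; written to
#'   `path` when given.
#' @export
render_report <- function(results, alpha = 0.05, path = NULL,
                          title = "AE-derived biomarker discovery report",
                          figures = NULL) {
  pv <- attr(results, "provenance") %||% list()
  g <- glance(structure(results,
                        class = unique(c("ae_results", class(results)))))
  sig <- summarize_significant(results, alpha = alpha)
  lines <- c(
    paste0("# ", title),
    "",
    "## Provenance",
    "",
    paste0("- landmark day: ",
           pv$landmark_day %||% "none (full study period)"),
    paste0("- durations truncated at landmark: ",
           isTRUE(pv$truncate_at_landmark)),
    paste0("- alpha: ", alpha),
    paste0("- sparseness floor (patients with event): ",
           pv$min_patients_with_event %||% "NA"),
    paste0("- DOT correlation: ", pv$dot_method %||% "pearson"),
    paste0("- patients: ", pv$n_patients %||% "NA",
           "; scopes: ", pv$n_scopes %||% "NA",
           "; result rows: ", nrow(results)),
    paste0("- modelled rows: ", g$n_ok,
           "; skipped sparse: ", g$n_skipped_sparse,
           "; skipped constant: ", g$n_skipped_constant),
    paste0("- package: aemark ",
           pv$package_version %||% as.character(packageVersion("aemark"))),
    ""
  )
  for (cap in names(figures)) {
    lines <- c(lines, paste0("![", cap, "](", figures[[cap]], ")"), "")
  }
  level_title <- c(overall = "Overall AE level",
                   category = "Toxicity category level",
                   term = "Individual AE level")
  for (lev in intersect(names(level_title),
                        unique(results$scope_level))) {
    lines <- c(lines, paste0("## ", level_title[[lev]]), "")
    sub <- filter(sig, .data$scope_level == lev)
    if (nrow(sub) == 0) {
      lines <- c(lines, "No significant biomarkers.", "")
      next
    }
    for (nm in unique(sub$scope_name)) {
      rows <- filter(sub, .data$scope_name == nm)
      lines <- c(lines, paste0("### ", nm), "")
      lines <- c(lines, pmap(rows, function(...) {
        r <- list(...)
        paste0("- ", r$stratum, " / ", r$measurement, " vs ", r$outcome,
               ": ", r$effect_kind, " = ", fmt_num(r$effect),
               ", p = ", fmt_num(r$p_value, 2),
               " (BH ", fmt_num(r$p_adj, 2), ") — ", r$direction)
      }) |> unlist(), "")
    }
  }
  lines <- as.character(lines)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
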