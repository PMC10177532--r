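biomarker_axis_levels <- function() {
  lv <- biomarker_names()
  gsub(".", " · ", lv, fixed = TRUE)
}

biomarker_axis_label <- function(stratum, measurement) {
  factor(paste(stratum, "·", measurement),
         levels = rev(biomarker_axis_levels()))
}

empty_panel <- function(msg) {
  ggplot() +
    annotate("text", x = 0, y = 0, label = msg) +
    theme_void()
}

#' Effect-size summary plot for one scope
#'
#' The panel view of a discovery run: all 24 biomarkers on the y axis
#' (grouped by the six strata), hazard ratios for OS/PFS on a log x axis
#' with a reference line at HR = 1, and DC - PD mean differences with a
#' reference at 0. Points with p below the threshold are drawn in the
#' highlight colour.
#'
#' @param results An `ae_results` table from [run_discovery()].
#' @param scope_name Scope to display (default `"overall"`).
#' @param alpha Highlight threshold in (0, 1).
#' @param panels `"both"` (survival over response, assembled with
#'   patchwork), `"survival"`, or `"response"`.
#' @param highlight Colour for significant points.
#' @param log_hr Draw the HR axis on a log scale?
#' @return A ggplot (single panel) or patchwork object.
#' @examples
#' sim <- simulate_cohort(sim_config(n_patients = 40, seed = 3))
#' res <- run_discovery(derive_matrix(sim$cohort, "overall",
#'                                    landmark_day = 30), sim$clinical)
#' plot_effect_summary(res)
#' @export
plot_effect_summary <- function(results, scope_name = "overall",
                                alpha = 0.05,
                                panels = c("both", "survival", "response"),
                                highlight = "red", log_hr = TRUE) {
  stopifnot(alpha > 0, alpha < 1)
  panels <- match.arg(panels)
  rows <- filter(as_tibble(results), .data$scope_name == !!scope_name,
                 .data$status == "ok")
  rows <- mutate(rows,
                 y = biomarker_axis_label(.data$stratum, .data$measurement),
                 significant = .data$p_value < alpha)
  surv <- filter(rows, .data$outcome %in% c("PFS", "OS"),
                 is.finite(.data$effect))
  resp <- filter(rows, .data$outcome == "DC_vs_PD")
  cols <- c(`TRUE` = highlight, `FALSE` = "grey35")

  p_surv <- if (nrow(surv) == 0) {
    empty_panel("no modelled survival results for this scope")
  } else {
    p <- ggplot(surv, aes(x = .data$effect, y = .data$y)) +
      geom_vline(xintercept = 1, linetype = "dashed", colour = "grey60") +
      geom_point(aes(colour = .data$significant), size = 1.8) +
      facet_wrap(~outcome) +
      scale_colour_manual(values = cols, guide = "none") +
      labs(x = "hazard ratio", y = NULL,
           title = paste0("Survival associations — ", scope_name)) +
      theme_minimal(base_size = 9)
    if (log_hr) p <- p + scale_x_log10()
    p
  }
  p_resp <- if (nrow(resp) == 0) {
    empty_panel("no modelled response results for this scope")
  } else {
    ggplot(resp, aes(x = .data$effect, y = .data$y)) +
      geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
      geom_point(aes(colour = .data$significant), size = 1.8) +
      scale_colour_manual(values = cols, guide = "none") +
      labs(x = "mean difference (DC - PD)", y = NULL,
           title = paste0("Response associations — ", scope_name)) +
      theme_minimal(base_size = 9)
  }
  switch(panels,
         survival = p_surv,
         response = p_resp,
         both = patchwork::wrap_plots(p_surv, p_resp, ncol = 1))
}

#' @method autoplot ae_results
#' @export
autoplot.ae_results <- function(object, ...) {
  plot_effect_summary(object, ...)
}

#' Kaplan-Meier plot with medians and at-risk table
#'
#' Step curves per occurrence group, dotted drop lines at the group
#' medians, the log-rank p in the subtitle, and the number at risk per
#' time tick rendered beneath the curves.
#'
#' @param km A `km_summary` from [km_logrank()].
#' @param palette Two colours for the without/with groups.
#' @param risk_table Include the at-risk table panel?
#' @return A ggplot or (with the risk table) patchwork object.
#' @export
plot_km <- function(km, palette = c("cyan3", "red"), risk_table = TRUE) {
  fit <- km$fit
  groups <- names(km$medians)
  strata_n <- if (is.null(fit$strata)) setNames(length(fit$time), groups[1])
              else setNames(as.integer(fit$strata),
                            sub("^grp=", "", names(fit$strata)))
  curve <- tibble(
    time = fit$time, surv = fit$surv,
    group = rep(names(strata_n), strata_n)
  )
  curve <- bind_rows(
    tibble(time = 0, surv = 1, group = names(strata_n)), curve)
  meds <- tidy(km)
  meds <- filter(meds, !is.na(.data$median))
  pal <- setNames(rep_len(palette, length(groups)), groups)
  lab <- paste0(groups, " (n=", as.integer(km$n[groups]), ")")
  p <- ggplot(curve, aes(x = .data$time, y = .data$surv,
                         colour = .data$group)) +
    geom_step(linewidth = 0.7) +
    scale_colour_manual(values = pal, labels = setNames(lab, groups)) +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "months", y = "survival probability", colour = NULL,
         subtitle = if (!is.na(km$logrank_p)) {
           paste0("log-rank p = ", format.pval(km$logrank_p, digits = 2))
         } else NULL) +
    theme_minimal(base_size = 10) +
    theme(legend.position = "bottom")
  if (nrow(meds) > 0) {
    p <- p + geom_segment(
      data = meds,
      aes(x = .data$median, xend = .data$median, y = 0, yend = 0.5,
          colour = .data$group),
      linetype = "dotted", inherit.aes = FALSE, show.legend = FALSE)
  }
  if (!risk_table) return(p)
  tab <- ggplot(km$at_risk,
                aes(x = .data$time, y = .data$group,
                    label = .data$n_risk)) +
    geom_text(size = 3) +
    labs(x = NULL, y = NULL, title = "number at risk") +
    theme_minimal(base_size = 9) +
    theme(panel.grid = element_blank(),
          plot.title = element_text(size = 9))
  patchwork::wrap_plots(p, tab, ncol = 1, heights = c(4, 1))
}

#' @method autoplot km_summary
#' @export
autoplot.km_summary <- function(object, ...) {
  plot_km(object, ...)
}

#' Boxplots of a biomarker by response group
#'
#' Side-by-side boxplots of a biomarker in the disease-control and
#' progressive-disease groups (DC blue, PD red, per the field's usual
#' colouring), with group sizes in the axis labels. NE patients are
#' dropped; an empty group yields a single box with a warning.
#'
#' @param x Numeric biomarker values.
#' @param response `"DC"`/`"PD"` per patient ([response_group()] output).
#' @param title Optional plot title.
#' @param palette Named colours for DC and PD.
#' @return A ggplot object.
#' @export
plot_box_response <- function(x, response, title = NULL,
                              palette = c(DC = "blue", PD = "red")) {
  keep <- !is.na(response) & response %in% c("DC", "PD") & !is.na(x)
  d <- tibble(value = x[keep],
              response = factor(response[keep], levels = c("DC", "PD")))
  present <- levels(droplevels(d$response))
  if (length(present) < 2) {
    warn("one response group is empty; drawing a single box")
  }
  n_lab <- table(d$response)
  labs_x <- paste0(names(n_lab), " (n=", as.integer(n_lab), ")")
  ggplot(d, aes(x = .data$response, y = .data$value,
                fill = .data$response)) +
    geom_boxplot(show.legend = FALSE, na.rm = TRUE) +
    scale_fill_manual(values = palette) +
    scale_x_discrete(labels = setNames(labs_x, names(n_lab)),
                     drop = FALSE) +
    labs(x = NULL, y = "biomarker value", title = title) +
    theme_minimal(base_size = 10)
}
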