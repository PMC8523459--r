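#' Methylation versus age per CpG
#'
#' Scatter of called methylation against chronological age, one facet per
#' site, with per-group least-squares lines — the per-site view behind the
#' age-association table.
#'
#' @param methylation Methylation tibble.
#' @param cohort Cohort tibble.
#' @param sites Site subset (default the six blood-model CpGs); see
#'   [resolve_sites()].
#' @param panel Panel tibble.
#' @return A ggplot object.
#' @export
plot_methylation_age <- function(methylation, cohort, sites = "blood6",
                                 panel = visage_panel()) {
  sel <- resolve_sites(panel, sites)
  df <- methylation %>%
    filter(!is.na(.data$meth_pct)) %>%
    semi_join(sel, by = c("marker", "cpg_label")) %>%
    inner_join(as_tibble(cohort)[c("sample_id", "age", "group")],
               by = "sample_id") %>%
    mutate(site = site_key(.data$marker, .data$cpg_label))
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$meth_pct,
                                   colour = .data$group)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.6) +
    ggplot2::facet_wrap(~site, scales = "free_y") +
    ggplot2::labs(x = "chronological age (years)",
                  y = "DNA methylation (%)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Predicted versus chronological age
#'
#' @param predictions Prediction tibble from [predict_age()].
#' @param cohort Cohort tibble (for group colour).
#' @return A ggplot object.
#' @export
plot_predictions <- function(predictions, cohort) {
  df <- predictions %>%
    inner_join(as_tibble(cohort)[c("sample_id", "group")], by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$chronological_age,
                                   .data$predicted_age,
                                   colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "chronological age (years)",
                  y = "predicted age (years)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Epigenetic age acceleration by group
#'
#' Boxplots of EAA residuals per group (optionally split by age stratum),
#' the visual counterpart of the covariate-adjusted association.
#'
#' @param eaa An [compute_eaa()] result.
#' @param cohort Cohort tibble.
#' @param by_stratum Facet by the two age categories.
#' @param age_cut Stratum boundary.
#' @return A ggplot object.
#' @export
plot_eaa <- function(eaa, cohort, by_stratum = FALSE, age_cut = 45) {
  df <- as_tibble(eaa) %>%
    inner_join(as_tibble(cohort)[c("sample_id", "group", "age")],
               by = "sample_id") %>%
    mutate(stratum = ifelse(.data$age <= age_cut,
                            paste0("<=", age_cut), paste0(">", age_cut)))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$eaa,
                                        fill = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(alpha = 0.7, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "epigenetic age acceleration (years)") +
    ggplot2::theme_minimal()
  if (by_stratum) p <- p + ggplot2::facet_wrap(~stratum)
  p
}
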