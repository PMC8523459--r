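#' Two-sample t-test from summary statistics
#'
#' The pooled-variance (Student) independent-samples t-test computed
#' directly from group sizes, means and SDs, so printed summary rows can be
#' re-analyzed without the underlying data:
#' `Sp^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1+n2-2)`,
#' `se = sqrt(Sp^2 (1/n1 + 1/n2))`, `t = (m1 - m2)/se` on `n1+n2-2`
#' degrees of freedom, two-sided p. Welch's unequal-variance form is
#' available with `welch = TRUE` (Satterthwaite df).
#'
#' @param n1,mean1,sd1 First group (reported first; differences are
#'   group1 - group2).
#' @param n2,mean2,sd2 Second group.
#' @param welch Use Welch's unequal-variance statistic.
#' @param metric Optional label carried into the output.
#' @return A one-row tibble: `metric`, `n1`, `mean1`, `sd1`, `n2`, `mean2`,
#'   `sd2`, `mean_difference`, `se_difference`, `t_statistic`, `df`,
#'   `p_value`, `variance_mode`, `degenerate` (`TRUE` when both groups are
#'   constant so the SE is zero; t and p are then `NA` rather than a
#'   division by zero).
#' @examples
#' pooled_ttest_summary(100, 0.972, 4.138, 100, -0.447, 4.461)
#' @export
pooled_ttest_summary <- function(n1, mean1, sd1, n2, mean2, sd2,
                                 welch = FALSE, metric = NA_character_) {
  if (n1 < 2 || n2 < 2) abort("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) abort("SDs must be non-negative")
  diff <- mean1 - mean2
  if (welch) {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- if (se > 0) (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1)) else NA_real_
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  degenerate <- se == 0
  t_stat <- if (degenerate) NA_real_ else diff / se
  p <- if (degenerate) NA_real_ else 2 * pt(-abs(t_stat), df)
  tibble(metric = metric, n1 = n1, mean1 = mean1, sd1 = sd1,
         n2 = n2, mean2 = mean2, sd2 = sd2,
         mean_difference = diff, se_difference = se,
         t_statistic = t_stat, df = df, p_value = p,
         variance_mode = if (welch) "welch" else "pooled",
         degenerate = degenerate)
}

#' Two-sample t-test from raw values
#'
#' Computes each group's n/mean/SD and delegates to
#' [pooled_ttest_summary()], so the two entry points agree exactly.
#'
#' @param values1,values2 Numeric vectors (group1 - group2 differences).
#' @inheritParams pooled_ttest_summary
#' @return A one-row comparison tibble (see [pooled_ttest_summary()]).
#' @export
ttest_samples <- function(values1, values2, welch = FALSE,
                          metric = NA_character_) {
  values1 <- values1[!is.na(values1)]
  values2 <- values2[!is.na(values2)]
  if (length(values1) < 2 || length(values2) < 2) {
    abort("both groups need at least 2 non-missing values")
  }
  pooled_ttest_summary(length(values1), mean(values1), sd(values1),
                       length(values2), mean(values2), sd(values2),
                       welch = welch, metric = metric)
}

#' Per-CpG abuser-vs-control methylation comparison
#'
#' One Student's t-test per CpG site on called methylation percentages,
#' abuser minus control. Nominal p-values mirror the headline analysis
#' (no multiplicity adjustment feeds the `significant` flag); Bonferroni
#' and Benjamini-Hochberg columns are emitted alongside for reference.
#'
#' @param methylation Methylation tibble.
#' @param cohort Cohort tibble.
#' @param welch Use Welch's statistic.
#' @param alpha Significance threshold for the flag.
#' @return A tibble with one row per site: the comparison columns of
#'   [pooled_ttest_summary()] plus `marker`, `cpg_label`, `p_bonferroni`,
#'   `p_bh`, `significant`. Sites with fewer than two values in a group
#'   yield an all-`NA` row with `degenerate = TRUE`.
#' @export
per_cpg_group_comparison <- function(methylation, cohort, welch = FALSE,
                                     alpha = 0.05) {
  df <- methylation %>%
    filter(!is.na(.data$meth_pct)) %>%
    inner_join(as_tibble(cohort)[c("sample_id", "group")], by = "sample_id")
  sites <- distinct(methylation, .data$marker, .data$cpg_label)
  out <- purrr::pmap_dfr(sites, function(marker, cpg_label) {
    v <- df[df$marker == marker & df$cpg_label == cpg_label, ]
    a <- v$meth_pct[v$group == "abuser"]
    c_ <- v$meth_pct[v$group == "control"]
    row <- if (length(a) >= 2 && length(c_) >= 2) {
      ttest_samples(a, c_, welch = welch, metric = "methylation_pct")
    } else {
      tibble(metric = "methylation_pct", n1 = length(a), mean1 = NA_real_,
             sd1 = NA_real_, n2 = length(c_), mean2 = NA_real_,
             sd2 = NA_real_, mean_difference = NA_real_,
             se_difference = NA_real_, t_statistic = NA_real_,
             df = NA_real_, p_value = NA_real_,
             variance_mode = if (welch) "welch" else "pooled",
             degenerate = TRUE)
    }
    bind_cols(tibble(marker = marker, cpg_label = cpg_label), row)
  })
  out %>%
    mutate(p_bonferroni = stats::p.adjust(.data$p_value, "bonferroni"),
           p_bh = stats::p.adjust(.data$p_value, "BH"),
           significant = !is.na(.data$p_value) & .data$p_value < alpha)
}

#' Per-CpG association of methylation with age
#'
#' Univariate OLS of methylation on chronological age per site, run
#' separately within each group (equivalent to a Pearson correlation test).
#'
#' @param methylation Methylation tibble.
#' @param cohort Cohort tibble.
#' @param groups Groups to analyze (default both, separately).
#' @param conf_level Confidence level for the slope interval.
#' @return A tibble per (site, group): `slope` (percentage points per
#'   year), `se`, `conf_low`, `conf_high`, `r`, `p_value`, `n`,
#'   `degenerate` (constant methylation or n < 3).
#' @export
per_cpg_age_association <- function(methylation, cohort,
                                    groups = c("abuser", "control"),
                                    conf_level = 0.95) {
  df <- methylation %>%
    filter(!is.na(.data$meth_pct)) %>%
    inner_join(as_tibble(cohort)[c("sample_id", "age", "group")],
               by = "sample_id") %>%
    filter(.data$group %in% groups)
  sites <- distinct(methylation, .data$marker, .data$cpg_label)
  grid <- tidyr::crossing(sites, group = groups)
  purrr::pmap_dfr(grid, function(marker, cpg_label, group) {
    v <- df[df$marker == marker & df$cpg_label == cpg_label &
              df$group == group, ]
    base <- tibble(marker = marker, cpg_label = cpg_label, group = group,
                   n = nrow(v))
    if (nrow(v) < 3 || sd(v$meth_pct) == 0 || sd(v$age) == 0) {
      return(bind_cols(base, tibble(slope = NA_real_, se = NA_real_,
                                    conf_low = NA_real_, conf_high = NA_real_,
                                    r = NA_real_, p_value = NA_real_,
                                    degenerate = TRUE)))
    }
    fit <- lm(meth_pct ~ age, data = v)
    # noiseless fixtures fit exactly; the perfect-fit warning is expected
    s <- suppressWarnings(summary(fit))$coefficients
    crit <- qt(1 - (1 - conf_level) / 2, fit$df.residual)
    bind_cols(base, tibble(
      slope = s["age", 1], se = s["age", 2],
      conf_low = s["age", 1] - crit * s["age", 2],
      conf_high = s["age", 1] + crit * s["age", 2],
      r = stats::cor(v$meth_pct, v$age),
      p_value = s["age", 4], degenerate = FALSE))
  })
}

#' Matching checks: age distribution and sex ratio
#'
#' Two-sample Kolmogorov-Smirnov test on the age distributions of abusers
#' vs controls, and a 2x2 chi-square on sex counts (no continuity
#' correction by default). Integer ages always tie, so the KS p-value is
#' the asymptotic approximation; a perfectly matched cohort gives D = 0 and
#' chi-square = 0.
#'
#' @param cohort Cohort tibble.
#' @param correct Apply Yates continuity correction to the chi-square.
#' @return A list: `ks_statistic`, `ks_p`, `chisq_statistic`, `chisq_p`,
#'   `sex_table` (2x2 counts).
#' @export
matching_checks <- function(cohort, correct = FALSE) {
  cohort <- as_tibble(cohort)
  a <- cohort$age[cohort$group == "abuser"]
  c_ <- cohort$age[cohort$group == "control"]
  if (!length(a) || !length(c_)) abort("both groups must be non-empty")
  ks <- suppressWarnings(ks.test(a, c_))
  tab <- table(factor(cohort$group, c("abuser", "control")),
               factor(cohort$sex, c("male", "female")))
  chi <- if (all(rowSums(tab) > 0) && any(colSums(tab) > 0) &&
             length(unique(cohort$sex)) > 1) {
    suppressWarnings(chisq.test(tab, correct = correct))
  } else NULL
  list(
    ks_statistic = unname(ks$statistic),
    ks_p = ks$p.value,
    chisq_statistic = if (is.null(chi)) NA_real_ else unname(chi$statistic),
    chisq_p = if (is.null(chi)) NA_real_ else chi$p.value,
    sex_table = tab
  )
}
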