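#' Epigenetic age acceleration as calibration residuals
#'
#' EAA is the residual from regressing predicted (methylation) age on
#' chronological age: positive values mean the epigenetic age exceeds what
#' the cohort-wide age trend predicts. The calibration line is fit on the
#' full analysis cohort by default (`calibration = "pooled"`); a
#' controls-only calibration is available, which shifts abuser residual
#' means by any abuser-specific offset instead of splitting it between
#' groups.
#'
#' @param predictions Prediction tibble from [predict_age()] (needs
#'   `predicted_age` and `chronological_age`).
#' @param calibration `"pooled"` (all samples) or `"controls"` (requires
#'   `cohort`).
#' @param cohort Cohort tibble, required for `calibration = "controls"`.
#' @return An `eaa_result` tibble: `sample_id`, `chronological_age`,
#'   `predicted_age`, `eaa` (years), with the calibration intercept/slope
#'   in `eaa_calibration()`.
#' @examples
#' pred <- tibble::tibble(sample_id = letters[1:4],
#'                        predicted_age = c(31, 39, 52, 58),
#'                        chronological_age = c(30, 40, 50, 60))
#' eaa <- compute_eaa(pred)
#' sum(eaa$eaa)   # ~0 by construction
#' @export
compute_eaa <- function(predictions, calibration = c("pooled", "controls"),
                        cohort = NULL) {
  calibration <- match.arg(calibration)
  df <- predictions %>%
    filter(!is.na(.data$predicted_age), !is.na(.data$chronological_age))
  if (nrow(df) < 3) abort("need at least 3 samples with both ages")
  if (sd(df$chronological_age) == 0) {
    abort("chronological age is constant; calibration slope is undefined")
  }
  cal_df <- df
  if (calibration == "controls") {
    if (is.null(cohort)) abort("controls-only calibration needs a cohort")
    ctrl <- cohort$sample_id[cohort$group == "control"]
    cal_df <- df[df$sample_id %in% ctrl, ]
    if (nrow(cal_df) < 3 || sd(cal_df$chronological_age) == 0) {
      abort("too few controls for controls-only calibration")
    }
  }
  fit <- lm(predicted_age ~ chronological_age, data = cal_df)
  out <- df %>%
    mutate(eaa = .data$predicted_age -
             unname(predict(fit, df["chronological_age"]))) %>%
    select("sample_id", "chronological_age", "predicted_age", "eaa")
  attr(out, "calibration") <- list(
    mode = calibration,
    intercept = unname(coef(fit)[1]),
    slope = unname(coef(fit)[2]),
    n = nrow(cal_df)
  )
  class(out) <- c("eaa_result", class(out))
  out
}

#' @rdname compute_eaa
#' @param x An `eaa_result`.
#' @export
eaa_calibration <- function(x) attr(x, "calibration")

#' Covariate-adjusted association of group with EAA
#'
#' OLS of EAA on group (abuser = 1), age (years) and sex (male = 1),
#' reporting the group term: unstandardized beta (years), standardized beta
#' (`b * SD(group) / SD(eaa)`), t and two-sided p. Run overall and within
#' the requested age strata; residuals are computed once on the full cohort
#' and only the association refits per stratum. A covariate that is
#' constant within a stratum (e.g. a single-sex stratum) is dropped with a
#' warning rather than breaking the fit.
#'
#' @param eaa An [compute_eaa()] result.
#' @param cohort Cohort tibble (`group`, `age`, `sex`).
#' @param strata Subset of `c("all", "le45", "ge46")`.
#' @param age_cut Stratum boundary (stratum 1: age <= cut; 2: age > cut).
#' @return A tibble per stratum: `stratum`, `n`, `beta_group` (years),
#'   `std_beta`, `t_statistic`, `p_value`, `covariates`.
#' @export
eaa_association <- function(eaa, cohort, strata = c("all", "le45", "ge46"),
                            age_cut = 45) {
  strata <- match.arg(strata, c("all", "le45", "ge46"), several.ok = TRUE)
  df <- as_tibble(eaa) %>%
    inner_join(as_tibble(cohort)[c("sample_id", "age", "sex", "group")],
               by = "sample_id") %>%
    mutate(group01 = as.numeric(.data$group == "abuser"),
           male01 = as.numeric(.data$sex == "male"))
  purrr::map_dfr(strata, function(s) {
    d <- switch(s,
      all  = df,
      le45 = filter(df, .data$age <= age_cut),
      ge46 = filter(df, .data$age > age_cut))
    if (!nrow(d) || n_distinct(d$group) < 2) {
      abort(paste0("stratum '", s, "' lacks both groups"))
    }
    covs <- c("group01", "age", "male01")
    drop <- covs[vapply(d[covs], function(v) sd(v) == 0, logical(1))]
    drop <- setdiff(drop, "group01")
    if (length(drop)) {
      warn(paste0("dropping constant covariate(s) in stratum '", s, "': ",
                  paste(drop, collapse = ", ")))
      covs <- setdiff(covs, drop)
    }
    fit <- lm(stats::reformulate(covs, response = "eaa"), data = d)
    s_tab <- summary(fit)$coefficients
    b <- s_tab["group01", 1]
    tibble(
      stratum = s, n = nrow(d),
      beta_group = b,
      std_beta = b * sd(d$group01) / sd(d$eaa),
      t_statistic = s_tab["group01", 3],
      p_value = s_tab["group01", 4],
      covariates = paste(covs, collapse = "+")
    )
  })
}
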