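#' Study configuration
#'
#' Bundles the simulation (or real-input paths) and analysis settings for
#' [run_study()].
#'
#' @param sim A [sim_config()] describing the synthetic cohort (ignored
#'   when `inputs` is given).
#' @param inputs Optional list of file paths (`counts`, `cohort`, and
#'   optionally `controls`, `panel`) to run on real data instead of
#'   simulating.
#' @param seed Integer seed for the whole run (overrides `sim$seed`).
#' @param min_depth Per-CpG paired-read threshold for methylation calling.
#' @param required_sites Sites whose absence excludes a sample (default:
#'   blood-model CpGs of *ELOVL2* and *PDE4C*).
#' @param pair_preserving Drag matched partners through QC exclusions.
#' @param age_cut Age-stratum boundary in years.
#' @param calibration EAA calibration set, `"pooled"` or `"controls"`.
#' @param welch Use Welch's t statistic in group comparisons.
#' @return A `study_config` list.
#' @export
study_config <- function(sim = sim_config(), inputs = NULL, seed = NULL,
                         min_depth = 1000, required_sites = NULL,
                         pair_preserving = TRUE, age_cut = 45,
                         calibration = c("pooled", "controls"),
                         welch = FALSE) {
  calibration <- match.arg(calibration)
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, inputs = inputs, seed = sim$seed,
                 min_depth = min_depth, required_sites = required_sites,
                 pair_preserving = pair_preserving, age_cut = age_cut,
                 calibration = calibration, welch = welch),
            class = "study_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "': ", conditionMessage(e)))
  })
}

#' Group comparison table for prediction metrics
#'
#' Student's t comparisons of MAE, ME and predicted age between abusers and
#' controls (abuser minus control), overall and within the two age strata.
#'
#' @param predictions Prediction tibble with errors.
#' @param cohort Cohort tibble.
#' @param age_cut Stratum boundary.
#' @param welch Use Welch's statistic.
#' @return A tibble: `metric`, `stratum`, plus the
#'   [pooled_ttest_summary()] columns.
#' @export
metric_comparison_table <- function(predictions, cohort, age_cut = 45,
                                    welch = FALSE) {
  df <- predictions %>%
    inner_join(as_tibble(cohort)[c("sample_id", "group")], by = "sample_id")
  cells <- tidyr::crossing(
    metric = c("mae", "me", "predicted_age"),
    stratum = c("all", paste0("<=", age_cut), paste0(">=", age_cut + 1))
  )
  purrr::pmap_dfr(cells, function(metric, stratum) {
    d <- switch(stratum,
      all = df,
      switch(substr(stratum, 1, 2),
        "<=" = filter(df, .data$chronological_age <= age_cut),
        ">=" = filter(df, .data$chronological_age > age_cut)))
    col <- switch(metric, mae = "abs_error", me = "error",
                  predicted_age = "predicted_age")
    row <- ttest_samples(d[[col]][d$group == "abuser"],
                         d[[col]][d$group == "control"],
                         welch = welch, metric = metric)
    bind_cols(tibble(stratum = stratum), row)
  }) %>%
    select("metric", "stratum", dplyr::everything())
}

#' Run the full study replica end to end
#'
#' Simulate (or load) the cohort and read counts, call methylation and
#' apply pair-preserving QC, fit both age models on controls, predict all
#' retained samples, compare prediction metrics and per-CpG methylation
#' between groups, and compute epigenetic age acceleration with its
#' covariate-adjusted group association — emitting one structured report.
#'
#' @param config A [study_config()].
#' @return A `study_report` list: `qc`, `matching`, `models`,
#'   `predictions`, `metrics`, `metric_comparisons`, `per_cpg_comparison`,
#'   `per_cpg_association`, `eaa`, `provenance`.
#' @examples
#' \donttest{
#' rep <- run_study(study_config(sim_config(n_pairs = 30), seed = 7))
#' rep$metric_comparisons$blood6
#' }
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  panel <- config$sim$panel

  if (is.null(config$inputs)) {
    sim <- config$sim
    sim$seed <- config$seed
    data <- with_stage("simulate", simulate_study_data(sim))
  } else {
    inp <- config$inputs
    if (!is.null(inp$panel)) panel <- load_marker_panel(inp$panel)
    data <- with_stage("load", list(
      counts = read_count_table(inp$counts),
      controls = if (is.null(inp$controls)) NULL
                 else read_conversion_controls(inp$controls),
      cohort = load_cohort(inp$cohort, age_tolerance = Inf)
    ))
  }

  qc <- with_stage("qc", qc_report(
    data$counts, data$cohort, controls = data$controls, panel = panel,
    min_depth = config$min_depth, required_sites = config$required_sites,
    pair_preserving = config$pair_preserving))
  meth <- qc$methylation
  cohort <- qc$cohort
  controls_only <- filter(cohort, .data$group == "control")

  matching <- with_stage("matching", matching_checks(cohort))

  models <- with_stage("fit", list(
    blood6 = fit_age_model(meth, controls_only, "blood6", panel),
    mir29_c1 = fit_age_model(meth, controls_only, "mir29_c1", panel)
  ))

  predictions <- with_stage("predict", purrr::map(
    models, function(m) predict_age(m, meth, cohort)))

  metrics <- with_stage("metrics", purrr::map(
    predictions, prediction_metrics, cohort = cohort,
    age_cut = config$age_cut))
  comparisons <- with_stage("compare", purrr::map(
    predictions, metric_comparison_table, cohort = cohort,
    age_cut = config$age_cut, welch = config$welch))

  per_cpg_cmp <- with_stage("compare",
    per_cpg_group_comparison(meth, cohort, welch = config$welch))
  per_cpg_assoc <- with_stage("associate",
    per_cpg_age_association(meth, cohort))

  eaa <- with_stage("eaa", purrr::map(predictions, function(p) {
    r <- compute_eaa(p, calibration = config$calibration, cohort = cohort)
    list(residuals = r,
         association = eaa_association(r, cohort, age_cut = config$age_cut))
  }))

  structure(list(
    qc = qc, matching = matching, models = models,
    predictions = predictions, metrics = metrics,
    metric_comparisons = comparisons,
    per_cpg_comparison = per_cpg_cmp,
    per_cpg_association = per_cpg_assoc,
    eaa = eaa,
    provenance = list(
      seed = config$seed,
      config_hash = rlang::hash(config),
      n_analyzed = nrow(cohort),
      package_version = as.character(utils::packageVersion("epiage")),
      timestamp = NA_character_  # deterministic reports carry no clock
    )
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed=", x$provenance$seed %||% "none",
      "  n analyzed=", x$provenance$n_analyzed, "\n", sep = "")
  for (m in names(x$metric_comparisons)) {
    row <- x$metric_comparisons[[m]]
    r <- row[row$metric == "me" & row$stratum == "all", ]
    cat(sprintf("  %s: ME diff %.3f +/- %.3f (p=%.3f)\n",
                m, r$mean_difference, r$se_difference, r$p_value))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a study report to a directory
#'
#' One TSV per table (metric comparisons, per-CpG comparison/association,
#' stratified metrics, EAA associations, QC exclusions, normalized depth)
#' plus a JSON bundle of everything serializable.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) readr::write_tsv(x, file.path(dir, name),
                                           progress = FALSE)
  for (m in names(report$metric_comparisons)) {
    wt(report$metric_comparisons[[m]],
       paste0("metric_comparisons_", m, ".tsv"))
    wt(report$metrics[[m]], paste0("metrics_", m, ".tsv"))
    wt(report$eaa[[m]]$association, paste0("eaa_association_", m, ".tsv"))
    wt(as_tibble(report$eaa[[m]]$residuals), paste0("eaa_", m, ".tsv"))
    wt(report$predictions[[m]], paste0("predictions_", m, ".tsv"))
  }
  wt(report$per_cpg_comparison, "per_cpg_comparison.tsv")
  wt(report$per_cpg_association, "per_cpg_association.tsv")
  wt(report$qc$exclusions, "qc_exclusions.tsv")
  wt(report$qc$normalized_depth, "qc_normalized_depth.tsv")
  wt(report$qc$sample_coverage, "qc_sample_coverage.tsv")

  bundle <- list(
    provenance = report$provenance,
    matching = report$matching[c("ks_statistic", "ks_p",
                                 "chisq_statistic", "chisq_p")],
    misincorporation_pct = report$qc$misincorporation$overall_pct,
    models = purrr::map(report$models, function(m) {
      list(subset = m$subset, intercept = m$intercept,
           coefficients = as.list(m$coefficients),
           training = list(n = m$training_n, r2 = m$training_r2,
                           mae = m$training_mae))
    }),
    eaa_association = purrr::map(report$eaa, "association")
  )
  jsonlite::write_json(bundle, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
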