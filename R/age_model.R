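#' Fit a linear CpG age predictor
#'
#' Ordinary least squares of chronological age on methylation percentages
#' at a chosen site subset (all predictors entered simultaneously). The
#' packaged subsets are `"blood6"` — the six blood-model CpGs — and
#' `"mir29_c1"` — *MIR29B2CHG* C1 alone. Samples missing any subset site
#' are dropped and logged. Models fit here are always trained on supplied
#' (by default synthetic) data; no published coefficients are shipped.
#'
#' @param methylation Methylation tibble from [call_methylation()] (or any
#'   tibble with `sample_id`, `marker`, `cpg_label`, `meth_pct`).
#' @param cohort Cohort tibble supplying `sample_id` and `age` (typically
#'   restricted to the training group before calling).
#' @param subset `"blood6"`, `"mir29_c1"`, or a `marker`/`cpg_label` data
#'   frame (see [resolve_sites()]).
#' @param panel Panel tibble used to resolve the subset.
#' @return A `cpg_age_model`: intercept, per-site coefficients (years per
#'   percentage point), training n, R-squared and MAE, plus the underlying
#'   `lm` fit. Supports [tidy()], [glance()] and [predict_age()].
#' @examples
#' dat <- simulate_study_data(sim_config(n_pairs = 40, seed = 1))
#' meth <- call_methylation(dat$counts, min_depth = 0)
#' ctrl <- dplyr::filter(dat$cohort, group == "control")
#' fit <- fit_age_model(meth, ctrl, subset = "blood6")
#' glance(fit)
#' @export
fit_age_model <- function(methylation, cohort, subset = "blood6",
                          panel = visage_panel()) {
  sites <- resolve_sites(panel, subset)
  subset_name <- if (is.character(subset)) subset else "custom"
  wide <- pivot_sites(methylation, sites)
  df <- inner_join(as_tibble(cohort)[c("sample_id", "age")], wide,
                   by = "sample_id")
  keys <- site_key(sites$marker, sites$cpg_label)
  complete <- complete.cases(df[keys])
  if (any(!complete)) {
    inform(paste0("dropping ", sum(!complete),
                  " sample(s) with missing model sites from training"))
    df <- df[complete, ]
  }
  p <- length(keys)
  if (nrow(df) < p + 2) {
    abort(paste0("need at least ", p + 2, " complete samples to fit ",
                 p, " site(s); got ", nrow(df)))
  }
  sds <- vapply(df[keys], sd, numeric(1))
  if (any(sds == 0)) {
    abort(paste0("constant methylation at site(s): ",
                 paste(keys[sds == 0], collapse = ", ")))
  }
  X <- as.data.frame(df[keys])
  names(X) <- make.names(keys)
  fit <- lm(df$age ~ ., data = X)
  if (anyNA(coef(fit))) {
    bad <- keys[is.na(coef(fit)[-1])]
    abort(paste0("collinear predictors, coefficient undetermined for: ",
                 paste(bad, collapse = ", ")))
  }
  pred <- fitted(fit)
  structure(list(
    intercept = unname(coef(fit)[1]),
    coefficients = setNames(unname(coef(fit)[-1]), keys),
    sites = sites,
    subset = subset_name,
    training_n = nrow(df),
    training_r2 = suppressWarnings(summary(fit))$r.squared,
    training_mae = mean(abs(pred - df$age)),
    training_mean_age = mean(df$age),
    fit = fit
  ), class = "cpg_age_model")
}

# long methylation -> one column per site, keyed marker:label
pivot_sites <- function(methylation, sites) {
  methylation %>%
    semi_join(as_tibble(sites), by = c("marker", "cpg_label")) %>%
    mutate(site = site_key(.data$marker, .data$cpg_label)) %>%
    select("sample_id", "site", "meth_pct") %>%
    tidyr::pivot_wider(names_from = "site", values_from = "meth_pct")
}

#' Predict age from methylation
#'
#' `predicted = intercept + sum(coef_j * meth_j)`. Samples lacking any model
#' site are omitted (and logged), never errors. When the cohort supplies
#' chronological ages, signed and absolute errors are attached.
#'
#' @param model A [fit_age_model()] object.
#' @param methylation Methylation tibble.
#' @param cohort Optional cohort tibble with `sample_id` and `age`.
#' @return A prediction tibble: `sample_id`, `predicted_age`, and (when
#'   ages are available) `chronological_age`, `error`
#'   (predicted - chronological), `abs_error`.
#' @export
predict_age <- function(model, methylation, cohort = NULL) {
  stopifnot(inherits(model, "cpg_age_model"))
  keys <- names(model$coefficients)
  if (nrow(methylation) == 0) {
    return(tibble(sample_id = character(), predicted_age = numeric()))
  }
  wide <- pivot_sites(methylation, model$sites)
  for (k in setdiff(keys, names(wide))) wide[[k]] <- NA_real_
  complete <- complete.cases(wide[keys])
  if (any(!complete)) {
    inform(paste0("omitting ", sum(!complete),
                  " sample(s) with missing model sites from prediction"))
  }
  wide <- wide[complete, ]
  pred <- tibble(
    sample_id = wide$sample_id,
    predicted_age = model$intercept +
      as.vector(as.matrix(wide[keys]) %*% model$coefficients)
  )
  if (!is.null(cohort)) {
    pred <- pred %>%
      left_join(as_tibble(cohort)[c("sample_id", "age")], by = "sample_id") %>%
      rename(chronological_age = "age") %>%
      mutate(error = .data$predicted_age - .data$chronological_age,
             abs_error = abs(.data$error))
  }
  pred
}

#' Prediction-accuracy metrics per group and age stratum
#'
#' MAE (mean absolute error), ME (mean signed error, predicted minus
#' chronological) and mean predicted age with their SDs, per group, overall
#' and within the two age categories split at `age_cut` (stratum 1:
#' age <= cut; stratum 2: age >= cut + 1, on integer ages).
#'
#' @param predictions Prediction tibble from [predict_age()] (with errors).
#' @param cohort Cohort tibble.
#' @param age_cut Stratum boundary in years (default 45).
#' @return A tibble with one row per (group, stratum) cell: `n`, `mae`,
#'   `me`, `mean_predicted`, `sd_abs_error`, `sd_error`, `sd_predicted`.
#'   Empty cells are absent (flagged via message).
#' @export
prediction_metrics <- function(predictions, cohort, age_cut = 45) {
  df <- predictions %>%
    inner_join(as_tibble(cohort)[c("sample_id", "group")], by = "sample_id")
  if (!nrow(df)) abort("predictions and cohort share no samples")
  strat <- function(d, label) {
    d %>%
      group_by(.data$group) %>%
      summarise(stratum = label, n = n(),
                mae = mean(.data$abs_error), me = mean(.data$error),
                mean_predicted = mean(.data$predicted_age),
                sd_abs_error = sd(.data$abs_error),
                sd_error = sd(.data$error),
                sd_predicted = sd(.data$predicted_age),
                .groups = "drop")
  }
  out <- bind_rows(
    strat(df, "all"),
    strat(filter(df, .data$chronological_age <= age_cut),
          paste0("<=", age_cut)),
    strat(filter(df, .data$chronological_age > age_cut),
          paste0(">=", age_cut + 1))
  )
  expected <- 2 * 3
  if (nrow(out) < expected) inform("some (group, stratum) cells are empty")
  out
}

#' @export
print.cpg_age_model <- function(x, ...) {
  cat("<cpg_age_model> subset=", x$subset,
      " (synthetic-trained, not published coefficients)\n", sep = "")
  cat(sprintf("  n=%d  R2=%.3f  training MAE=%.2f years\n",
              x$training_n, x$training_r2, x$training_mae))
  cat(sprintf("  intercept %.3f + %d site coefficient(s)\n",
              x$intercept, length(x$coefficients)))
  invisible(x)
}

#' @rdname fit_age_model
#' @param x,object A `cpg_age_model`.
#' @param ... Unused.
#' @export
tidy.cpg_age_model <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4])
  )
}

#' @rdname fit_age_model
#' @export
glance.cpg_age_model <- function(x, ...) {
  tibble(subset = x$subset, n = x$training_n,
         r.squared = x$training_r2, mae = x$training_mae)
}

#' Serialize / deserialize a fitted age model as JSON
#'
#' The JSON carries the intercept, the `marker:label`-keyed coefficients
#' and a provenance block recording that the coefficients are trained on
#' supplied data.
#'
#' @param model A `cpg_age_model`.
#' @param path JSON file path.
#' @return `path` invisibly; `read_age_model()` returns a `cpg_age_model`
#'   (without the underlying `lm`, so [tidy()] is unavailable on it).
#' @export
write_age_model <- function(model, path) {
  jsonlite::write_json(list(
    subset = model$subset,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    training = list(n = model$training_n, r2 = model$training_r2,
                    mae = model$training_mae,
                    mean_age = model$training_mean_age),
    provenance = "trained on supplied data; not published coefficients"
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_age_model
#' @export
read_age_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- names(j$coefficients)
  parts <- strsplit(keys, ":", fixed = TRUE)
  structure(list(
    intercept = j$intercept,
    coefficients = setNames(unlist(j$coefficients), keys),
    sites = tibble(marker = vapply(parts, `[`, "", 1),
                   cpg_label = vapply(parts, `[`, "", 2)),
    subset = j$subset,
    training_n = j$training$n,
    training_r2 = j$training$r2,
    training_mae = j$training$mae,
    training_mean_age = j$training$mean_age,
    fit = NULL
  ), class = "cpg_age_model")
}
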