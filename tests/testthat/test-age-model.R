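test_that("OLS recovers a noiseless linear law to machine precision", {
  set.seed(101)
  panel <- visage_panel()
  sites <- resolve_sites(panel, "blood6")
  n <- 40
  ids <- sprintf("S%03d", seq_len(n))
  meth <- meth_at_sites(ids, sites)
  meth$meth_pct <- runif(nrow(meth), 10, 90)
  true_coef <- c(0.9, -1.4, 0.5, 0.3, 0.8, -0.2)
  wide <- tidyr::pivot_wider(
    dplyr::mutate(meth, site = paste0(marker, ":", cpg_label)),
    id_cols = "sample_id", names_from = "site", values_from = "meth_pct")
  keys <- paste0(sites$marker, ":", sites$cpg_label)
  ages <- 12 + as.matrix(wide[keys]) %*% true_coef
  cohort <- tibble::tibble(sample_id = wide$sample_id, age = as.vector(ages))

  fit <- fit_age_model(meth, cohort, "blood6")
  expect_equal(unname(fit$coefficients[keys]), true_coef, tolerance = 1e-8)
  expect_equal(fit$intercept, 12, tolerance = 1e-8)
  expect_equal(fit$training_mae, 0, tolerance = 1e-8)
  expect_equal(fit$training_r2, 1, tolerance = 1e-10)
})

test_that("a three-point single-site fit matches the hand calculation", {
  site <- tibble::tibble(marker = "MIR29B2CHG", cpg_label = "C1")
  meth <- tibble::tibble(sample_id = c("S1", "S2", "S3"),
                         marker = "MIR29B2CHG", cpg_label = "C1",
                         depth = 5000, meth_pct = c(60, 50, 40),
                         qc_reason = NA_character_)
  cohort <- tibble::tibble(sample_id = c("S1", "S2", "S3"),
                           age = c(30, 40, 50))
  fit <- fit_age_model(meth, cohort, site)
  expect_equal(unname(fit$coefficients), -1)
  expect_equal(fit$intercept, 90)

  pred <- predict_age(fit, dplyr::mutate(meth, meth_pct = 45))
  expect_equal(pred$predicted_age, rep(45, 3))
})

test_that("OLS training properties hold: residual sum, mean prediction, MAE", {
  set.seed(102)
  cfg <- sim_config(n_pairs = 30, seed = 55)
  dat <- simulate_study_data(cfg)
  meth <- call_methylation(dat$counts, min_depth = 1)
  ctrl <- dplyr::filter(dat$cohort, group == "control")
  fit <- fit_age_model(meth, ctrl, "blood6")

  pred <- predict_age(fit, meth, ctrl)
  pred <- pred[!is.na(pred$chronological_age), ]
  # residuals sum to zero with an intercept in the model
  expect_lt(abs(sum(pred$error)), 1e-8 * nrow(pred) * sd(pred$error))
  # applying the model to its training data reproduces the training MAE
  expect_equal(mean(pred$abs_error), fit$training_mae, tolerance = 1e-12)

  # a sample sitting at the training methylation means predicts the mean age
  means <- dplyr::summarise(
    dplyr::semi_join(dplyr::filter(meth, sample_id %in% ctrl$sample_id),
                     fit$sites, by = c("marker", "cpg_label")),
    meth_pct = mean(meth_pct), .by = c("marker", "cpg_label"))
  at_mean <- dplyr::mutate(means, sample_id = "MEAN", depth = 5000,
                           qc_reason = NA_character_)
  expect_equal(predict_age(fit, at_mean)$predicted_age,
               fit$training_mean_age, tolerance = 1e-9)
})

test_that("degenerate designs raise informative errors", {
  sites <- resolve_sites(visage_panel(), "blood6")
  ids <- sprintf("S%02d", 1:10)
  meth <- meth_at_sites(ids, sites, value = 50)
  meth$meth_pct <- runif(nrow(meth), 20, 80)
  meth$meth_pct[meth$marker == "KLF14"] <- 33  # constant predictor
  cohort <- tibble::tibble(sample_id = ids, age = 31:40)
  expect_error(fit_age_model(meth, cohort, "blood6"), "KLF14")

  expect_error(
    fit_age_model(meth_at_sites(ids[1:5], sites), cohort[1:5, ], "blood6"),
    "at least")
})

test_that("samples missing model sites are omitted from prediction, not fatal", {
  site <- tibble::tibble(marker = "MIR29B2CHG", cpg_label = "C1")
  meth <- tibble::tibble(sample_id = sprintf("S%d", 1:5),
                         marker = "MIR29B2CHG", cpg_label = "C1",
                         depth = 5000,
                         meth_pct = c(60, 55, NA, 45, 40),
                         qc_reason = c(NA, NA, "low_depth", NA, NA))
  cohort <- tibble::tibble(sample_id = sprintf("S%d", 1:5),
                           age = c(30, 35, 40, 45, 50))
  fit <- fit_age_model(meth, cohort, site)
  expect_message(pred <- predict_age(fit, meth, cohort), "omitting")
  expect_equal(nrow(pred), 4)
  expect_false("S3" %in% pred$sample_id)

  empty <- predict_age(fit, meth[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("stratified metrics compute MAE and ME per cell", {
  cohort <- tibble::tibble(
    sample_id = sprintf("S%d", 1:6),
    age = c(40, 42, 44, 50, 52, 54),
    group = rep(c("abuser", "control"), 3)
  )
  pred <- tibble::tibble(
    sample_id = cohort$sample_id,
    predicted_age = cohort$age + c(1, -2, 3, 1, -2, 3),
    chronological_age = cohort$age,
    error = c(1, -2, 3, 1, -2, 3),
    abs_error = abs(c(1, -2, 3, 1, -2, 3))
  )
  m <- prediction_metrics(pred, cohort, age_cut = 45)
  all_ab <- m[m$group == "abuser" & m$stratum == "all", ]
  expect_equal(all_ab$mae, mean(c(1, 3, 2)))
  expect_equal(all_ab$me, mean(c(1, 3, -2)))
  young <- m[m$stratum == "<=45" & m$group == "abuser", ]
  expect_equal(young$n, 2)

  zero <- dplyr::mutate(pred, error = 0, abs_error = 0,
                        predicted_age = chronological_age)
  mz <- prediction_metrics(zero, cohort)
  expect_true(all(mz$mae == 0) && all(mz$me == 0))
})

test_that("MAE never falls below |ME|, with equality for one-signed errors", {
  set.seed(103)
  for (i in 1:25) {
    e <- rnorm(20, sd = sample(1:5, 1)) + sample(-3:3, 1)
    expect_gte(mean(abs(e)), abs(mean(e)))
  }
  one_sign <- abs(rnorm(20))
  expect_equal(mean(abs(one_sign)), abs(mean(one_sign)))
})

test_that("an injected shift moves predictions by shift times coefficient", {
  # sigma = 0 construction: control methylation exactly linear in age,
  # abusers shifted by -2.1 points at MIR29B2CHG C1
  ages <- rep(30:49, 2)
  ids <- sprintf("S%03d", seq_along(ages))
  group <- rep(c("control", "abuser"), each = 20)
  meth_val <- 75 - 0.35 * ages + ifelse(group == "abuser", -2.1, 0)
  meth <- tibble::tibble(sample_id = ids, marker = "MIR29B2CHG",
                         cpg_label = "C1", depth = 5000,
                         meth_pct = meth_val, qc_reason = NA_character_)
  cohort <- tibble::tibble(sample_id = ids, age = ages, group = group)
  fit <- fit_age_model(meth, dplyr::filter(cohort, group == "control"),
                       "mir29_c1")
  pred <- predict_age(fit, meth, cohort)
  by_group <- tapply(pred$predicted_age, cohort$group[match(pred$sample_id,
                                                            cohort$sample_id)],
                     mean)
  expect_equal(unname(by_group["abuser"] - by_group["control"]),
               2.1 * abs(unname(fit$coefficients)), tolerance = 1e-9)
})

test_that("models serialize to JSON and back without changing predictions", {
  dat <- simulate_study_data(sim_config(n_pairs = 25, seed = 77))
  meth <- call_methylation(dat$counts, min_depth = 1)
  fit <- fit_age_model(meth, dplyr::filter(dat$cohort, group == "control"),
                       "blood6")
  path <- withr::local_tempfile(fileext = ".json")
  write_age_model(fit, path)
  back <- read_age_model(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(predict_age(back, meth), predict_age(fit, meth))

  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 7)
  expect_equal(glance(fit)$mae, fit$training_mae)
})
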