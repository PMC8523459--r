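#' Default per-site linear methylation parameters
#'
#' Each CpG follows a linear age law on the percent scale:
#' `meth = b0 + b1 * age + noise`, with `b0` the extrapolated level at age 0,
#' `b1` the slope in percentage points per year (sign matching the site's
#' age direction) and `sigma` the biological between-individual SD in
#' percentage points. The six blood-model sites carry the strongest, most
#' site-specific settings; the remaining sites get direction-consistent
#' defaults. The values are calibrated so a six-CpG model fit on synthetic
#' controls aged 30-60 reaches a training MAE near 3.2 years.
#'
#' @param panel A panel tibble (default [visage_panel()]).
#' @return A tibble `marker`, `cpg_label`, `b0`, `b1`, `sigma`.
#' @export
default_site_params <- function(panel = visage_panel()) {
  specific <- tibble(
    marker    = c("ELOVL2", "MIR29B2CHG", "KLF14", "FHL2", "TRIM59", "PDE4C",
                  "MIR29B2CHG", "MIR29B2CHG", "FHL2", "EDARADD", "EDARADD"),
    cpg_label = c("C7", "C1", "C4", "C1", "C8", "C5",
                  "C2", "C3", "C7", "C1", "C2"),
    b0    = c(15, 75,  2, 20, 10, 15, 72, 74, 22, 62, 58),
    b1    = c(0.90, -0.35, 0.25, 0.30, 0.50, 0.45,
              -0.30, -0.32, 0.25, -0.28, -0.22),
    sigma = c(5.9, 3.5, 3.0, 4.7, 5.3, 4.7, 3.5, 3.5, 3.5, 3.0, 3.0)
  )
  out <- as_tibble(panel)[c("marker", "cpg_label", "age_direction")] %>%
    left_join(specific, by = c("marker", "cpg_label")) %>%
    mutate(
      b1    = dplyr::coalesce(.data$b1,
                              ifelse(.data$age_direction == "increases",
                                     0.25, -0.25)),
      b0    = dplyr::coalesce(.data$b0,
                              ifelse(.data$age_direction == "increases",
                                     18, 70)),
      sigma = dplyr::coalesce(.data$sigma, 3.5)
    ) %>%
    select(-"age_direction")
  out
}

#' Default abuser-vs-control methylation shifts
#'
#' Percentage-point shifts added to abusers' latent methylation: -2.1, -2.8
#' and -3.0 at *MIR29B2CHG* C1, C2 and C3, and -1.7 at *FHL2* C7; zero
#' elsewhere.
#'
#' @return A tibble `marker`, `cpg_label`, `delta`.
#' @export
default_group_deltas <- function() {
  tibble(
    marker    = c("MIR29B2CHG", "MIR29B2CHG", "MIR29B2CHG", "FHL2"),
    cpg_label = c("C1", "C2", "C3", "C7"),
    delta     = c(-2.1, -2.8, -3.0, -1.7)
  )
}

#' Default relative read-depth weights per marker
#'
#' Relative allocation of a sample's total paired reads across the eight
#' amplicons. The defaults reproduce the observed imbalance pattern:
#' *TRIM59* and *FHL2* overperform (normalized read depth above 1) while
#' *PDE4C* receives the least depth per CpG.
#'
#' @return A named numeric vector of positive weights.
#' @export
default_marker_weights <- function() {
  # weight = target per-site depth ratio x number of CpGs in the amplicon
  c(ELOVL2 = 6.75, MIR29B2CHG = 4.4, KLF14 = 3.4, FHL2 = 16.0,
    TRIM59 = 15.2, PDE4C = 3.0, EDARADD = 2.0, ASPA = 1.6)
}

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic matched
#' case-control cohort. Defaults emulate the study conditions: 100 pairs
#' aged 30-60 (83% male), linear age-dependent methylation per CpG, abuser
#' shifts at four CpGs, per-sample coverage 316,048 +/- 28,300 paired reads
#' with marker-skewed allocation, bisulfite non-conversion 0.4% and
#' misincorporation 0.1%.
#'
#' @param n_pairs Number of matched abuser/control pairs.
#' @param age_range Integer age range sampled uniformly, inclusive.
#' @param male_fraction Probability a pair is male.
#' @param site_params Per-site `b0`/`b1`/`sigma` tibble
#'   (default [default_site_params()]).
#' @param group_deltas Per-site abuser shift tibble
#'   (default [default_group_deltas()]).
#' @param delta_age_interaction Optional multiplier: each delta is scaled by
#'   `1 + delta_age_interaction * max(0, age - 45)`, emulating a
#'   duration-of-exposure effect in the older stratum. Default 0.
#' @param total_depth_mean,total_depth_sd Per-sample total paired reads,
#'   normal truncated at zero.
#' @param marker_weights Named positive weights
#'   (default [default_marker_weights()]).
#' @param non_cpg_positions Conversion-control cytosines per amplicon.
#' @param non_conversion_rate Probability an unmethylated C escapes
#'   conversion (reads as C).
#' @param misincorporation_rate Probability a read carries neither C nor T.
#' @param seed Optional integer seed; fixed seeds give byte-identical
#'   output.
#' @param panel Panel the simulation covers.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_pairs = 100L,
                       age_range = c(30L, 60L),
                       male_fraction = 0.83,
                       site_params = default_site_params(panel),
                       group_deltas = default_group_deltas(),
                       delta_age_interaction = 0,
                       total_depth_mean = 316048,
                       total_depth_sd = 28300,
                       marker_weights = default_marker_weights(),
                       non_cpg_positions = 20L,
                       non_conversion_rate = 0.004,
                       misincorporation_rate = 0.001,
                       seed = NULL,
                       panel = visage_panel()) {
  if (n_pairs < 1) abort("n_pairs must be at least 1")
  if (length(age_range) != 2 || age_range[1] > age_range[2]) {
    abort("age_range must be c(min, max) with min <= max")
  }
  if (male_fraction < 0 || male_fraction > 1) {
    abort("male_fraction must lie in [0, 1]")
  }
  if (non_conversion_rate < 0 || non_conversion_rate >= 1 ||
      misincorporation_rate < 0 || misincorporation_rate >= 1) {
    abort("rates must lie in [0, 1)")
  }
  if (any(marker_weights <= 0)) abort("marker_weights must be positive")
  if (any(site_params$sigma < 0)) abort("sigma must be non-negative")
  missing_w <- setdiff(unique(panel$marker), names(marker_weights))
  if (length(missing_w)) {
    abort(paste0("marker_weights missing for: ",
                 paste(missing_w, collapse = ", ")))
  }
  structure(
    list(n_pairs = as.integer(n_pairs),
         age_range = as.integer(age_range),
         male_fraction = male_fraction,
         site_params = as_tibble(site_params),
         group_deltas = as_tibble(group_deltas),
         delta_age_interaction = delta_age_interaction,
         total_depth_mean = total_depth_mean,
         total_depth_sd = total_depth_sd,
         marker_weights = marker_weights,
         non_cpg_positions = as.integer(non_cpg_positions),
         non_conversion_rate = non_conversion_rate,
         misincorporation_rate = misincorporation_rate,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         panel = panel),
    class = "sim_config"
  )
}

#' Read a simulation configuration from YAML
#'
#' Scalar fields override [sim_config()] defaults; `site_params` and
#' `group_deltas` may be given as lists of records.
#'
#' @param path YAML file.
#' @return A `sim_config` list.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      setdiff(names(formals(sim_config)), "panel"))]
  for (fld in c("site_params", "group_deltas")) {
    if (!is.null(args[[fld]])) args[[fld]] <- bind_rows(lapply(args[[fld]], as_tibble))
  }
  if (!is.null(args$marker_weights)) args$marker_weights <- unlist(args$marker_weights)
  if (!is.null(args$age_range)) args$age_range <- unlist(args$age_range)
  do.call(sim_config, args)
}

maybe_seed <- function(seed) {
  if (!is.null(seed)) set.seed(seed)
  invisible(NULL)
}

#' Simulate a matched case-control cohort
#'
#' Draws `n_pairs` pairs; within a pair the abuser and control share an
#' integer age (uniform over the configured range) and sex (male with the
#' configured probability), so groups are perfectly matched by construction.
#'
#' @param config A [sim_config()].
#' @return A cohort tibble (`sample_id`, `age`, `sex`, `group`, `pair_id`,
#'   `flagged`).
#' @export
simulate_cohort <- function(config) {
  maybe_seed(config$seed)
  n <- config$n_pairs
  ages <- sample(seq(config$age_range[1], config$age_range[2]), n,
                 replace = TRUE)
  sexes <- ifelse(runif(n) < config$male_fraction, "male", "female")
  pair_id <- sprintf("P%04d", seq_len(n))
  cohort <- tibble(
    sample_id = c(sprintf("A%04d", seq_len(n)), sprintf("C%04d", seq_len(n))),
    age = rep(ages, 2),
    sex = rep(sexes, 2),
    group = rep(c("abuser", "control"), each = n),
    pair_id = rep(pair_id, 2),
    flagged = FALSE
  )
  validate_cohort(cohort, age_tolerance = 0)
}

#' Simulate latent per-sample methylation
#'
#' Applies the linear age law with additive Gaussian biological noise and
#' the abuser shift, clips to the percent scale:
#' `meth = clip(b0 + b1 * age + delta * [abuser] * (1 + dai * (age - 45)+) + e, 0, 100)`.
#'
#' @param cohort A cohort tibble.
#' @param config A [sim_config()].
#' @return A truth tibble `sample_id`, `marker`, `cpg_label`,
#'   `true_meth_pct` (0-100).
#' @export
simulate_true_methylation <- function(cohort, config) {
  maybe_seed(config$seed)
  panel <- as_tibble(config$panel)[c("marker", "cpg_label")]
  params <- left_join(panel, config$site_params, by = c("marker", "cpg_label"))
  if (anyNA(params$b0) || anyNA(params$b1) || anyNA(params$sigma)) {
    bad <- site_key(params$marker, params$cpg_label)[is.na(params$b0) |
                                                     is.na(params$b1) |
                                                     is.na(params$sigma)]
    abort(paste0("missing site parameters for: ", paste(bad, collapse = ", ")))
  }
  params <- left_join(params, config$group_deltas, by = c("marker", "cpg_label")) %>%
    mutate(delta = dplyr::coalesce(.data$delta, 0))

  grid <- tidyr::crossing(as_tibble(cohort)[c("sample_id", "age", "group")],
                          params)
  dai <- config$delta_age_interaction
  meth <- with(grid,
    b0 + b1 * age +
      delta * (group == "abuser") * (1 + dai * pmax(0, age - 45)) +
      rnorm(nrow(grid), 0, grid$sigma))
  grid$true_meth_pct <- pmin(pmax(meth, 0), 100)
  grid[c("sample_id", "marker", "cpg_label", "true_meth_pct")]
}

#' Simulate bisulfite amplicon read counts
#'
#' Per sample, a total paired-read depth is drawn from a normal truncated
#' at zero, allocated to amplicons proportionally to `marker_weights` and
#' split evenly across each amplicon's CpGs. At a site with depth `d` and
#' true methylation fraction `f`: `other_reads ~ Binomial(d, eta)` and the
#' remaining reads are C with probability `f + (1 - f) * eps` (incomplete
#' conversion inflates C), else T. Conversion controls aggregate the
#' amplicon's non-CpG cytosines with T probability `1 - eps`.
#'
#' @param truth Truth tibble from [simulate_true_methylation()].
#' @param config A [sim_config()].
#' @return A list with `counts` (count tibble) and `controls`
#'   (conversion-control tibble).
#' @export
simulate_read_counts <- function(truth, config) {
  maybe_seed(config$seed)
  panel <- as_tibble(config$panel)
  missing_sites <- anti_join(panel[c("marker", "cpg_label")],
                             truth[c("marker", "cpg_label")],
                             by = c("marker", "cpg_label"))
  if (nrow(missing_sites)) {
    abort("truth table does not cover all panel sites")
  }
  eps <- config$non_conversion_rate
  eta <- config$misincorporation_rate
  w <- config$marker_weights / sum(config$marker_weights)
  n_cpg <- table(panel$marker)

  samples <- unique(truth$sample_id)
  totals <- pmax(rnorm(length(samples), config$total_depth_mean,
                       config$total_depth_sd), 0)
  depth_tbl <- tibble(sample_id = samples, total_depth = totals)

  counts <- truth %>%
    left_join(depth_tbl, by = "sample_id") %>%
    mutate(
      site_depth = round(.data$total_depth * w[.data$marker] /
                           as.integer(n_cpg[.data$marker])),
      f = .data$true_meth_pct / 100
    )
  d <- counts$site_depth
  other <- rbinom(nrow(counts), d, eta)
  c_reads <- rbinom(nrow(counts), d - other, counts$f + (1 - counts$f) * eps)
  counts <- counts %>%
    mutate(other_reads = other,
           c_reads = c_reads,
           t_reads = d - other - c_reads) %>%
    select("sample_id", "marker", "cpg_label", "c_reads", "t_reads",
           "other_reads")

  ctrl <- tidyr::crossing(depth_tbl,
                          tibble(marker = names(w))) %>%
    mutate(ctrl_depth = pmax(round(.data$total_depth * w[.data$marker] /
                                     as.integer(n_cpg[.data$marker])) *
                               config$non_cpg_positions, 1))
  t_ctrl <- rbinom(nrow(ctrl), ctrl$ctrl_depth, 1 - eps)
  controls <- ctrl %>%
    mutate(t_reads = t_ctrl, c_reads = .data$ctrl_depth - t_ctrl) %>%
    select("sample_id", "marker", "t_reads", "c_reads")

  list(counts = counts, controls = controls)
}

#' Simulate a complete study data set
#'
#' Runs cohort, latent methylation and read-count simulation under a single
#' seed.
#'
#' @param config A [sim_config()].
#' @return A list with `cohort`, `truth`, `counts`, `controls`.
#' @export
simulate_study_data <- function(config) {
  maybe_seed(config$seed)
  inner <- config
  inner$seed <- NULL
  cohort <- simulate_cohort(inner)
  truth <- simulate_true_methylation(cohort, inner)
  rc <- simulate_read_counts(truth, inner)
  list(cohort = cohort, truth = truth,
       counts = rc$counts, controls = rc$controls)
}

#' Write the simulated tables to a directory
#'
#' Emits `counts.tsv`, `controls.tsv`, `cohort.csv` and `truth.tsv` in the
#' package's interchange formats.
#'
#' @param data Result of [simulate_study_data()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_data <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_table(data$counts, file.path(dir, "counts.tsv"))
  write_conversion_controls(data$controls, file.path(dir, "controls.tsv"))
  write_cohort(data$cohort, file.path(dir, "cohort.csv"))
  readr::write_tsv(
    data$truth %>% rename(true_methylation_pct = "true_meth_pct"),
    file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
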