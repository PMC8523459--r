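#' Read a per-CpG read-count table
#'
#' The table is the shape produced by extracting CpG positions from
#' bam-readcount output: one row per sample and CpG with paired-read counts
#' of C (methylated), T (converted) and any other base (misincorporation).
#'
#' @param path TSV with columns `sample_id`, `marker`, `cpg_label`,
#'   `c_reads`, `t_reads`, `other_reads`.
#' @param panel Optional panel to resolve records against; unknown sites
#'   raise a warning and are kept with `resolved = FALSE`.
#' @return A tibble of count records (plus a `resolved` column when a panel
#'   is supplied).
#' @export
read_count_table <- function(path, panel = NULL) {
  if (!file.exists(path)) abort(paste0("no such count table: ", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         sample_id = readr::col_character(),
                         marker = readr::col_character(),
                         cpg_label = readr::col_character(),
                         c_reads = readr::col_double(),
                         t_reads = readr::col_double(),
                         other_reads = readr::col_double()
                       ))
  validate_counts(x)
  if (!is.null(panel)) {
    known <- site_key(panel$marker, panel$cpg_label)
    x$resolved <- site_key(x$marker, x$cpg_label) %in% known
    if (any(!x$resolved)) {
      bad <- unique(site_key(x$marker, x$cpg_label)[!x$resolved])
      warn(paste0("count table contains sites absent from the panel: ",
                  paste(bad, collapse = ", ")))
    }
  }
  x
}

validate_counts <- function(x) {
  required <- c("sample_id", "marker", "cpg_label", "c_reads", "t_reads",
                "other_reads")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(paste0("count table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cnt <- c(x$c_reads, x$t_reads, x$other_reads)
  if (anyNA(cnt) || any(cnt < 0)) {
    abort("read counts must be non-negative integers")
  }
  invisible(x)
}

#' Write a per-CpG read-count table
#' @param counts Count tibble (see [read_count_table()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  validate_counts(counts)
  cols <- c("sample_id", "marker", "cpg_label", "c_reads", "t_reads",
            "other_reads")
  readr::write_tsv(counts[cols], path, progress = FALSE)
  invisible(path)
}

#' Read / write non-CpG conversion-control counts
#'
#' One row per sample and amplicon: `t_reads` converted (as expected at a
#' non-CpG cytosine after complete bisulfite conversion) and `c_reads`
#' unconverted.
#'
#' @param path TSV with columns `sample_id`, `marker`, `t_reads`, `c_reads`.
#' @return A tibble of conversion-control records.
#' @export
read_conversion_controls <- function(path) {
  if (!file.exists(path)) abort(paste0("no such control table: ", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("sample_id", "marker", "t_reads", "c_reads")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(paste0("control table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(x$t_reads + x$c_reads <= 0)) {
    abort("conversion-control records must have positive total reads")
  }
  x
}

#' @rdname read_conversion_controls
#' @param controls Control tibble.
#' @export
write_conversion_controls <- function(controls, path) {
  readr::write_tsv(
    controls[c("sample_id", "marker", "t_reads", "c_reads")], path,
    progress = FALSE)
  invisible(path)
}

#' Load a matched case-control cohort
#'
#' @param path CSV with columns `sample_id`, `age`, `sex` (`male`/`female`),
#'   `group` (`abuser`/`control`), `pair_id`, and optionally `flagged`
#'   (pre-analysis exclusions such as failed libraries).
#' @param age_tolerance Maximum allowed within-pair age difference in years
#'   (0 = perfectly matched).
#' @return A validated cohort tibble.
#' @export
load_cohort <- function(path, age_tolerance = 0) {
  if (!file.exists(path)) abort(paste0("no such cohort file: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(x, age_tolerance = age_tolerance)
}

#' Validate cohort metadata and its pairing structure
#'
#' Each `pair_id` must hold exactly one abuser and one control of the same
#' sex with ages within `age_tolerance` years; ages must be plausible.
#'
#' @param cohort Cohort data frame.
#' @param age_tolerance Maximum within-pair age difference in years.
#' @return The cohort as a tibble (rows ordered by `pair_id` then `group`),
#'   with a `flagged` column added if absent.
#' @export
validate_cohort <- function(cohort, age_tolerance = 0) {
  x <- as_tibble(cohort)
  required <- c("sample_id", "age", "sex", "group", "pair_id")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    abort(paste0("cohort is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"flagged" %in% names(x)) x$flagged <- FALSE
  x$flagged[is.na(x$flagged)] <- FALSE
  if (anyDuplicated(x$sample_id)) abort("duplicated sample_id in cohort")
  if (any(is.na(x$age) | x$age <= 0 | x$age >= 130)) {
    abort("ages must lie strictly between 0 and 130 years")
  }
  if (!all(x$sex %in% c("male", "female"))) {
    abort("sex must be 'male' or 'female'")
  }
  if (!all(x$group %in% c("abuser", "control"))) {
    abort("group must be 'abuser' or 'control'")
  }

  chk <- x %>%
    group_by(.data$pair_id) %>%
    summarise(
      n = n(),
      n_abuser = sum(.data$group == "abuser"),
      n_sex = n_distinct(.data$sex),
      age_gap = max(.data$age) - min(.data$age),
      .groups = "drop"
    )
  bad_comp <- chk$pair_id[chk$n != 2 | chk$n_abuser != 1]
  if (length(bad_comp)) {
    abort(paste0("pairs must hold exactly one abuser and one control; ",
                 "offending pair_id: ", paste(bad_comp, collapse = ", ")))
  }
  bad_sex <- chk$pair_id[chk$n_sex != 1]
  if (length(bad_sex)) {
    abort(paste0("sex mismatch within pair_id: ",
                 paste(bad_sex, collapse = ", ")))
  }
  bad_age <- chk$pair_id[chk$age_gap > age_tolerance]
  if (length(bad_age)) {
    abort(paste0("age difference above tolerance (", age_tolerance,
                 ") within pair_id: ", paste(bad_age, collapse = ", ")))
  }
  arrange(x, .data$pair_id, .data$group)
}

#' @rdname load_cohort
#' @param cohort Cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(as_tibble(cohort), path, progress = FALSE)
  invisible(path)
}
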