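#' Call methylation percentages from read counts
#'
#' The methylation level at a CpG is the C-read percentage,
#' `100 * C / (C + T)`; reads that are neither C nor T (misincorporations)
#' never enter the denominator. Sites whose paired-read depth `C + T` falls
#' below `min_depth` are set missing with reason `"low_depth"`; sites with
#' no C or T reads at all are missing with reason `"no_data"`.
#'
#' @param counts Count tibble (see [read_count_table()]).
#' @param panel Panel to resolve sites against; records not in the panel are
#'   dropped with a warning.
#' @param min_depth Minimum paired reads (R1 + R2) required to call a value.
#' @return A methylation tibble: `sample_id`, `marker`, `cpg_label`,
#'   `depth` (C + T), `meth_pct` (in \[0, 100\] or `NA`), `qc_reason`
#'   (`NA` when called).
#' @examples
#' counts <- tibble::tibble(sample_id = "S1", marker = "ELOVL2",
#'                          cpg_label = "C7", c_reads = 750, t_reads = 250,
#'                          other_reads = 1)
#' call_methylation(counts, min_depth = 0)
#' @export
call_methylation <- function(counts, panel = visage_panel(), min_depth = 1000) {
  validate_counts(counts)
  known <- site_key(panel$marker, panel$cpg_label)
  resolved <- site_key(counts$marker, counts$cpg_label) %in% known
  if (any(!resolved)) {
    warn(paste0("dropping ", sum(!resolved),
                " count record(s) at sites absent from the panel"))
    counts <- counts[resolved, ]
  }
  counts %>%
    mutate(
      depth = .data$c_reads + .data$t_reads,
      meth_pct = ifelse(.data$depth >= max(min_depth, 1) & .data$depth > 0,
                        100 * .data$c_reads / .data$depth, NA_real_),
      qc_reason = case_when(
        .data$depth == 0 ~ "no_data",
        .data$depth < min_depth ~ "low_depth",
        TRUE ~ NA_character_
      )
    ) %>%
    select("sample_id", "marker", "cpg_label", "depth", "meth_pct",
           "qc_reason")
}

#' Per-sample bisulfite conversion efficiency
#'
#' For each sample, the mean over amplicons of the T-read percentage at
#' non-CpG cytosines, `100 * T / (T + C)`; complete conversion gives 100.
#'
#' @param controls Conversion-control tibble
#'   (see [read_conversion_controls()]).
#' @return A tibble `sample_id`, `conversion_efficiency_pct`, `n_amplicons`,
#'   `flagged` (`TRUE` when a sample had no usable control reads).
#' @export
conversion_efficiency <- function(controls) {
  controls %>%
    mutate(tot = .data$t_reads + .data$c_reads) %>%
    group_by(.data$sample_id) %>%
    summarise(
      conversion_efficiency_pct =
        mean(ifelse(.data$tot > 0, 100 * .data$t_reads / .data$tot, NA_real_),
             na.rm = TRUE),
      n_amplicons = sum(.data$tot > 0),
      .groups = "drop"
    ) %>%
    mutate(
      conversion_efficiency_pct = ifelse(is.nan(.data$conversion_efficiency_pct),
                                         NA_real_,
                                         .data$conversion_efficiency_pct),
      flagged = .data$n_amplicons == 0
    )
}

#' Base misincorporation rate at target CpGs
#'
#' The percentage of reads carrying neither C nor T,
#' `100 * other / (C + T + other)`, per site and overall as a read-weighted
#' mean.
#'
#' @param counts Count tibble.
#' @return A list with `overall_pct` (scalar) and `per_site` (tibble
#'   `marker`, `cpg_label`, `misincorporation_pct`).
#' @export
misincorporation_rate <- function(counts) {
  validate_counts(counts)
  per_site <- counts %>%
    group_by(.data$marker, .data$cpg_label) %>%
    summarise(
      total = sum(.data$c_reads + .data$t_reads + .data$other_reads),
      misincorporation_pct = ifelse(.data$total > 0,
                                    100 * sum(.data$other_reads) / .data$total,
                                    NA_real_),
      .groups = "drop"
    ) %>%
    select(-"total")
  tot <- sum(counts$c_reads + counts$t_reads + counts$other_reads)
  overall <- if (tot > 0) 100 * sum(counts$other_reads) / tot else NA_real_
  list(overall_pct = overall, per_site = per_site)
}

#' Normalized read depth per marker
#'
#' Read balance across the eight amplicons, computed from one designated
#' CpG per marker: the marker's mean depth at its representative site
#' divided by the grand mean over all representative sites, so the ratios
#' average to 1 under perfectly even allocation. By default the
#' representative site is the marker's blood-model CpG when it has one,
#' otherwise its first panel site.
#'
#' @param counts Count tibble.
#' @param panel Panel tibble.
#' @param representative_sites Optional tibble `marker`, `cpg_label`
#'   overriding the default choice.
#' @return A tibble `marker`, `cpg_label`, `mean_depth`, `normalized_depth`.
#' @export
normalized_read_depth <- function(counts, panel = visage_panel(),
                                  representative_sites = NULL) {
  if (is.null(representative_sites)) {
    representative_sites <- as_tibble(panel) %>%
      arrange(.data$marker, dplyr::desc(.data$in_blood_model), .data$pos) %>%
      group_by(.data$marker) %>%
      summarise(cpg_label = first(.data$cpg_label), .groups = "drop")
  }
  dup <- anyDuplicated(representative_sites$marker)
  if (dup) abort("exactly one representative site per marker is required")
  depth <- counts %>%
    inner_join(representative_sites, by = c("marker", "cpg_label")) %>%
    group_by(.data$marker, .data$cpg_label) %>%
    summarise(mean_depth = mean(.data$c_reads + .data$t_reads +
                                  .data$other_reads),
              .groups = "drop")
  out <- representative_sites %>%
    left_join(depth, by = c("marker", "cpg_label")) %>%
    mutate(normalized_depth = .data$mean_depth /
             mean(.data$mean_depth, na.rm = TRUE))
  out
}

#' Apply pair-preserving QC exclusions
#'
#' A sample is excluded when it is pre-flagged in the cohort (e.g. a failed
#' library) or lacks a called value at any required site; in pair-preserving
#' mode its matched partner is excluded too (reason `"matched_exclusion"`),
#' so the filtered cohort keeps its one-abuser-one-control pairing and
#' identical age/sex margins between groups.
#'
#' @param methylation Methylation tibble from [call_methylation()].
#' @param cohort Cohort tibble (column `flagged` marks pre-analysis
#'   exclusions).
#' @param required_sites Tibble `marker`, `cpg_label` of sites every
#'   retained sample must have; defaults to the blood-model CpGs of
#'   *ELOVL2* and *PDE4C*.
#' @param pair_preserving Drag the matched partner of every excluded sample.
#' @return A list with `methylation` and `cohort` (filtered) and
#'   `exclusions` (tibble `sample_id`, `pair_id`, `reason`,
#'   `dragged_pair_member`).
#' @export
apply_qc_exclusions <- function(methylation, cohort,
                                required_sites = NULL,
                                pair_preserving = TRUE) {
  cohort <- validate_cohort(cohort, age_tolerance = Inf)
  if (is.null(required_sites)) {
    p <- visage_panel()
    required_sites <- as_tibble(p)[p$in_blood_model &
                                     p$marker %in% c("ELOVL2", "PDE4C"),
                                   c("marker", "cpg_label")]
  }
  required_sites <- as_tibble(required_sites)[c("marker", "cpg_label")]

  called <- methylation %>%
    filter(is.na(.data$qc_reason)) %>%
    semi_join(required_sites, by = c("marker", "cpg_label")) %>%
    count(.data$sample_id, name = "n_called")
  have <- cohort %>%
    left_join(called, by = "sample_id") %>%
    mutate(n_called = dplyr::coalesce(.data$n_called, 0L))

  direct <- have %>%
    mutate(reason = case_when(
      .data$flagged ~ "pre_flagged",
      .data$n_called < nrow(required_sites) ~ "missing_required_site",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$reason)) %>%
    select("sample_id", "pair_id", "reason")

  exclusions <- direct %>% mutate(dragged_pair_member = FALSE)
  if (pair_preserving && nrow(direct)) {
    partners <- cohort %>%
      filter(.data$pair_id %in% direct$pair_id,
             !.data$sample_id %in% direct$sample_id) %>%
      mutate(reason = "matched_exclusion", dragged_pair_member = TRUE) %>%
      select("sample_id", "pair_id", "reason", "dragged_pair_member")
    exclusions <- bind_rows(exclusions, partners)
  }

  keep <- !(cohort$sample_id %in% exclusions$sample_id)
  if (!any(keep)) abort("QC exclusions removed every sample")
  list(
    methylation = methylation %>%
      filter(.data$sample_id %in% cohort$sample_id[keep]),
    cohort = cohort[keep, ],
    exclusions = arrange(exclusions, .data$pair_id, .data$sample_id)
  )
}

#' Assemble a full QC report
#'
#' Bundles per-sample coverage, conversion efficiency, misincorporation,
#' normalized read depth and the pair-preserving exclusion list. The
#' normalized-depth definition (ratio of a marker's representative-site mean
#' depth to the grand mean, averaging 1 under even allocation) is recorded
#' in the report metadata.
#'
#' @inheritParams apply_qc_exclusions
#' @param counts Count tibble.
#' @param controls Conversion-control tibble (optional).
#' @param panel Panel tibble.
#' @param min_depth Minimum paired reads per CpG.
#' @return A `qc_report` list: `sample_coverage`, `conversion`,
#'   `misincorporation`, `normalized_depth`, `methylation`, `cohort`,
#'   `exclusions`, `meta`.
#' @export
qc_report <- function(counts, cohort, controls = NULL,
                      panel = visage_panel(), min_depth = 1000,
                      required_sites = NULL, pair_preserving = TRUE) {
  meth <- call_methylation(counts, panel, min_depth = min_depth)
  excl <- apply_qc_exclusions(meth, cohort, required_sites = required_sites,
                              pair_preserving = pair_preserving)
  structure(list(
    sample_coverage = counts %>%
      group_by(.data$sample_id) %>%
      summarise(total_paired_reads = sum(.data$c_reads + .data$t_reads +
                                           .data$other_reads),
                .groups = "drop"),
    conversion = if (is.null(controls)) NULL else conversion_efficiency(controls),
    misincorporation = misincorporation_rate(counts),
    normalized_depth = normalized_read_depth(counts, panel),
    methylation = excl$methylation,
    cohort = excl$cohort,
    exclusions = excl$exclusions,
    meta = list(
      min_depth = min_depth,
      pair_preserving = pair_preserving,
      normalized_depth_definition = paste(
        "representative-site mean depth / grand mean over markers;",
        "ratios average 1 under even allocation")
    )
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat("  samples in:  ", nrow(x$sample_coverage), "\n", sep = "")
  cat("  excluded:    ", nrow(x$exclusions), "\n", sep = "")
  cat("  retained:    ", nrow(x$cohort), "\n", sep = "")
  if (!is.null(x$conversion)) {
    cat(sprintf("  mean conversion efficiency: %.2f%%\n",
                mean(x$conversion$conversion_efficiency_pct, na.rm = TRUE)))
  }
  cat(sprintf("  misincorporation: %.3f%%\n",
              x$misincorporation$overall_pct))
  invisible(x)
}
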