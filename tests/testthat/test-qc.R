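test_that("methylation calling implements the C-read percentage", {
  counts <- tibble::tibble(
    sample_id = "S1",
    marker = c("ELOVL2", "PDE4C", "KLF14", "FHL2"),
    cpg_label = c("C7", "C5", "C4", "C1"),
    c_reads = c(750, 400, 1, 0),
    t_reads = c(250, 400, 3, 0),
    other_reads = c(5, 0, 0, 0)
  )
  m0 <- call_methylation(counts, min_depth = 0)
  expect_equal(m0$meth_pct[1], 75)
  expect_equal(m0$meth_pct[3], 25)
  expect_equal(m0$qc_reason[4], "no_data")

  m1000 <- call_methylation(counts, min_depth = 1000)
  expect_equal(m1000$meth_pct[1], 75)          # depth 1000 = C + T passes
  expect_true(is.na(m1000$meth_pct[2]))        # depth 800 fails
  expect_equal(m1000$qc_reason[2], "low_depth")
})

test_that("methylation is invariant to misincorporated reads and scaling", {
  base <- tibble::tibble(sample_id = "S1", marker = "ELOVL2",
                         cpg_label = "C7", c_reads = 1500, t_reads = 500,
                         other_reads = 0)
  with_other <- dplyr::mutate(base, other_reads = 400)
  scaled <- dplyr::mutate(base, c_reads = c_reads * 7, t_reads = t_reads * 7)
  v <- function(x) call_methylation(x, min_depth = 0)$meth_pct
  expect_equal(v(with_other), v(base))
  expect_equal(v(scaled), v(base))
})

test_that("conversion efficiency is the mean non-CpG T percentage", {
  ctrl <- tibble::tibble(
    sample_id = c("S1", "S2", "S3"),
    marker = "ELOVL2",
    t_reads = c(1000, 996, 0),
    c_reads = c(0, 4, 0)
  )
  eff <- conversion_efficiency(ctrl)
  expect_equal(eff$conversion_efficiency_pct[eff$sample_id == "S1"], 100)
  expect_equal(eff$conversion_efficiency_pct[eff$sample_id == "S2"], 99.6)
  # no usable control reads -> missing and flagged
  expect_true(is.na(eff$conversion_efficiency_pct[eff$sample_id == "S3"]))
  expect_true(eff$flagged[eff$sample_id == "S3"])

  # simulated at the default non-conversion rate: cohort mean near 99.6
  dat <- simulate_study_data(sim_config(n_pairs = 20, seed = 17))
  sim_eff <- conversion_efficiency(dat$controls)
  expect_lt(abs(mean(sim_eff$conversion_efficiency_pct) - 99.6), 0.1)
})

test_that("misincorporation rate is the other-read percentage", {
  counts <- tibble::tibble(
    sample_id = "S1", marker = c("ELOVL2", "PDE4C"),
    cpg_label = c("C7", "C5"),
    c_reads = c(500, 600), t_reads = c(499, 400), other_reads = c(1, 0)
  )
  mis <- misincorporation_rate(counts)
  expect_equal(mis$per_site$misincorporation_pct, c(0.1, 0))
  expect_equal(mis$overall_pct, 100 * 1 / 2000)
})

test_that("normalized read depth is the ratio to the grand mean", {
  panel <- visage_panel()
  rep_sites <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(panel), marker),
    cpg_label = cpg_label[1], .groups = "drop")
  equal <- dplyr::mutate(rep_sites, sample_id = "S1", c_reads = 500,
                         t_reads = 500, other_reads = 0)
  nd <- normalized_read_depth(equal, panel, rep_sites)
  expect_equal(nd$normalized_depth, rep(1, 8))

  # one marker at twice the depth of the other seven
  unequal <- equal
  unequal$c_reads[unequal$marker == "TRIM59"] <- 1500
  nd2 <- normalized_read_depth(unequal, panel, rep_sites)
  expect_equal(nd2$normalized_depth[nd2$marker == "TRIM59"], 16 / 9)
  expect_equal(nd2$normalized_depth[nd2$marker != "TRIM59"], rep(8 / 9, 7))
  expect_equal(mean(nd2$normalized_depth), 1)
})

test_that("pair-preserving exclusions drag partners and keep matching", {
  panel <- visage_panel()
  required <- tibble::as_tibble(panel)[panel$in_blood_model &
                                         panel$marker %in% c("ELOVL2", "PDE4C"), ]
  cohort <- make_pairs(106, flagged_ids = sprintf("A%04d", 1:4))
  meth <- meth_at_sites(cohort$sample_id, required)
  # two further samples in distinct pairs drop below depth at a required site
  low <- meth$sample_id %in% c("C0005", "A0006") & meth$marker == "PDE4C"
  meth$meth_pct[low] <- NA
  meth$qc_reason[low] <- "low_depth"

  res <- apply_qc_exclusions(meth, cohort, required_sites = required)
  expect_equal(nrow(res$cohort), 200)
  expect_equal(dplyr::n_distinct(res$cohort$pair_id), 100)
  expect_equal(nrow(res$exclusions), 12)
  expect_equal(sum(res$exclusions$reason == "matched_exclusion"), 6)
  expect_setequal(
    res$exclusions$sample_id[res$exclusions$reason == "pre_flagged"],
    sprintf("A%04d", 1:4))
  # the filtered cohort still satisfies all pairing invariants
  expect_silent(validate_cohort(res$cohort))
  by_group <- split(res$cohort, res$cohort$group)
  expect_equal(sort(by_group$abuser$age), sort(by_group$control$age))
  expect_equal(table(by_group$abuser$sex), table(by_group$control$sex))
})

test_that("exclusion edge cases: identity, double-flagged pair, emptying", {
  panel <- visage_panel()
  required <- tibble::as_tibble(panel)[panel$in_blood_model &
                                         panel$marker %in% c("ELOVL2", "PDE4C"), ]
  cohort <- make_pairs(106)
  meth <- meth_at_sites(cohort$sample_id, required)

  # nothing flagged -> identity
  res <- apply_qc_exclusions(meth, cohort, required_sites = required)
  expect_equal(nrow(res$cohort), 212)
  expect_equal(nrow(res$exclusions), 0)

  # both members of one pair flagged -> exactly that pair removed, no drag
  cohort2 <- make_pairs(106, flagged_ids = c("A0001", "C0001"))
  res2 <- apply_qc_exclusions(meth, cohort2, required_sites = required)
  expect_equal(nrow(res2$cohort), 210)
  expect_equal(dplyr::n_distinct(res2$cohort$pair_id), 105)
  expect_equal(sum(res2$exclusions$reason == "matched_exclusion"), 0)

  # flagging everyone is an error, not an empty result
  cohort3 <- make_pairs(2, flagged_ids = c("A0001", "A0002"))
  expect_error(
    apply_qc_exclusions(meth_at_sites(cohort3$sample_id, required), cohort3,
                        required_sites = required),
    "every sample")
})

test_that("qc_report bundles coverage, quality and exclusions", {
  dat <- simulate_study_data(sim_config(n_pairs = 15, seed = 19))
  rep <- qc_report(dat$counts, dat$cohort, controls = dat$controls)
  expect_s3_class(rep, "qc_report")
  expect_equal(nrow(rep$sample_coverage), 30)
  expect_equal(nrow(rep$cohort), 30)
  expect_equal(nrow(rep$normalized_depth), 8)
  expect_lt(abs(rep$misincorporation$overall_pct - 0.1), 0.05)
  expect_match(rep$meta$normalized_depth_definition, "grand mean")
})
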