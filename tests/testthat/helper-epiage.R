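# shared fixture builders (everything generated in code)

# a perfectly matched cohort with deterministic ages cycling over age_seq
make_pairs <- function(n_pairs, age_seq = 30:60, sexes = NULL,
                       flagged_ids = character()) {
  ages <- rep_len(age_seq, n_pairs)
  if (is.null(sexes)) sexes <- rep_len(c("male", "male", "male", "female",
                                         "male"), n_pairs)
  tibble::tibble(
    sample_id = c(sprintf("A%04d", seq_len(n_pairs)),
                  sprintf("C%04d", seq_len(n_pairs))),
    age = rep(ages, 2),
    sex = rep(sexes, 2),
    group = rep(c("abuser", "control"), each = n_pairs),
    pair_id = rep(sprintf("P%04d", seq_len(n_pairs)), 2),
    flagged = c(sprintf("A%04d", seq_len(n_pairs)),
                sprintf("C%04d", seq_len(n_pairs))) %in% flagged_ids
  )
}

# simulation config with biological and technical noise switched off
zero_noise_config <- function(n_pairs = 5, seed = NULL, deltas = NULL, ...) {
  params <- default_site_params()
  params$sigma <- 0
  sim_config(
    n_pairs = n_pairs,
    site_params = params,
    group_deltas = if (is.null(deltas)) default_group_deltas() else deltas,
    non_conversion_rate = 0,
    misincorporation_rate = 0,
    seed = seed,
    ...
  )
}

# treat latent methylation as if it had been called (no read noise)
truth_as_meth <- function(truth) {
  tibble::tibble(
    sample_id = truth$sample_id,
    marker = truth$marker,
    cpg_label = truth$cpg_label,
    depth = 1e6,
    meth_pct = truth$true_meth_pct,
    qc_reason = NA_character_
  )
}

# methylation table covering given samples at the required model sites
meth_at_sites <- function(sample_ids, sites, value = 50) {
  tidyr::crossing(tibble::tibble(sample_id = sample_ids),
                  sites[c("marker", "cpg_label")]) |>
    dplyr::mutate(depth = 5000, meth_pct = value, qc_reason = NA_character_)
}
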