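#' The default eight-marker age panel
#'
#' Builds the 44-CpG panel over the eight age-informative markers
#' (*ELOVL2*, *MIR29B2CHG*, *KLF14*, *FHL2*, *TRIM59*, *PDE4C*, *EDARADD*,
#' *ASPA*) used throughout the package. Eight sites carry their published
#' GRCh37 coordinates (the six blood-model CpGs plus the two *EDARADD*
#' CpGs); the remaining 36 sites are placeholders that preserve the panel's
#' shape — they sit at marker-local offsets and are flagged
#' `synthetic = TRUE` so they are never mistaken for real coordinates.
#'
#' @param n_control_positions Number of non-CpG cytosine conversion-control
#'   positions assumed per amplicon (used by the simulator and conversion
#'   efficiency bookkeeping).
#'
#' @return A `cpg_panel` tibble with one row per CpG site and columns
#'   `marker`, `cpg_label`, `chrom`, `pos`, `in_blood_model`,
#'   `age_direction` (`"increases"` or `"decreases"`), `synthetic`.
#' @examples
#' panel <- visage_panel()
#' nrow(panel)                      # 44
#' sum(panel$in_blood_model)        # 6
#' @export
visage_panel <- function(n_control_positions = 20L) {
  anchors <- tibble(
    marker    = c("ELOVL2", "MIR29B2CHG", "KLF14", "FHL2", "TRIM59",
                  "PDE4C", "EDARADD", "ASPA"),
    chrom     = c("chr6", "chr1", "chr7", "chr2", "chr3",
                  "chr19", "chr1", "chr17"),
    direction = c("increases", "decreases", "increases", "increases",
                  "increases", "increases", "decreases", "decreases"),
    n_sites   = c(9L, 4L, 4L, 10L, 8L, 5L, 2L, 2L)
  )

  # published sites: blood-model six plus the two EDARADD CpGs
  printed <- tibble(
    marker    = c("ELOVL2", "MIR29B2CHG", "KLF14", "FHL2", "TRIM59",
                  "PDE4C", "EDARADD", "EDARADD"),
    cpg_label = c("C7", "C1", "C4", "C1", "C8", "C5", "C1", "C2"),
    pos       = c(11044634, 207823681, 130734375, 105399282, 160450202,
                  18233105, 236394383, 236394371),
    in_blood_model = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )

  sites <- purrr::pmap_dfr(anchors, function(marker, chrom, direction, n_sites) {
    lab <- paste0("C", seq_len(n_sites))
    known <- printed[printed$marker == marker, ]
    # anchor on the first printed site when one exists; CpGs spaced a few bp
    # apart within the amplicon, labelled in coordinate order
    anchor_pos <- if (nrow(known)) known$pos[1] else 3476225
    anchor_idx <- if (nrow(known)) as.integer(sub("C", "", known$cpg_label[1])) else 1L
    pos <- anchor_pos + (seq_len(n_sites) - anchor_idx) * 8L
    synthetic <- rep(TRUE, n_sites)
    in_model <- rep(FALSE, n_sites)
    for (i in seq_len(nrow(known))) {
      j <- match(known$cpg_label[i], lab)
      pos[j] <- known$pos[i]
      synthetic[j] <- FALSE
      in_model[j] <- known$in_blood_model[i]
    }
    tibble(marker = marker, cpg_label = lab, chrom = chrom, pos = pos,
           in_blood_model = in_model, age_direction = direction,
           synthetic = synthetic)
  })

  new_cpg_panel(sites, n_control_positions = n_control_positions)
}

new_cpg_panel <- function(x, n_control_positions = 20L) {
  x <- as_tibble(x)
  attr(x, "n_control_positions") <- as.integer(n_control_positions)
  class(x) <- c("cpg_panel", class(x))
  validate_panel(x)
}

#' Validate a marker panel
#'
#' Checks the structural invariants of a panel: positive coordinates and
#' uniqueness of both `(marker, cpg_label)` and `(chrom, pos)`.
#'
#' @param panel A panel tibble (see [visage_panel()]).
#' @return The panel, invisibly unchanged, or an error naming the offending
#'   rows.
#' @export
validate_panel <- function(panel) {
  required <- c("marker", "cpg_label", "chrom", "pos", "in_blood_model",
                "age_direction")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols)) {
    abort(paste0("panel is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(panel$pos <= 0)) {
    abort("panel contains non-positive coordinates")
  }
  if (!all(panel$age_direction %in% c("increases", "decreases"))) {
    abort("age_direction must be 'increases' or 'decreases'")
  }
  key <- paste(panel$marker, panel$cpg_label)
  if (anyDuplicated(key)) {
    abort(paste0("duplicated (marker, cpg_label): ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  loc <- paste0(panel$chrom, ":", panel$pos)
  if (anyDuplicated(loc)) {
    abort(paste0("duplicated (chrom, pos): ",
                 paste(unique(loc[duplicated(loc)]), collapse = "; ")))
  }
  invisible(panel)
}

#' Read a marker manifest
#'
#' @param path TSV with columns `marker`, `cpg_label`, `chrom`, `pos`,
#'   `in_blood_model`, `age_direction` and optionally `synthetic`.
#' @param require_blood_model If `TRUE`, error unless the manifest flags at
#'   least one blood-model site.
#' @return A validated `cpg_panel` tibble.
#' @export
load_marker_panel <- function(path, require_blood_model = FALSE) {
  if (!file.exists(path)) abort(paste0("no such manifest: ", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  x$pos <- as.numeric(x$pos)
  x$in_blood_model <- as.logical(x$in_blood_model)
  if (!"synthetic" %in% names(x)) x$synthetic <- NA
  panel <- new_cpg_panel(x)
  if (require_blood_model && !any(panel$in_blood_model)) {
    abort("manifest flags no blood-model sites but blood-model use was requested")
  }
  panel
}

#' Write a marker manifest
#'
#' @param panel A panel tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_marker_panel <- function(panel, path) {
  readr::write_tsv(as_tibble(panel), path, progress = FALSE)
  invisible(path)
}

#' Resolve a named site subset against a panel
#'
#' `"blood6"` selects the six blood-model CpGs, `"mir29_c1"` the single
#' *MIR29B2CHG* C1 site; a two-column data frame (`marker`, `cpg_label`)
#' selects custom sites.
#'
#' @param panel A panel tibble.
#' @param subset `"blood6"`, `"mir29_c1"`, or a data frame.
#' @return The selected panel rows.
#' @export
resolve_sites <- function(panel, subset = "blood6") {
  if (is.character(subset) && length(subset) == 1) {
    out <- switch(subset,
      blood6   = panel[panel$in_blood_model, ],
      mir29_c1 = panel[panel$marker == "MIR29B2CHG" & panel$cpg_label == "C1", ],
      abort(paste0("unknown site subset: ", subset))
    )
  } else {
    subset <- as_tibble(subset)
    out <- semi_join(as_tibble(panel), subset, by = c("marker", "cpg_label"))
    if (nrow(out) != nrow(distinct(subset, .data$marker, .data$cpg_label))) {
      abort("some requested sites are absent from the panel")
    }
  }
  if (!nrow(out)) abort("site subset resolved to zero sites")
  out
}

#' @export
print.cpg_panel <- function(x, ...) {
  cat("<cpg_panel> ", nrow(x), " CpG sites, ",
      n_distinct(x$marker), " markers, ",
      sum(x$in_blood_model), " blood-model sites\n", sep = "")
  NextMethod()
}

site_key <- function(marker, cpg_label) paste0(marker, ":", cpg_label)
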