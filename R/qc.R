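#' Sequence quality thresholds
#'
#' Two quality grades are applied to recovered barcodes. The stricter
#' "reference" (BIN) grade requires length strictly greater than
#' `bin_min_length` (default 500 bp); the "analysis" (MOTU) grade requires
#' length of at least `motu_min_length` (default 300 bp). Both require an
#' ambiguous-residue fraction strictly below `max_ambiguous_fraction`
#' (default 1%). The asymmetric boundary semantics (strict ">", inclusive
#' ">=", strict "<") are deliberate and fixed.
#'
#' @param bin_min_length integer bp, exclusive lower bound for the
#'   reference grade.
#' @param motu_min_length integer bp, inclusive lower bound for the
#'   analysis grade.
#' @param max_ambiguous_fraction proportion in (0, 1), exclusive upper
#'   bound on `n_ambiguous / length`.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(bin_min_length = 500L, motu_min_length = 300L,
                          max_ambiguous_fraction = 0.01) {
  stopifnot(motu_min_length <= bin_min_length,
            max_ambiguous_fraction > 0, max_ambiguous_fraction < 1)
  structure(list(bin_min_length = as.integer(bin_min_length),
                 motu_min_length = as.integer(motu_min_length),
                 max_ambiguous_fraction = max_ambiguous_fraction),
            class = "qc_thresholds")
}

.ambig_ok <- function(seqs, t) {
  # zero-length sequences have no defined ambiguity fraction; they fail
  # the length bound anyway, so report FALSE without erroring
  frac <- ifelse(seqs$length > 0, seqs$n_ambiguous / seqs$length, 1)
  frac < t$max_ambiguous_fraction
}

#' Reference-grade (BIN) quality filter
#'
#' TRUE iff length > `bin_min_length` and ambiguous fraction <
#' `max_ambiguous_fraction`.
#'
#' @param seqs a [barcode_set()].
#' @param thresholds a [qc_thresholds()].
#' @return logical vector, one element per sequence.
#' @export
passes_bin_grade <- function(seqs, thresholds = qc_thresholds()) {
  stopifnot(inherits(seqs, "barcode_set"))
  seqs$length > thresholds$bin_min_length & .ambig_ok(seqs, thresholds)
}

#' Analysis-grade (MOTU) quality filter
#'
#' TRUE iff length >= `motu_min_length` and ambiguous fraction <
#' `max_ambiguous_fraction`.
#'
#' @inheritParams passes_bin_grade
#' @return logical vector, one element per sequence.
#' @export
passes_motu_grade <- function(seqs, thresholds = qc_thresholds()) {
  stopifnot(inherits(seqs, "barcode_set"))
  seqs$length >= thresholds$motu_min_length & .ambig_ok(seqs, thresholds)
}

#' Summarize sequencing success
#'
#' Overall and per-group recovery rates: the fraction of specimens selected
#' for sequencing from which a barcode was recovered.
#'
#' @param metadata specimen metadata (one row per attempted specimen).
#' @param recovered_ids character vector of specimen ids with a recovered
#'   sequence; must be a subset of `metadata$specimen_id`.
#' @param group_by name of the metadata column to group by (default
#'   `"order"`).
#' @return an object of class `success_summary` with fields `attempted`,
#'   `recovered`, `rate` and a `per_group` data frame.
#' @export
summarize_success <- function(metadata, recovered_ids, group_by = "order") {
  stopifnot(group_by %in% names(metadata))
  extra <- setdiff(recovered_ids, metadata$specimen_id)
  if (length(extra))
    stop("recovered ids absent from metadata: ",
         paste(utils::head(extra, 5), collapse = ", "))
  rec <- metadata$specimen_id %in% recovered_ids
  grp <- metadata[[group_by]]
  att_g <- tapply(rec, grp, length)
  rec_g <- tapply(rec, grp, sum)
  per_group <- data.frame(group = names(att_g),
                          attempted = as.integer(att_g),
                          recovered = as.integer(rec_g),
                          rate = ifelse(att_g > 0, rec_g / att_g, NA_real_),
                          stringsAsFactors = FALSE)
  rownames(per_group) <- NULL
  structure(list(attempted = nrow(metadata),
                 recovered = sum(rec),
                 rate = if (nrow(metadata) > 0) sum(rec) / nrow(metadata) else NA_real_,
                 group_by = group_by,
                 per_group = per_group),
            class = "success_summary")
}

#' @export
print.success_summary <- function(x, ...) {
  cat(sprintf("Sequencing success: %d / %d specimens (%.1f%%)\n",
              x$recovered, x$attempted, 100 * x$rate))
  pg <- x$per_group
  pg$rate <- sprintf("%.1f%%", 100 * pg$rate)
  print(pg, row.names = FALSE)
  invisible(x)
}

#' Chi-square test of homogeneous recovery success across groups
#'
#' Pearson chi-square on the groups x {recovered, failed} contingency
#' table, with `groups - 1` degrees of freedom and no continuity
#' correction. When any expected cell is below 1 the test is still
#' computed, but the result carries a `low_expected` flag.
#'
#' @param per_group data frame with columns `group`, `attempted`,
#'   `recovered` (as produced by [summarize_success()]), or a 2-column
#'   matrix of (recovered, failed) counts with group rownames.
#' @return an object of class `htest` with additional element
#'   `low_expected`.
#' @export
success_homogeneity_test <- function(per_group) {
  if (is.data.frame(per_group)) {
    stopifnot(all(c("attempted", "recovered") %in% names(per_group)))
    m <- cbind(recovered = per_group$recovered,
               failed = per_group$attempted - per_group$recovered)
    rownames(m) <- per_group$group
  } else {
    m <- as.matrix(per_group)
  }
  if (nrow(m) < 2) stop("need at least 2 groups")
  if (any(rowSums(m) <= 0)) stop("all groups must have attempted > 0")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  ht$low_expected <- any(ht$expected < 1)
  if (ht$low_expected)
    warning("expected cell count < 1; chi-square approximation is unreliable")
  ht$data.name <- "recovery success by group"
  ht
}
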