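#' Alignment parameters for pairwise barcode comparison
#'
#' Barcode pairs are aligned globally with free terminal gaps (an "overlap"
#' alignment), so a sequence and its exact substring have distance 0.
#' Scores follow the usual DNA convention: `match` reward, `mismatch`
#' penalty, and affine gap costs (`gap_open` is charged when a gap is
#' opened, `gap_extend` per gap position, both as positive costs).
#'
#' @param match match score (default 1).
#' @param mismatch mismatch penalty, positive (default 1).
#' @param gap_open gap opening cost, positive (default 3).
#' @param gap_extend gap extension cost per position, positive (default 1).
#' @param count_gaps logical; count internal gap columns as differences
#'   (default TRUE — COI barcodes are length-conserved, so indels signal
#'   real divergence).
#' @return an object of class `alignment_params`.
#' @export
alignment_params <- function(match = 1, mismatch = 1, gap_open = 3,
                             gap_extend = 1, count_gaps = TRUE) {
  stopifnot(match > 0, mismatch >= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, count_gaps = isTRUE(count_gaps)),
            class = "alignment_params")
}

.as_residues <- function(x) {
  if (inherits(x, "barcode_set")) {
    stopifnot(nrow(x) == 1L)
    return(x$residues)
  }
  stopifnot(is.character(x), length(x) == 1L)
  toupper(gsub("-", "", x, fixed = TRUE))
}

# Count differences between two aligned strings of equal length.
# Columns where either residue is ambiguous (outside A/C/G/T and not a
# gap) are excluded from both the difference count and the compared-site
# count; internal gap columns count as one difference each (when
# count_gaps) but always as compared sites.
.count_aligned <- function(a_chars, b_chars, count_gaps) {
  plain <- c("A", "C", "G", "T")
  amb <- (!(a_chars %in% plain) & a_chars != "-") |
         (!(b_chars %in% plain) & b_chars != "-")
  keep_a <- a_chars[!amb]
  keep_b <- b_chars[!amb]
  is_gap <- keep_a == "-" | keep_b == "-"
  diffs <- sum(keep_a[!is_gap] != keep_b[!is_gap]) +
    if (count_gaps) sum(is_gap) else 0L
  list(n_differences = as.integer(diffs),
       compared_sites = length(keep_a))
}

#' Pairwise nucleotide differences between two barcodes
#'
#' Aligns the two sequences with free terminal gaps and counts absolute
#' nucleotide differences: substitutions plus internal gap columns, over
#' the aligned overlap. Ambiguous columns are excluded from both the
#' difference count and the number of compared sites. If the alignment
#' yields no comparable overlap the distance is undefined
#' (`n_differences = NA`), which downstream clustering treats as
#' above-threshold.
#'
#' @param a,b nucleotide strings (or single-row [barcode_set()]s).
#' @param params an [alignment_params()].
#' @return list with `n_differences`, `compared_sites`, and `defined`.
#' @export
pairwise_differences <- function(a, b, params = alignment_params()) {
  a <- .as_residues(a); b <- .as_residues(b)
  if (nchar(a) == 0 || nchar(b) == 0)
    return(list(n_differences = NA_integer_, compared_sites = 0L,
                defined = FALSE))
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = -params$mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "overlap", substitutionMatrix = submat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  al_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  al_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  cnt <- .count_aligned(al_a, al_b, params$count_gaps)
  if (cnt$compared_sites == 0L)
    return(list(n_differences = NA_integer_, compared_sites = 0L,
                defined = FALSE))
  c(cnt, list(defined = TRUE))
}

# Positionwise (Hamming) difference matrix for equal-length, co-aligned
# sequences, via one-hot cross-products: for each base b,
# matches += X_b X_b'; compared = U U' with U the unambiguous indicator.
.hamming_matrices <- function(seqs) {
  n <- nrow(seqs)
  M <- matrix(unlist(strsplit(seqs$residues, ""), use.names = FALSE),
              nrow = n, byrow = TRUE)
  matches <- matrix(0, n, n)
  U <- matrix(FALSE, n, ncol(M))
  for (b in c("A", "C", "G", "T")) {
    Xb <- M == b
    U <- U | Xb
    matches <- matches + tcrossprod(Xb)
  }
  compared <- tcrossprod(U)
  diffs <- compared - matches
  dimnames(diffs) <- dimnames(compared) <-
    list(seqs$specimen_id, seqs$specimen_id)
  list(differences = diffs, compared_sites = compared)
}

# Align many patterns against one subject in a single vectorized call
# and count differences/compared sites per pair.
.align_counts <- function(patterns, subject, params) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = -params$mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    patterns, subject, type = "overlap", substitutionMatrix = submat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  diffs <- integer(length(patterns)); comp <- integer(length(patterns))
  for (k in seq_along(patterns)) {
    cnt <- .count_aligned(strsplit(al_a[k], "")[[1]],
                          strsplit(al_b[k], "")[[1]], params$count_gaps)
    diffs[k] <- cnt$n_differences
    comp[k] <- cnt$compared_sites
  }
  list(n_differences = diffs, compared_sites = comp)
}

#' Pairwise distance matrix over a barcode set
#'
#' Computes the full matrix of absolute nucleotide differences. When all
#' sequences have equal length they are assumed co-aligned and a fast
#' positionwise comparison is used (`method = "hamming"`); with mixed
#' lengths the default hybrid strategy applies the positionwise path to
#' the (typically dominant) modal-length block and free-end-gap alignment
#' to every pair involving an off-length sequence; `method = "align"`
#' aligns every pair. On equal-length inputs all paths agree. Pairs with
#' no comparable overlap get `NA`.
#'
#' @param seqs a [barcode_set()].
#' @param params an [alignment_params()].
#' @param method `"auto"` (default), `"hamming"`, or `"align"`.
#' @return object of class `barcode_dist`: list with matrices
#'   `differences` and `compared_sites`, plus `labels` and `method`.
#' @export
distance_matrix <- function(seqs, params = alignment_params(),
                            method = c("auto", "hamming", "align")) {
  stopifnot(inherits(seqs, "barcode_set"))
  method <- match.arg(method)
  n <- nrow(seqs)
  if (n == 0) {
    m <- matrix(integer(), 0, 0)
    return(structure(list(differences = m, compared_sites = m,
                          labels = character(), method = method),
                     class = "barcode_dist"))
  }
  equal_len <- length(unique(seqs$length)) == 1L && seqs$length[1] > 0
  if (method == "hamming" && !equal_len)
    stop("hamming method requires equal-length sequences")
  if (method == "auto" && equal_len) method <- "hamming"

  dn <- list(seqs$specimen_id, seqs$specimen_id)
  if (method == "hamming") {
    hm <- .hamming_matrices(seqs)
    diffs <- hm$differences; comp <- hm$compared_sites
  } else {
    diffs <- matrix(NA_real_, n, n, dimnames = dn)
    comp <- matrix(0, n, n, dimnames = dn)
    diag(diffs) <- 0
    diag(comp) <- seqs$length - seqs$n_ambiguous
    if (method == "auto") {
      # hybrid: positionwise block for the modal length, alignment for
      # pairs touching an off-length sequence
      len_tab <- table(seqs$length)
      l_mode <- as.integer(names(len_tab)[which.max(len_tab)])
      in_block <- seqs$length == l_mode
      if (sum(in_block) > 1) {
        blk <- seqs[in_block, ]
        class(blk) <- c("barcode_set", "data.frame")
        hm <- .hamming_matrices(blk)
        diffs[in_block, in_block] <- hm$differences
        comp[in_block, in_block] <- hm$compared_sites
      }
      odd <- which(!in_block)
      for (i in odd) {
        others <- setdiff(seq_len(n), i)
        others <- others[others > i | in_block[others]]
        if (!length(others)) next
        ac <- .align_counts(seqs$residues[others], seqs$residues[i], params)
        diffs[others, i] <- diffs[i, others] <- ac$n_differences
        comp[others, i] <- comp[i, others] <- ac$compared_sites
      }
    } else {
      for (i in seq_len(n - 1)) {
        others <- (i + 1):n
        ac <- .align_counts(seqs$residues[others], seqs$residues[i], params)
        diffs[others, i] <- diffs[i, others] <- ac$n_differences
        comp[others, i] <- comp[i, others] <- ac$compared_sites
      }
    }
  }
  diffs[comp == 0 & row(comp) != col(comp)] <- NA_real_
  structure(list(differences = diffs, compared_sites = comp,
                 labels = seqs$specimen_id, method = method),
            class = "barcode_dist")
}

#' Delineate MOTUs at an absolute nucleotide-change threshold
#'
#' MOTUs are the connected components of the graph joining every pair of
#' sequences with `n_differences <= threshold` (single linkage at the
#' cutoff). Pairs with undefined distance (no comparable overlap) are
#' treated as above-threshold. Labels are assigned contiguously in order
#' of each MOTU's first-seen specimen, so the labelling is deterministic
#' given input order; the member *sets* are independent of input order.
#'
#' @param x a [barcode_set()] or a precomputed [distance_matrix()] result.
#' @param threshold integer; maximum nucleotide changes joining a pair
#'   (default 15, i.e. 2.3% of a full 648-bp barcode).
#' @param params an [alignment_params()], used when `x` is a barcode set.
#' @param method distance method passed to [distance_matrix()].
#' @return an object of class `motu_partition`: list with `threshold`,
#'   `assignment` (named character vector specimen -> MOTU label),
#'   `motu_labels`, and `sizes`.
#' @export
delineate_motus <- function(x, threshold = 15L, params = alignment_params(),
                            method = "auto") {
  stopifnot(threshold >= 0)
  bd <- if (inherits(x, "barcode_dist")) x else distance_matrix(x, params, method)
  n <- length(bd$labels)
  if (n == 0) {
    return(structure(list(threshold = as.integer(threshold),
                          assignment = structure(character(), names = character()),
                          motu_labels = character(), sizes = integer()),
                     class = "motu_partition"))
  }
  if (n == 1) {
    comp <- 1L
  } else {
    D <- bd$differences
    D[is.na(D)] <- threshold + 1
    hc <- stats::hclust(stats::as.dist(D), method = "single")
    comp <- stats::cutree(hc, h = threshold)
  }
  # relabel components contiguously by first-seen specimen order
  first_seen <- unique(comp)
  relabel <- match(comp, first_seen)
  width <- max(4L, nchar(length(first_seen)))
  labels <- sprintf(paste0("M%0", width, "d"), relabel)
  assignment <- structure(labels, names = bd$labels)
  motu_labels <- sprintf(paste0("M%0", width, "d"), seq_along(first_seen))
  sizes <- table(factor(labels, levels = motu_labels))
  structure(list(threshold = as.integer(threshold), assignment = assignment,
                 motu_labels = motu_labels,
                 sizes = structure(as.integer(sizes), names = motu_labels)),
            class = "motu_partition")
}

#' @export
print.motu_partition <- function(x, ...) {
  cat("MOTU partition at threshold", x$threshold, "nucleotide changes\n")
  cat(" ", length(x$assignment), "specimens in", length(x$motu_labels),
      "MOTUs\n")
  if (length(x$assignment))
    cat(sprintf("  mean specimens/MOTU: %.1f\n",
                length(x$assignment) / length(x$motu_labels)))
  invisible(x)
}

#' Per-MOTU summary table
#'
#' Annotates each MOTU with its abundance and majority order/family; MOTUs
#' whose specimens span more than one family are flagged as taxonomically
#' mixed. The attached attributes give the per-order MOTU counts (by
#' majority order) and the mean specimens per MOTU.
#'
#' @param partition a [delineate_motus()] result.
#' @param metadata specimen metadata covering every assigned specimen.
#' @return data frame with columns `motu`, `n_specimens`, `order`,
#'   `family`, `mixed`; attributes `mean_specimens_per_motu` and
#'   `motus_per_order`.
#' @export
motu_summary <- function(partition, metadata) {
  stopifnot(inherits(partition, "motu_partition"))
  ids <- names(partition$assignment)
  missing_md <- setdiff(ids, metadata$specimen_id)
  if (length(missing_md))
    stop("specimen(s) without metadata: ",
         paste(utils::head(missing_md, 5), collapse = ", "))
  md <- metadata[match(ids, metadata$specimen_id), ]
  motu <- factor(partition$assignment, levels = partition$motu_labels)
  majority <- function(v) names(sort(table(v), decreasing = TRUE))[1]
  out <- data.frame(
    motu = partition$motu_labels,
    n_specimens = as.integer(table(motu)),
    order = as.character(tapply(md$order, motu, majority)),
    family = as.character(tapply(md$family, motu, majority)),
    mixed = as.logical(tapply(md$family, motu,
                              function(v) length(unique(v)) > 1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "mean_specimens_per_motu") <-
    round_half_up(length(ids) / nrow(out), 1)
  attr(out, "motus_per_order") <- table(out$order)
  out
}
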