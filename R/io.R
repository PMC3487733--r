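#' Construct a barcode sequence set
#'
#' Normalizes raw nucleotide strings into the canonical representation used
#' throughout the package: residues uppercased, alignment gaps (`-`)
#' stripped, `U` mapped to `T`, and the number of ambiguous residues
#' (anything outside `A`, `C`, `G`, `T` — `N` and all partial IUPAC codes
#' count alike) recorded per sequence.
#'
#' @param residues named character vector of nucleotide strings; names are
#'   specimen ids and must be non-empty and unique.
#' @return a `barcode_set`: data frame with columns `specimen_id`,
#'   `residues`, `length`, `n_ambiguous`.
#' @export
barcode_set <- function(residues) {
  ids <- names(residues)
  if (length(residues) == 0) {
    out <- data.frame(specimen_id = character(), residues = character(),
                      length = integer(), n_ambiguous = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("barcode_set", "data.frame")
    return(out)
  }
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop("every sequence must carry a non-empty specimen id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate specimen id(s): ", paste(dup, collapse = ", "))
  res <- toupper(as.character(residues))
  res <- gsub("-", "", res, fixed = TRUE)
  res <- gsub("U", "T", res, fixed = TRUE)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", res)
  if (any(bad))
    stop("non-IUPAC residues in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  len <- nchar(res)
  n_amb <- len - vapply(gregexpr("[ACGT]", res),
                        function(m) if (m[1] == -1L) 0L else length(m),
                        integer(1))
  out <- data.frame(specimen_id = ids, residues = res, length = len,
                    n_ambiguous = n_amb, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("barcode_set", "data.frame")
  out
}

#' @export
print.barcode_set <- function(x, ...) {
  cat("Barcode sequence set:", nrow(x), "sequences\n")
  if (nrow(x)) {
    cat("  length range:", min(x$length), "-", max(x$length), "bp\n")
    cat("  with ambiguous residues:", sum(x$n_ambiguous > 0), "\n")
  }
  invisible(x)
}

#' Read COI barcode sequences from a FASTA file
#'
#' The first whitespace-delimited token of each header is taken as the
#' specimen id. Residues are normalized as in [barcode_set()].
#'
#' @param path path to a FASTA file.
#' @return a [barcode_set()].
#' @export
read_barcode_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) return(barcode_set(character()))
  ids <- sub("\\s.*$", "", names(ss))
  empty <- Biostrings::width(ss) == 0
  if (any(empty))
    stop("record(s) with empty sequence: ", paste(ids[empty], collapse = ", "))
  res <- as.character(ss)
  names(res) <- ids
  barcode_set(res)
}

#' Write a barcode set to FASTA
#'
#' @param x a [barcode_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(x, path) {
  stopifnot(inherits(x, "barcode_set"))
  ss <- Biostrings::DNAStringSet(structure(x$residues, names = x$specimen_id))
  Biostrings::writeXStringSet(ss, path, width = 70)
  invisible(path)
}

.metadata_required <- c("specimen_id", "order", "family", "genus", "site_id",
                        "site_type", "substrate", "method", "year")
.site_type_levels <- c("forested", "non-forested")

#' Read a specimen metadata table
#'
#' Accepts a tab- or comma-delimited table (delimiter auto-detected from the
#' header line, tab preferred) with at least the columns `specimen_id`,
#' `order`, `family`, `genus`, `site_id`, `site_type`, `substrate`,
#' `method`, `year`. Extra columns are preserved untouched.
#'
#' @param path path to the delimited table.
#' @return data frame of specimen records.
#' @export
read_specimen_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  cols <- strsplit(header, sep, fixed = TRUE)[[1]]
  # pin required columns to their types so all-empty character columns
  # (e.g. genus) survive as "" rather than collapsing to logical NA
  cc <- structure(rep(NA_character_, length(cols)), names = cols)
  cc[intersect(cols, setdiff(.metadata_required, "year"))] <- "character"
  md <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, comment.char = "",
                          check.names = FALSE, colClasses = cc)
  for (col in intersect(names(md), setdiff(.metadata_required, "year")))
    md[[col]][is.na(md[[col]])] <- ""
  validate_specimen_metadata(md)
}

#' Validate a specimen metadata data frame
#'
#' @param md data frame of specimen records.
#' @return `md`, with `year` coerced to integer.
#' @export
validate_specimen_metadata <- function(md) {
  missing_cols <- setdiff(.metadata_required, names(md))
  if (length(missing_cols))
    stop("metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  dup <- unique(md$specimen_id[duplicated(md$specimen_id)])
  if (length(dup))
    stop("duplicate specimen id(s) in metadata: ", paste(dup, collapse = ", "))
  bad <- which(!(md$site_type %in% .site_type_levels))
  if (length(bad))
    stop("site_type outside {", paste(.site_type_levels, collapse = ", "),
         "} at row(s): ", paste(bad, collapse = ", "))
  md$year <- as.integer(md$year)
  md
}

#' Write a specimen metadata table (tab-delimited)
#'
#' @param md data frame of specimen records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_specimen_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a dendrogram as Newick
#'
#' Merge trees from complete-linkage clustering are written ultrametrically:
#' a leaf under a merge at height *h* sits at depth *h*/2, so two leaves
#' merged at 0.5 give `(A:0.25,B:0.25);`. A single-label input is written
#' using the degenerate dialect `A:0;`.
#'
#' @param x an [stats::hclust] merge tree, or a single character label.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  if (is.character(x) && length(x) == 1L) {
    writeLines(paste0(x, ":0;"), path)
    return(invisible(path))
  }
  stopifnot(inherits(x, "hclust"))
  if (anyDuplicated(x$labels))
    stop("duplicate leaf labels in dendrogram")
  if (any(x$height < 0) || is.unsorted(x$height))
    stop("merge heights must be non-negative and non-decreasing")
  phy <- ape::as.phylo(x)
  ape::write.tree(phy, file = path)
  invisible(path)
}
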