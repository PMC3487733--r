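#' Build an analytical-unit x MOTU community matrix
#'
#' Counts specimens per MOTU in each aggregate unit (site or substrate).
#' When aggregating by site, the forested / non-forested site type is
#' attached as the unit grouping for downstream ANOSIM. Units that end up
#' with no specimens are dropped with a warning.
#'
#' @param metadata specimen metadata.
#' @param partition a [delineate_motus()] result; only assigned specimens
#'   are counted.
#' @param aggregate_by `"site"` or `"substrate"`.
#' @param year optional; keep only records from these years (the
#'   systematic-survey filter).
#' @param method optional; keep only records with these collection
#'   methods.
#' @return integer matrix (units x MOTUs) of class `community_matrix`
#'   with attributes `grouping` (named character, site aggregation only)
#'   and `aggregate_by`.
#' @export
community_matrix <- function(metadata, partition,
                             aggregate_by = c("site", "substrate"),
                             year = NULL, method = NULL) {
  aggregate_by <- match.arg(aggregate_by)
  md <- metadata
  if (!is.null(year)) md <- md[md$year %in% year, , drop = FALSE]
  if (!is.null(method)) md <- md[md$method %in% method, , drop = FALSE]
  md <- md[md$specimen_id %in% names(partition$assignment), , drop = FALSE]
  if (nrow(md) == 0) stop("no specimens left after filtering")
  unit <- if (aggregate_by == "site") md$site_id else md$substrate
  motu <- partition$assignment[md$specimen_id]
  m <- table(unit, motu)
  m <- matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
  names(dimnames(m)) <- NULL
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warning("dropping empty unit(s): ",
            paste(rownames(m)[empty], collapse = ", "))
    m <- m[!empty, , drop = FALSE]
  }
  grouping <- NULL
  if (aggregate_by == "site") {
    st <- md$site_type[match(rownames(m), md$site_id)]
    grouping <- structure(st, names = rownames(m))
  }
  structure(m, class = c("community_matrix", class(m)),
            grouping = grouping, aggregate_by = aggregate_by)
}

#' Hellinger transformation
#'
#' Square root of relative abundance: y'(i, j) = sqrt(y(i, j) / rowsum_i).
#' Every transformed row has unit sum of squares.
#'
#' @param m non-negative matrix with positive row sums.
#' @return transformed numeric matrix.
#' @export
hellinger_transform <- function(m) {
  m <- unclass(as.matrix(m))
  if (any(m < 0)) stop("abundances must be non-negative")
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("zero-sum row(s): ", paste(rownames(m)[rs == 0], collapse = ", "),
         " (drop empty units first)")
  sqrt(sweep(m, 1, rs, "/"))
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' d = sum |u - v| / sum (u + v); 0 for identical vectors, 1 for
#' disjoint supports.
#'
#' @param u,v non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(u, v) {
  stopifnot(length(u) == length(v), all(u >= 0), all(v >= 0))
  tot <- sum(u) + sum(v)
  if (tot == 0) stop("Bray-Curtis undefined for two all-zero vectors")
  sum(abs(u - v)) / tot
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param m abundance (or Hellinger-transformed) matrix, units in rows.
#' @return a [stats::dist] object of pairwise Bray-Curtis dissimilarities.
#' @export
bray_curtis_matrix <- function(m) {
  m <- unclass(as.matrix(m))
  rs <- rowSums(m)
  if (any(rs == 0))
    stop("zero-sum row(s): ", paste(rownames(m)[rs == 0], collapse = ", "))
  num <- as.matrix(stats::dist(m, method = "manhattan"))
  d <- num / outer(rs, rs, "+")
  stats::as.dist(d)
}

#' Complete-linkage hierarchical clustering of community units
#'
#' Agglomerative merge tree where the distance between clusters is the
#' maximum pairwise dissimilarity of their members.
#'
#' @param d a [stats::dist] (e.g. from [bray_curtis_matrix()]) or a
#'   symmetric dissimilarity matrix with unit labels.
#' @return an [stats::hclust] tree.
#' @export
complete_linkage <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  if (attr(d, "Size") < 2) stop("need at least 2 units to cluster")
  stats::hclust(d, method = "complete")
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. All n(n-1)/2 dissimilarities are
#' ranked with mid-ranks for ties; R = (mean between-group rank - mean
#' within-group rank) / (M / 2), with M = n(n-1)/2. The p-value counts
#' the observed labelling among the permutations:
#' p = (1 + #\{permuted R >= observed R\}) / (1 + n_permutations).
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @param groups group label per unit (>= 2 groups, each of size >= 2).
#' @param n_permutations number of random relabelings (default 999).
#' @param seed optional integer seed.
#' @return object of class `anosim_result`: list with `R`, `p`,
#'   `n_permutations`, `seed`, `perm_R`.
#' @export
anosim_test <- function(d, groups, n_permutations = 999L, seed = NULL) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  n <- attr(d, "Size")
  groups <- as.character(groups)
  stopifnot(length(groups) == n)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups")
  if (any(sizes < 2))
    stop("every group needs >= 2 units (within-group ranks undefined): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  r <- rank(as.vector(d))  # mid-ranks for ties
  M <- length(r)
  pair_i <- rep(seq_len(n - 1), times = (n - 1):1)
  pair_j <- unlist(lapply(seq_len(n - 1), function(i) (i + 1):n))
  stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(r[!within]) - mean(r[within])) / (M / 2)
  }
  R_obs <- stat(groups)
  perm_R <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) stat(sample(groups)),
           numeric(1))
  })
  p <- (1 + sum(perm_R >= R_obs)) / (1 + n_permutations)
  structure(list(R = R_obs, p = p,
                 n_permutations = as.integer(n_permutations),
                 seed = seed, perm_R = perm_R),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.3g (%d permutations)\n",
              x$R, x$p, x$n_permutations))
  invisible(x)
}

#' Mean off-diagonal dissimilarity
#'
#' Arithmetic mean over the n(n-1)/2 unordered unit pairs; the summary
#' statistic used to describe overall community turnover.
#'
#' @param d a [stats::dist] or symmetric dissimilarity matrix.
#' @return mean dissimilarity.
#' @export
mean_dissimilarity <- function(d) {
  if (!inherits(d, "dist")) d <- stats::as.dist(as.matrix(d))
  if (attr(d, "Size") < 2) stop("need at least 2 units")
  mean(as.vector(d))
}
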