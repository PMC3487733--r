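# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and Biostrings) so that agreement is evidence,
# not tautology.

BASES <- c("A", "C", "G", "T")

random_seq <- function(len) paste(sample(BASES, len, replace = TRUE),
                                  collapse = "")

# substitute exactly k positions, each to a different base
mutate_seq <- function(s, k) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), k)
  ch[pos] <- vapply(ch[pos], function(b) sample(setdiff(BASES, b), 1), "")
  paste(ch, collapse = "")
}

# Ends-free affine Needleman-Wunsch, O(nm) dynamic programming with
# traceback; counts mismatches + internal gap columns of one optimal
# alignment. Gap of length g costs open + g * extend (the convention the
# package documents).
oracle_nw_count <- function(a, b, match = 1, mismatch = 1,
                            gap_open = 3, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in a gap in B (A over -)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in a gap in A
  M[1, 1] <- 0
  # free terminal gaps: starting anywhere on either sequence costs 0
  M[, 1] <- 0; M[1, ] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else -mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
    }
  }
  # free terminal gaps: best score anywhere on the last row/column
  ends <- rbind(cbind(n + 1, 1:(m + 1)), cbind(1:n, m + 1))
  vals <- apply(ends, 1, function(e) max(M[e[1], e[2]], X[e[1], e[2]],
                                         Y[e[1], e[2]]))
  best <- which.max(vals)
  i <- ends[best, 1]; j <- ends[best, 2]
  state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
  diffs <- 0L
  while (i > 1 && j > 1) {
    if (state == "M") {
      s <- if (A[i - 1] == B[j - 1]) match else -mismatch
      if (A[i - 1] != B[j - 1]) diffs <- diffs + 1L
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- c("M", "X", "Y")[which.max(prev)]
      if (i == 2 || j == 2) state <- "M"  # boundary rows are in M
      i <- i - 1; j <- j - 1
    } else if (state == "X") {
      diffs <- diffs + 1L
      state <- if (X[i, j] == X[i - 1, j] - gap_extend && i > 2) "X" else "M"
      i <- i - 1
    } else {
      diffs <- diffs + 1L
      state <- if (Y[i, j] == Y[i, j - 1] - gap_extend && j > 2) "Y" else "M"
      j <- j - 1
    }
  }
  list(score = vals[best], n_differences = diffs)
}

# Union-find connected components at a distance cutoff.
oracle_union_find <- function(D, threshold) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.na(D[i, j]) && D[i, j] <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# canonical form of a partition: sorted list of sorted member sets
partition_sets <- function(labels, ids = names(labels)) {
  if (is.null(ids)) ids <- seq_along(labels)
  sets <- split(as.character(ids), as.character(labels))
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, `[`, "", 1))])
}

# Naive O(n^3) complete-linkage agglomeration; returns the cophenetic
# distance matrix.
oracle_complete_linkage_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      dmax <- max(D[clusters[[a]], clusters[[b]]])
      if (dmax < best[1]) best <- c(dmax, a, b)
    }
    a <- best[2]; b <- best[3]
    coph[clusters[[a]], clusters[[b]]] <- best[1]
    coph[clusters[[b]], clusters[[a]]] <- best[1]
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    clusters[[b]] <- NULL
  }
  coph
}

# ANOSIM R statistic straight from the definition (rank-based).
oracle_anosim_R <- function(D, groups) {
  d <- D[lower.tri(D)]
  r <- rank(d)
  n <- nrow(D)
  within <- outer(groups, groups, "==")[lower.tri(D)]
  (mean(r[!within]) - mean(r[within])) / (length(r) / 2)
}

# Exact permutation distribution over all relabelings with the given
# group-size profile (two groups).
oracle_anosim_exact <- function(D, groups) {
  n <- nrow(D)
  g1 <- unique(groups)[1]
  k <- sum(groups == g1)
  combos <- utils::combn(n, k)
  apply(combos, 2, function(idx) {
    g <- rep(unique(groups)[2], n)
    g[idx] <- g1
    oracle_anosim_R(D, g)
  })
}

# random symmetric integer "difference" matrix with zero diagonal
random_distance_matrix <- function(n, max_d = 30) {
  D <- matrix(0L, n, n)
  v <- sample(0:max_d, n * (n - 1) / 2, replace = TRUE)
  D[lower.tri(D)] <- v
  D <- D + t(D)
  dimnames(D) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  D
}

# wrap a plain difference matrix as the package's distance object
as_barcode_dist <- function(D) {
  structure(list(differences = D,
                 compared_sites = matrix(648L, nrow(D), ncol(D),
                                         dimnames = dimnames(D)),
                 labels = rownames(D), method = "hamming"),
            class = "barcode_dist")
}

# hand-build a MOTU partition object
make_partition <- function(assignment, threshold = 15L) {
  labels <- unique(assignment)
  structure(list(threshold = threshold, assignment = assignment,
                 motu_labels = labels,
                 sizes = structure(as.integer(table(factor(assignment,
                                                           levels = labels))),
                                   names = labels)),
            class = "motu_partition")
}

make_metadata <- function(n, order = "Mesostigmata", family = "FamA",
                          site_id = "Site01", site_type = "forested",
                          substrate = "moss", method = "berlese",
                          year = 2010L, prefix = "sp") {
  data.frame(specimen_id = paste0(prefix, seq_len(n)),
             order = order, family = family, genus = "",
             site_id = site_id, site_type = site_type,
             substrate = substrate, method = method, year = year,
             stringsAsFactors = FALSE)
}
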