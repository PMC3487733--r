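test_that("pairwise differences: identity, planted substitutions, substrings", {
  withr::local_seed(10)
  a <- random_seq(648)
  expect_equal(pairwise_differences(a, a),
               list(n_differences = 0L, compared_sites = 648L,
                    defined = TRUE))

  b <- mutate_seq(a, 15)
  pd <- pairwise_differences(a, b)
  expect_equal(pd$n_differences, 15L)
  expect_equal(pd$compared_sites, 648L)
  # the conventional percent gloss of the default threshold
  expect_equal(round_half_up(100 * pd$n_differences / pd$compared_sites, 1),
               2.3)

  sub <- substr(a, 101, 500)  # exact 400-bp substring: overhangs are free
  pd2 <- pairwise_differences(a, sub)
  expect_equal(pd2$n_differences, 0L)
  expect_equal(pd2$compared_sites, 400L)
})

test_that("ambiguous columns are excluded from differences and compared sites", {
  a <- paste(rep("A", 50), collapse = "")
  b <- paste(c(rep("A", 40), rep("N", 10)), collapse = "")
  pd <- pairwise_differences(a, b)
  expect_equal(pd$compared_sites, 40L)
  expect_equal(pd$n_differences, 0L)
})

test_that("alignment distances match an independent DP oracle on random pairs", {
  withr::local_seed(11)
  for (k in 1:25) {
    a <- random_seq(60)
    nmut <- sample(0:8, 1)
    b <- mutate_seq(a, nmut)
    # random terminal truncation on one side
    if (runif(1) < 0.5) b <- substr(b, sample(1:5, 1), 60 - sample(0:5, 1))
    pd <- pairwise_differences(a, b)
    orc <- oracle_nw_count(a, b)
    expect_equal(pd$n_differences, orc$n_differences,
                 info = paste("pair", k))
  }
})

test_that("internal gaps count as one difference per column", {
  withr::local_seed(12)
  a <- random_seq(60)
  b <- paste0(substr(a, 1, 30), substr(a, 33, 60))  # 2-bp internal deletion
  pd <- pairwise_differences(a, b)
  expect_equal(pd$n_differences, 2L)
  pd_nogap <- pairwise_differences(a, b, alignment_params(count_gaps = FALSE))
  expect_equal(pd_nogap$n_differences, 0L)
})

test_that("positionwise and alignment paths agree on co-aligned input", {
  withr::local_seed(13)
  ref <- random_seq(120)
  res <- vapply(1:8, function(i) {
    s <- mutate_seq(ref, sample(0:6, 1))
    ch <- strsplit(s, "")[[1]]
    if (i %% 3 == 0) ch[sample(120, 2)] <- "N"
    paste(ch, collapse = "")
  }, "")
  bs <- barcode_set(structure(res, names = paste0("s", 1:8)))
  dh <- distance_matrix(bs, method = "hamming")
  da <- distance_matrix(bs, method = "align")
  expect_equal(unname(dh$differences), unname(da$differences))
  expect_equal(unname(dh$compared_sites), unname(da$compared_sites))
})

test_that("MOTUs are the connected components at the threshold", {
  D <- matrix(c(0, 10, 20,
                10, 0, 10,
                20, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  p <- delineate_motus(as_barcode_dist(D), threshold = 15)
  expect_equal(length(p$motu_labels), 1L)  # chained through B

  p9 <- delineate_motus(as_barcode_dist(D), threshold = 9)
  expect_equal(length(p9$motu_labels), 3L)  # everything separate

  # boundary: distance exactly equal to the threshold joins
  p10 <- delineate_motus(as_barcode_dist(D), threshold = 10)
  expect_equal(length(p10$motu_labels), 1L)
})

test_that("partition equals the union-find oracle and labels are first-seen
           contiguous", {
  withr::local_seed(14)
  for (trial in 1:20) {
    D <- random_distance_matrix(30)
    thr <- sample(0:30, 1)
    p <- delineate_motus(as_barcode_dist(D), threshold = thr)
    orc <- oracle_union_find(D, thr)
    expect_equal(partition_sets(p$assignment),
                 partition_sets(orc, rownames(D)))
  }
  # labels contiguous by first occurrence
  D <- random_distance_matrix(12)
  p <- delineate_motus(as_barcode_dist(D), threshold = 10)
  first <- p$assignment[!duplicated(p$assignment)]
  expect_equal(unname(first), p$motu_labels)
})

test_that("threshold monotonicity and refinement hold", {
  withr::local_seed(15)
  D <- random_distance_matrix(20, max_d = 50)
  parts <- lapply(0:50, function(t)
    delineate_motus(as_barcode_dist(D), threshold = t))
  n_motus <- vapply(parts, function(p) length(p$motu_labels), integer(1))
  expect_true(all(diff(n_motus) <= 0))
  expect_equal(n_motus[length(n_motus)], 1L)  # >= max distance: one MOTU
  # refinement: same label at t implies same label at t' > t
  for (t in c(5, 20, 35)) {
    a <- parts[[t + 1]]$assignment
    b <- parts[[t + 11]]$assignment
    for (lab in unique(a)) {
      members <- names(a)[a == lab]
      expect_equal(length(unique(b[members])), 1L)
    }
  }
})

test_that("member sets are invariant to input order", {
  withr::local_seed(16)
  seqs <- character(12)
  refs <- vapply(1:4, function(i) random_seq(200), "")
  for (i in 1:12) seqs[i] <- mutate_seq(refs[(i - 1) %% 4 + 1], sample(0:3, 1))
  names(seqs) <- paste0("s", 1:12)
  p1 <- delineate_motus(barcode_set(seqs), threshold = 15)
  perm <- sample(12)
  p2 <- delineate_motus(barcode_set(seqs[perm]), threshold = 15)
  expect_equal(partition_sets(p1$assignment), partition_sets(p2$assignment))
})

test_that("undefined distances are treated as above threshold", {
  D <- matrix(c(0, NA, NA, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- delineate_motus(as_barcode_dist(D), threshold = 100)
  expect_equal(length(p$motu_labels), 2L)
})

test_that("MOTU summary annotates abundance, majority taxon and mixing", {
  md <- rbind(make_metadata(6, family = "FamA", prefix = "a"),
              make_metadata(4, family = "FamB", order = "Trombidiformes",
                            prefix = "b"))
  asn <- structure(c(rep("M1", 3), rep("M2", 3), rep("M3", 2), rep("M4", 1),
                     "M5"),
                   names = md$specimen_id)
  p <- make_partition(asn)
  s <- motu_summary(p, md)
  expect_equal(nrow(s), 5L)
  expect_equal(attr(s, "mean_specimens_per_motu"), 2.0)
  expect_equal(s$family[s$motu == "M1"], "FamA")
  expect_false(any(s$mixed))

  # a MOTU spanning two families is flagged mixed with the majority family
  asn2 <- structure(c(rep("M1", 6), rep("M1", 2), "M2", "M2"),
                    names = md$specimen_id)
  s2 <- motu_summary(make_partition(asn2), md)
  expect_true(s2$mixed[s2$motu == "M1"])
  expect_equal(s2$family[s2$motu == "M1"], "FamA")

  expect_error(motu_summary(p, md[-1, ]), "a1")
})
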