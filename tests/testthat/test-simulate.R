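small_cfg <- function(...) {
  simulation_config(n_species = 30, n_sites = 6, seed = 101, ...)
}

clean_cfg <- function(...) {
  # no dropout, no artifacts: every drawn specimen yields a clean barcode
  small_cfg(per_group_success = c(Mesostigmata = 1, Sarcoptiformes = 1,
                                  Trombidiformes = 1),
            truncation_prob = 0, ambiguity_prob = 0, ...)
}

test_that("non-identifiable configs are rejected up front", {
  expect_error(simulation_config(min_interspecific = 20,
                                 max_intraspecific = 5, threshold = 15),
               "non-identifiable")
  expect_error(simulation_config(max_intraspecific = 10, threshold = 15),
               "non-identifiable")
  expect_error(simulation_config(barcode_length = 20, n_species = 900),
               "infeasible|non-identifiable|exceeds")
})

test_that("species pool respects the minimum interspecific divergence", {
  cfg2 <- simulation_config(n_species = 2, seed = 5)
  pool2 <- generate_species_pool(cfg2)
  bs <- barcode_set(pool2$sequences)
  d <- pairwise_differences(bs$residues[1], bs$residues[2])
  expect_gte(d$n_differences, 30)

  cfg50 <- simulation_config(n_species = 50, seed = 6)
  D <- distance_matrix(barcode_set(generate_species_pool(cfg50)$sequences),
                       method = "hamming")$differences
  expect_true(all(D[upper.tri(D)] >= 30))
})

test_that("pool generation is deterministic and taxonomy covers the shares", {
  cfg <- small_cfg()
  p1 <- generate_species_pool(cfg)
  p2 <- generate_species_pool(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$taxonomy), 30L)
  expect_setequal(unique(p1$taxonomy$order),
                  c("Mesostigmata", "Sarcoptiformes", "Trombidiformes"))
  # shares approximately 15/36/49
  expect_equal(unname(table(p1$taxonomy$order)[c("Mesostigmata",
                                                 "Sarcoptiformes",
                                                 "Trombidiformes")]),
               c(4L, 11L, 15L), ignore_attr = TRUE)
})

test_that("specimen sampling is a deterministic function of config + seed", {
  cfg <- small_cfg()
  pool <- generate_species_pool(cfg)
  s1 <- sample_specimens(pool)
  s2 <- sample_specimens(pool)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$metadata, s2$metadata)
  expect_identical(s1$truth, s2$truth)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_survey(s1, d1)
  write_synthetic_survey(s2, d2)
  for (f in c("sequences.fasta", "metadata.tsv", "truth.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})

test_that("specimens are conserved when dropout and artifacts are off", {
  sv <- sample_specimens(generate_species_pool(clean_cfg()))
  expect_equal(sv$counts$dropped, 0L)
  expect_equal(sv$counts$emitted, sv$counts$drawn)
  expect_equal(nrow(sv$sequences), nrow(sv$metadata))
  expect_true(all(passes_motu_grade(sv$sequences)))
})

test_that("turnover = 1 confines every species to one site type", {
  sv <- sample_specimens(generate_species_pool(clean_cfg(turnover = 1)))
  tab <- table(sv$truth$species_id, sv$metadata$site_type)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("turnover = 0 splits site types evenly on average", {
  sv <- sample_specimens(generate_species_pool(
    clean_cfg(turnover = 0, abundance_param = 0.99)))
  frac <- mean(sv$metadata$site_type == "forested")
  n <- nrow(sv$metadata)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / n) + 0.02)
})

test_that("sequencing dropout tracks the per-order success rates", {
  cfg <- simulation_config(n_species = 120, seed = 33, abundance_param = 0.99)
  sv <- sample_specimens(generate_species_pool(cfg))
  s <- summarize_success(sv$metadata, sv$recovered_ids)
  pg <- s$per_group
  for (o in pg$group) {
    p_true <- cfg$per_group_success[[o]]
    n <- pg$attempted[pg$group == o]
    expect_lt(abs(pg$rate[pg$group == o] - p_true),
              4 * sqrt(p_true * (1 - p_true) / n) + 0.01)
  }
})

test_that("QC artifacts produce sequences that fail the grades", {
  sv <- sample_specimens(generate_species_pool(
    small_cfg(truncation_prob = 0.5, ambiguity_prob = 0.3)))
  expect_gt(sv$counts$truncated, 0)
  expect_gt(sv$counts$ambiguity_injected, 0)
  expect_lt(sum(passes_bin_grade(sv$sequences)), nrow(sv$sequences))
  expect_true(all(sv$sequences$length[sv$sequences$length < 648] <= 480))
})

test_that("identifiable configs let clustering recover the true species
           exactly", {
  sv <- sample_specimens(generate_species_pool(clean_cfg()))
  rep <- end_to_end_truth_check(sv, n_permutations = 99, seed = 1)
  expect_true(rep$exact_match)
  expect_equal(rep$ari, 1)
  expect_equal(rep$n_motus, rep$n_true_species_observed)
})

test_that("undersampling a pool leaves singletons and pushes Chao above
           S_obs", {
  sv <- sample_specimens(generate_species_pool(clean_cfg()))
  keep <- sample(nrow(sv$sequences), round(0.3 * nrow(sv$sequences)))
  sub <- sv$sequences[sort(keep), ]
  class(sub) <- c("barcode_set", "data.frame")
  p <- delineate_motus(sub, threshold = 15)
  sp <- abundance_spectrum(p$assignment)
  expect_gt(sum(sp$abundances == 1), 0)
  expect_gt(chao1(sp)$estimate, sp$S_obs)
})

test_that("partition-agreement index matches the reference implementation", {
  withr::local_seed(50)
  for (i in 1:5) {
    a <- sample(letters[1:5], 40, replace = TRUE)
    b <- sample(letters[1:4], 40, replace = TRUE)
    expect_equal(barcodiv:::.adjusted_rand(a, b),
                 unname(mclust::adjustedRandIndex(a, b)), tolerance = 1e-12)
  }
  a <- rep(1:4, each = 5)
  expect_equal(barcodiv:::.adjusted_rand(a, a), 1)
})
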