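test_that("abundance spectrum satisfies its accounting identities", {
  sp <- abundance_spectrum(c("a", "a", "b", "c", "c", "c", "d"))
  expect_equal(sp$S_obs, 4L)
  expect_equal(sp$N, 7L)
  expect_equal(sum(sp$f), sp$S_obs)
  expect_equal(sum(as.integer(names(sp$f)) * sp$f), sp$N)
  expect_equal(unname(sp$f[c("1", "2", "3")]), c(2L, 1L, 1L))
})

test_that("accumulation curve endpoints are exact", {
  one <- accumulation_curve(rep("m", 20), iterations = 5, seed = 1)
  expect_true(all(one$curve$mean_S == 1))

  dis <- accumulation_curve(paste0("m", 1:15), iterations = 5, seed = 1)
  expect_equal(dis$curve$mean_S, as.numeric(1:15))

  mix <- accumulation_curve(c("a", "a", "b"), iterations = 50, seed = 1)
  expect_equal(mix$curve$mean_S[1], 1)
  expect_equal(mix$curve$mean_S[3], 2)  # ends exactly at S_obs
  expect_true(!is.unsorted(mix$curve$mean_S))

  expect_error(accumulation_curve(letters, iterations = 0), "iterations")
})

test_that("accumulation curves are reproducible under a seed", {
  labels <- sample(letters[1:6], 40, replace = TRUE)
  c1 <- accumulation_curve(labels, iterations = 100, seed = 99)
  c2 <- accumulation_curve(labels, iterations = 100, seed = 99)
  expect_identical(c1$curve, c2$curve)
})

test_that("analytic rarefaction matches exhaustive small cases", {
  # abundances (2,1), n = 2: of the 3 equally likely pairs, two contain
  # both MOTUs -> E[S] = 2 - 1/3 = 5/3
  sp <- abundance_spectrum(c(2L, 1L), type = "abundances")
  expect_equal(analytic_rarefaction(sp, 2), 5 / 3)
  expect_equal(analytic_rarefaction(sp, 1), 1)
  expect_equal(analytic_rarefaction(sp, 3), 2)
  expect_error(analytic_rarefaction(sp, 4), "between 0 and N")
})

test_that("Monte-Carlo curve converges to analytic rarefaction", {
  labels <- rep(paste0("m", 1:6), c(4, 3, 2, 1, 1, 1))
  it <- 1000L
  cu <- accumulation_curve(labels, iterations = it, seed = 7)
  sp <- abundance_spectrum(labels)
  exact <- analytic_rarefaction(sp, cu$curve$n)
  se <- cu$curve$sd_S / sqrt(it)
  expect_true(all(abs(cu$curve$mean_S - exact) <= 3 * se + 1e-9))
})

test_that("terminal slope and completeness categories follow the strict
           boundaries", {
  lin <- accumulation_curve(paste0("m", 1:20), iterations = 5, seed = 1)
  cc <- terminal_slope(lin)
  expect_equal(cc$terminal_slope, 1)
  expect_equal(cc$category, "very_undersampled")

  sat <- accumulation_curve(rep("m", 30), iterations = 5, seed = 1)
  expect_equal(terminal_slope(sat)$category, "well_sampled")

  fake <- function(slope) list(curve = data.frame(
    n = 1:20, mean_S = c(rep(5, 10), 5 + slope * (1:10))))
  expect_equal(terminal_slope(fake(0.1))$category, "modestly_undersampled")
  expect_equal(terminal_slope(fake(0.01))$category, "well_sampled")
  expect_equal(classify_completeness(0.007), "well_sampled")
  expect_equal(classify_completeness(0.200), "very_undersampled")
  expect_equal(classify_completeness(0.05), "modestly_undersampled")

  expect_error(terminal_slope(accumulation_curve(rep("m", 5), iterations = 2,
                                                 seed = 1)),
               "pool")
})

test_that("Chao1 reproduces hand-evaluated worked examples", {
  # abundances (1,1,2,3): S=4, f1=2, f2=1
  sp <- abundance_spectrum(c(1L, 1L, 2L, 3L), type = "abundances")
  expect_equal(chao1(sp, "classic")$estimate, 6.0)
  expect_equal(chao1(sp, "bias_corrected")$estimate, 4.5)

  # no singletons: nothing unseen is inferred
  sp0 <- abundance_spectrum(c(2L, 3L, 2L), type = "abundances")
  for (v in c("classic", "bias_corrected")) {
    est <- chao1(sp0, v)
    expect_equal(est$estimate, 3)
    expect_equal(est$se, 0)
  }
  expect_error(chao1(abundance_spectrum(integer(), type = "abundances")),
               "empty")
})

test_that("Chao1 estimate dominates S_obs and bias correction shrinks it", {
  withr::local_seed(20)
  for (i in 1:25) {
    ab <- sample(1:8, sample(3:30, 1), replace = TRUE)
    sp <- abundance_spectrum(ab, type = "abundances")
    cl <- chao1(sp, "classic"); bc <- chao1(sp, "bias_corrected")
    expect_gte(cl$estimate, sp$S_obs)
    expect_gte(bc$estimate, sp$S_obs)
    expect_gte(cl$se, 0)
    f1 <- sum(ab == 1); f2 <- sum(ab == 2)
    if (f2 > 0 && f1 > 1) expect_lte(bc$estimate, cl$estimate)
  }
})

test_that("family analysis groups follow the >100 specimens / >10 MOTUs rule", {
  md <- rbind(make_metadata(93, family = "Blatti", prefix = "b"),
              make_metadata(99, family = "Small", prefix = "s"),
              make_metadata(101, family = "Big", prefix = "g"))
  asn <- structure(c(paste0("B", rep(1:18, length.out = 93)),
                     paste0("S", rep(1:9, length.out = 99)),
                     paste0("G", rep(1:2, length.out = 101))),
                   names = md$specimen_id)
  ga <- group_for_analysis(md, make_partition(asn))
  grp <- function(fam) unique(ga$analysis_group[ga$family == fam])
  expect_equal(grp("Blatti"), "Blatti")      # 18 MOTUs > 10
  expect_equal(grp("Big"), "Big")            # 101 specimens > 100
  expect_equal(grp("Small"), "Others Mesostigmata")
  expect_true(all(ga$pooled[ga$family == "Small"]))
})

test_that("richness increases and checklist changes round half-up", {
  ri <- richness_increase(693, 899)
  expect_equal(ri$additional, 206)
  expect_equal(ri$percent_increase, 30)
  expect_equal(richness_increase(256, 327)$percent_increase, 28)
  expect_equal(richness_increase(100, 100)$percent_increase, 0)

  core <- paste0("m", 1:10)
  aug <- paste0("m", 1:13)
  ri2 <- richness_increase(core, aug)
  expect_equal(ri2$additional, 3)
  expect_equal(ri2$percent_increase, 30)
  expect_error(richness_increase(c(core, "zzz"), aug), "subset")

  expect_equal(percent_change(135, 76), 78)
  expect_equal(percent_change(327, 144), 127)
  expect_equal(percent_change(437, 122), 258)
  expect_equal(percent_change(50, 50), 0)
  expect_error(percent_change(10, 0), "reference")
})

test_that("order diversity shares use half-up integer percentages", {
  expect_equal(unname(percent_share(c(135, 327, 437))), c(15, 36, 49))
  expect_equal(unname(percent_share(c(1, 1))), c(50, 50))
})
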