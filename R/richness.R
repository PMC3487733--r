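#' Abundance spectrum of a group of specimens
#'
#' The frequency-of-frequencies summary feeding rarefaction and Chao
#' estimation: observed MOTU count `S_obs`, specimen count `N`, and the
#' histogram `f[k]` = number of MOTUs observed exactly `k` times
#' (`f1` singletons, `f2` doubletons).
#'
#' @param x per-specimen MOTU labels (character/factor), or a vector of
#'   per-MOTU abundances (integer counts >= 1).
#' @param group_label optional label carried into reports.
#' @param type `"labels"` (default) or `"abundances"`, how to read `x`.
#' @return object of class `abundance_spectrum`: list with `group_label`,
#'   `S_obs`, `N`, `abundances`, and `f` (named vector, names are k).
#' @export
abundance_spectrum <- function(x, group_label = "",
                               type = c("labels", "abundances")) {
  type <- match.arg(type)
  abund <- if (type == "labels") as.integer(table(as.character(x)))
           else as.integer(x)
  if (length(abund) && any(abund < 1)) stop("abundances must be >= 1")
  f_tab <- table(abund)
  f <- structure(as.integer(f_tab), names = names(f_tab))
  structure(list(group_label = group_label,
                 S_obs = length(abund), N = sum(abund),
                 abundances = abund, f = f),
            class = "abundance_spectrum")
}

.fk <- function(spectrum, k) {
  v <- unname(spectrum$f[as.character(k)])
  ifelse(is.na(v), 0L, as.integer(v))
}

#' Specimen-based MOTU accumulation curve
#'
#' For each of `iterations` random permutations of the specimens, counts
#' the distinct MOTUs among the first n specimens, for n = 1..N, and
#' reports the mean (and sd) across iterations. The curve starts at 1
#' and ends exactly at `S_obs`.
#'
#' @param labels per-specimen MOTU labels.
#' @param iterations number of random orderings (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @param group_label optional label carried into reports.
#' @return object of class `accumulation_curve`: list with `curve`
#'   (data frame `n`, `mean_S`, `sd_S`), `iterations`, `seed`,
#'   `group_label`, `S_obs`, `N`.
#' @export
accumulation_curve <- function(labels, iterations = 1000L, seed = NULL,
                               group_label = "") {
  if (iterations < 1) stop("iterations must be >= 1")
  x <- as.character(labels)
  N <- length(x)
  if (N < 1) stop("need at least one specimen")
  sums <- numeric(N); sumsq <- numeric(N)
  with_seed(seed, {
    for (it in seq_len(iterations)) {
      s <- cumsum(!duplicated(x[sample.int(N)]))
      sums <- sums + s
      sumsq <- sumsq + s^2
    }
  })
  mean_S <- sums / iterations
  var_S <- pmax(0, sumsq / iterations - mean_S^2)
  sd_S <- if (iterations > 1) sqrt(var_S * iterations / (iterations - 1))
          else rep(NA_real_, N)
  structure(list(curve = data.frame(n = seq_len(N), mean_S = mean_S,
                                    sd_S = sd_S),
                 iterations = as.integer(iterations), seed = seed,
                 group_label = group_label,
                 S_obs = length(unique(x)), N = N),
            class = "accumulation_curve")
}

#' @export
print.accumulation_curve <- function(x, ...) {
  cat(sprintf("Accumulation curve%s: %d MOTUs from %d specimens (%d iterations)\n",
              if (nzchar(x$group_label)) paste0(" [", x$group_label, "]") else "",
              x$S_obs, x$N, x$iterations))
  invisible(x)
}

#' @export
plot.accumulation_curve <- function(x, ...) {
  graphics::plot(x$curve$n, x$curve$mean_S, type = "l",
                 xlab = "Specimens", ylab = "MOTUs",
                 main = if (nzchar(x$group_label)) x$group_label
                        else "MOTU accumulation", ...)
  invisible(x)
}

#' Analytic (hypergeometric) rarefaction
#'
#' Closed-form expected MOTU count in a random subsample of n specimens:
#' E[S(n)] = S_obs - sum_i C(N - N_i, n) / C(N, n) over MOTU abundances
#' N_i, computed with log-binomials for numerical safety. This is the
#' exact expectation the Monte-Carlo accumulation curve converges to.
#'
#' @param spectrum an [abundance_spectrum()].
#' @param n integer vector of subsample sizes, each in 0..N.
#' @return numeric vector of expected MOTU counts.
#' @export
analytic_rarefaction <- function(spectrum, n) {
  stopifnot(inherits(spectrum, "abundance_spectrum"))
  if (any(n < 0) || any(n > spectrum$N))
    stop("n must be between 0 and N = ", spectrum$N)
  Ni <- spectrum$abundances
  N <- spectrum$N
  vapply(n, function(k) {
    spectrum$S_obs - sum(exp(lchoose(N - Ni, k) - lchoose(N, k)))
  }, numeric(1))
}

#' Terminal slope of an accumulation curve, with a completeness call
#'
#' The slope of the mean accumulation curve over its last `window`
#' specimens, (S(N) - S(N - window)) / window, in MOTUs per specimen.
#' Groups with slope > 0.1 are called very undersampled, slope > 0.01
#' modestly undersampled, and anything else well sampled (both bounds
#' strict, so slope exactly 0.1 is "modest" and exactly 0.01 "well").
#'
#' @param curve an [accumulation_curve()] (or any list with a `curve`
#'   data frame holding `n` and `mean_S`).
#' @param window number of terminal specimens (default 10).
#' @return object of class `completeness_call`: list with
#'   `terminal_slope`, `window`, `category`.
#' @export
terminal_slope <- function(curve, window = 10L) {
  cv <- curve$curve
  N <- max(cv$n)
  if (N <= window)
    stop("curve has only ", N, " specimens (<= window of ", window,
         "); pool this group into 'Others' before slope analysis")
  slope <- (cv$mean_S[cv$n == N] - cv$mean_S[cv$n == N - window]) / window
  structure(list(terminal_slope = slope, window = as.integer(window),
                 category = classify_completeness(slope)),
            class = "completeness_call")
}

#' Completeness category from a terminal slope
#'
#' @param slope terminal slope in MOTUs per specimen.
#' @return one of `"very_undersampled"`, `"modestly_undersampled"`,
#'   `"well_sampled"`.
#' @export
classify_completeness <- function(slope) {
  ifelse(slope > 0.1, "very_undersampled",
         ifelse(slope > 0.01, "modestly_undersampled", "well_sampled"))
}

#' Chao1 richness estimate with standard error
#'
#' Nonparametric lower-bound estimate of true MOTU richness from
#' singleton and doubleton counts. The classic form is
#' S_obs + f1^2 / (2 f2) (or S_obs + f1 (f1 - 1) / 2 when f2 = 0); the
#' bias-corrected form, the default and the behaviour of the estimator
#' in the vegan package, is S_obs + f1 (f1 - 1) / (2 (f2 + 1)).
#' Standard errors use the Chao (1987) variance family as tabulated in
#' the EstimateS documentation (Colwell), one variance formula per
#' variant and f2 case; with f1 = 0 the estimate is S_obs and the SE 0.
#'
#' @param spectrum an [abundance_spectrum()] (or abundance vector).
#' @param variant `"bias_corrected"` (default) or `"classic"`.
#' @return object of class `chao_estimate`: list with `estimate`, `se`,
#'   `variant`, `S_obs`, `f1`, `f2`.
#' @export
chao1 <- function(spectrum, variant = c("bias_corrected", "classic")) {
  variant <- match.arg(variant)
  if (!inherits(spectrum, "abundance_spectrum"))
    spectrum <- abundance_spectrum(spectrum, type = "abundances")
  if (spectrum$S_obs < 1) stop("empty abundance spectrum")
  S <- spectrum$S_obs
  f1 <- .fk(spectrum, 1); f2 <- .fk(spectrum, 2)
  if (f1 == 0) {
    est <- S; va <- 0
  } else if (variant == "classic") {
    if (f2 > 0) {
      est <- S + f1^2 / (2 * f2)
      r <- f1 / f2
      va <- f2 * (r^2 / 2 + r^3 + r^4 / 4)
    } else {
      est <- S + f1 * (f1 - 1) / 2
      va <- f1 * (f1 - 1) / 2 + f1 * (2 * f1 - 1)^2 / 4 - f1^4 / (4 * est)
    }
  } else {
    est <- S + f1 * (f1 - 1) / (2 * (f2 + 1))
    va <- f1 * (f1 - 1) / (2 * (f2 + 1)) +
      f1 * (2 * f1 - 1)^2 / (4 * (f2 + 1)^2) +
      f1^2 * f2 * (f1 - 1)^2 / (4 * (f2 + 1)^4)
  }
  structure(list(estimate = est, se = sqrt(max(0, va)), variant = variant,
                 S_obs = S, f1 = f1, f2 = f2),
            class = "chao_estimate")
}

#' @export
print.chao_estimate <- function(x, ...) {
  cat(sprintf("Chao1 (%s): %.1f (+/- %.1f SE); S_obs = %d, f1 = %d, f2 = %d\n",
              x$variant, x$estimate, x$se, x$S_obs, x$f1, x$f2))
  invisible(x)
}

#' Assign specimens to family-level analysis groups
#'
#' A family is analysed separately when it has strictly more than
#' `min_specimens` specimens or strictly more than `min_motus` MOTUs;
#' all remaining families are pooled into one "Others" group per order.
#'
#' @param metadata specimen metadata.
#' @param partition a [delineate_motus()] result covering the same
#'   specimens (specimens without an assignment are ignored).
#' @param min_specimens specimen threshold (default 100, exclusive).
#' @param min_motus MOTU threshold (default 10, exclusive).
#' @return data frame with columns `specimen_id`, `order`, `family`,
#'   `motu`, `analysis_group`, `pooled`.
#' @export
group_for_analysis <- function(metadata, partition, min_specimens = 100L,
                               min_motus = 10L) {
  ids <- intersect(metadata$specimen_id, names(partition$assignment))
  md <- metadata[match(ids, metadata$specimen_id), ]
  motu <- partition$assignment[ids]
  key <- paste(md$order, md$family, sep = "\r")
  n_spec <- tapply(ids, key, length)
  n_motu <- tapply(motu, key, function(m) length(unique(m)))
  separate <- n_spec > min_specimens | n_motu > min_motus
  sep_key <- separate[key]
  out <- data.frame(specimen_id = ids, order = md$order, family = md$family,
                    motu = unname(motu),
                    analysis_group = ifelse(sep_key, md$family,
                                            paste("Others", md$order)),
                    pooled = !sep_key, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Additional richness from augmented sampling
#'
#' How many MOTUs an augmented survey adds over a core survey, and the
#' percentage increase relative to the core. Inputs are either MOTU
#' label sets (core must be a subset of augmented) or plain richness
#' counts.
#'
#' @param core_motus character vector of core MOTU labels, or a single
#'   count.
#' @param augmented_motus character vector of augmented MOTU labels, or
#'   a single count >= core.
#' @return list with `core_richness`, `augmented_richness`, `additional`,
#'   `percent_increase` (half-up integer) and `percent_exact`.
#' @export
richness_increase <- function(core_motus, augmented_motus) {
  if (is.character(core_motus) || is.character(augmented_motus)) {
    core_motus <- unique(as.character(core_motus))
    augmented_motus <- unique(as.character(augmented_motus))
    if (length(setdiff(core_motus, augmented_motus)))
      stop("core MOTU set must be a subset of the augmented set")
    core <- length(core_motus); aug <- length(augmented_motus)
  } else {
    core <- as.numeric(core_motus); aug <- as.numeric(augmented_motus)
    if (aug < core) stop("augmented richness must be >= core richness")
  }
  additional <- aug - core
  pct <- if (core > 0) 100 * additional / core else NA_real_
  list(core_richness = core, augmented_richness = aug,
       additional = additional,
       percent_increase = if (is.na(pct)) NA_real_ else round_half_up(pct),
       percent_exact = pct)
}

#' Percent change against a reference checklist count
#'
#' (new - reference) / reference x 100, rounded half-up to an integer,
#' for comparing survey richness against previously published faunal
#' checklists.
#'
#' @param new_count newly observed richness.
#' @param reference_count checklist richness; must be > 0.
#' @return integer-valued percent change.
#' @export
percent_change <- function(new_count, reference_count) {
  if (any(reference_count <= 0)) stop("reference_count must be > 0")
  round_half_up(100 * (new_count - reference_count) / reference_count)
}
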