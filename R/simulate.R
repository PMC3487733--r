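#' Configuration for the synthetic community generator
#'
#' The generator emulates a subarctic soil-mite barcode survey: roughly
#' 900 species spread over three orders in proportions 15/36/49, a
#' long-tailed (log-series) abundance distribution rich in singletons,
#' 10 sites split between forested and non-forested settings, 8
#' substrates (7 Berlese-extracted substrates plus pooled pitfall
#' transects), per-order sequencing success between ~68% and ~80%, and
#' occasional quality artifacts (truncated reads, runs of ambiguous
#' bases). Species references diverge by at least `min_interspecific`
#' changes while conspecific specimens carry at most `max_intraspecific`
#' substitutions, so at the default clustering threshold of 15 changes
#' MOTUs recover true species exactly. The config is rejected as
#' non-identifiable unless
#' `2 * max_intraspecific <= threshold < min_interspecific - 2 * max_intraspecific`.
#'
#' @param n_species number of species in the pool.
#' @param barcode_length reference barcode length in bp.
#' @param min_interspecific minimum pairwise reference distance
#'   (nucleotide changes).
#' @param max_intraspecific maximum substitutions per specimen from its
#'   species reference.
#' @param threshold clustering threshold the dataset must be
#'   identifiable under.
#' @param abundance_model `"log_series"` or `"lognormal"`.
#' @param abundance_param log-series parameter x in (0, 1) (default
#'   0.955, giving ~7 specimens per species on average), or the lognormal
#'   sdlog.
#' @param n_sites number of sites.
#' @param forested_fraction fraction of sites that are forested.
#' @param n_substrates number of substrates (7 Berlese substrates +
#'   pitfall when 8).
#' @param turnover in \[0, 1\]; probability (1 + turnover)/2 that a
#'   specimen is sampled within its species' affinity site type and
#'   substrate.
#' @param order_names,order_shares synthetic order vocabulary and their
#'   species shares.
#' @param families_per_order number of families per order.
#' @param per_group_success named per-order sequencing success
#'   probabilities.
#' @param truncation_prob per-recovered-specimen probability of a
#'   truncated read; `truncation_range` gives its length range in bp.
#' @param ambiguity_prob probability of an injected run of Ns;
#'   `ambiguity_run` gives the run-length range.
#' @param qualitative list controlling an optional 2011 qualitative
#'   sampling layer: `enabled`, `species_fraction`, `max_specimens`,
#'   `substrate` (NULL = random per species).
#' @param seed integer seed; the whole dataset is a deterministic
#'   function of the config.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 900L,
                              barcode_length = 648L,
                              min_interspecific = 30L,
                              max_intraspecific = 5L,
                              threshold = 15L,
                              abundance_model = c("log_series", "lognormal"),
                              abundance_param = 0.955,
                              n_sites = 10L,
                              forested_fraction = 0.5,
                              n_substrates = 8L,
                              turnover = 0.8,
                              order_names = c("Mesostigmata",
                                              "Sarcoptiformes",
                                              "Trombidiformes"),
                              order_shares = c(0.15, 0.36, 0.49),
                              families_per_order = c(17L, 39L, 21L),
                              per_group_success = c(Mesostigmata = 0.765,
                                                    Sarcoptiformes = 0.804,
                                                    Trombidiformes = 0.682),
                              truncation_prob = 0.01,
                              truncation_range = c(150L, 480L),
                              ambiguity_prob = 0.005,
                              ambiguity_run = c(7L, 40L),
                              qualitative = list(enabled = FALSE,
                                                 species_fraction = 0.3,
                                                 max_specimens = 3L,
                                                 substrate = NULL),
                              seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(n_species >= 1, barcode_length >= 1,
            min_interspecific >= 1, max_intraspecific >= 0,
            turnover >= 0, turnover <= 1,
            n_sites >= 2, forested_fraction > 0, forested_fraction < 1,
            n_substrates >= 1,
            length(order_names) == length(order_shares),
            length(order_names) == length(families_per_order),
            abs(sum(order_shares) - 1) < 1e-8,
            all(order_names %in% names(per_group_success)),
            all(per_group_success > 0 & per_group_success <= 1))
  .check_sequence_space(n_species, barcode_length, min_interspecific)
  if (!(2 * max_intraspecific <= threshold &&
        threshold < min_interspecific - 2 * max_intraspecific))
    stop("non-identifiable config: need 2*max_intraspecific <= threshold ",
         "< min_interspecific - 2*max_intraspecific (got ",
         2 * max_intraspecific, " <= ", threshold, " < ",
         min_interspecific - 2 * max_intraspecific, ")")
  structure(list(n_species = as.integer(n_species),
                 barcode_length = as.integer(barcode_length),
                 min_interspecific = as.integer(min_interspecific),
                 max_intraspecific = as.integer(max_intraspecific),
                 threshold = as.integer(threshold),
                 abundance_model = abundance_model,
                 abundance_param = abundance_param,
                 n_sites = as.integer(n_sites),
                 forested_fraction = forested_fraction,
                 n_substrates = as.integer(n_substrates),
                 turnover = turnover,
                 order_names = order_names,
                 order_shares = order_shares,
                 families_per_order = as.integer(families_per_order),
                 per_group_success = per_group_success,
                 truncation_prob = truncation_prob,
                 truncation_range = as.integer(truncation_range),
                 ambiguity_prob = ambiguity_prob,
                 ambiguity_run = as.integer(ambiguity_run),
                 qualitative = utils::modifyList(
                   list(enabled = FALSE, species_fraction = 0.3,
                        max_specimens = 3L, substrate = NULL),
                   qualitative),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.bases <- c("A", "C", "G", "T")

# Log-series abundances (support k >= 1): P(k) proportional to x^k / k.
.rlogseries <- function(n, x) {
  stopifnot(x > 0, x < 1)
  kmax <- max(50L, ceiling(log(1e-14) / log(x)))
  k <- seq_len(kmax)
  sample(k, n, replace = TRUE, prob = x^k / k)
}

.mutate_chars <- function(chars, k) {
  if (k == 0) return(chars)
  pos <- sample.int(length(chars), k)
  chars[pos] <- vapply(chars[pos],
                       function(b) sample(setdiff(.bases, b), 1), "")
  chars
}

# Sphere-packing (Hamming-bound) feasibility check in log space.
.check_sequence_space <- function(n_species, L, min_inter) {
  if (min_inter > L)
    stop("min_interspecific exceeds the barcode length")
  r <- floor((min_inter - 1) / 2)
  logv <- lchoose(L, 0:r) + (0:r) * log(3)
  log_ball <- max(logv) + log(sum(exp(logv - max(logv))))
  if (log(n_species) + log_ball > L * log(4))
    stop("infeasible divergence constraints: ", n_species,
         " species cannot be packed at minimum distance ", min_inter,
         " in a ", L, "-bp sequence space")
  invisible(TRUE)
}

#' Generate a reference species pool
#'
#' Draws one reference barcode per species by placing `min_interspecific`
#' substitutions on a shared random ancestor, rejection-resampling any
#' species whose reference falls closer than `min_interspecific` changes
#' to another (verified exhaustively over all pairs). Species are
#' assigned to synthetic orders by the configured shares and to families
#' with long-tailed (Zipf-weighted) family sizes.
#'
#' @param config a [simulation_config()].
#' @return object of class `species_pool`: list with `sequences` (named
#'   character vector, one reference per species), `taxonomy` (data
#'   frame: `species_id`, `order`, `family`, `genus`), and `config`.
#' @export
generate_species_pool <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  L <- config$barcode_length
  nsp <- config$n_species
  .check_sequence_space(nsp, L, config$min_interspecific)
  with_seed(config$seed, {
    ancestor <- sample(.bases, L, replace = TRUE)
    draw_ref <- function() paste(.mutate_chars(ancestor,
                                               config$min_interspecific),
                                 collapse = "")
    refs <- vapply(seq_len(nsp), function(i) draw_ref(), "")
    ids <- sprintf("SP%04d", seq_len(nsp))
    names(refs) <- ids
    # enforce the minimum pairwise divergence by redrawing offenders
    for (round in seq_len(100L)) {
      bs <- barcode_set(refs)
      D <- .hamming_matrices(bs)$differences
      diag(D) <- Inf
      bad <- which(apply(D, 1, min) < config$min_interspecific)
      if (!length(bad)) break
      if (round == 100L)
        stop("could not satisfy divergence constraints after 100 rounds")
      refs[bad] <- vapply(bad, function(i) draw_ref(), "")
    }
    n_per_order <- stats::setNames(
      diff(round(cumsum(c(0, config$order_shares)) * nsp)),
      config$order_names)
    ord <- rep(config$order_names, n_per_order)
    fam <- character(nsp); gen <- character(nsp)
    for (k in seq_along(config$order_names)) {
      idx <- which(ord == config$order_names[k])
      nf <- config$families_per_order[k]
      fam_names <- sprintf("Fam_%s_%02d",
                           substr(config$order_names[k], 1, 4), seq_len(nf))
      # Zipf weights give a few large families and a long tail
      fam[idx] <- sample(fam_names, length(idx), replace = TRUE,
                         prob = 1 / seq_len(nf))
      gen[idx] <- if (k == 2) paste0(fam[idx], "_g") else ""
    }
    taxonomy <- data.frame(species_id = ids, order = ord, family = fam,
                           genus = gen, stringsAsFactors = FALSE)
    structure(list(sequences = refs, taxonomy = taxonomy, config = config),
              class = "species_pool")
  })
}

#' Sample a synthetic specimen dataset from a species pool
#'
#' Draws per-species abundances from the configured abundance model,
#' derives each specimen's sequence from its species reference with at
#' most `max_intraspecific` random substitutions, places specimens on
#' sites and substrates under the turnover model, applies per-order
#' sequencing dropout, and injects quality artifacts (truncations and
#' ambiguity runs) at the configured rates. With qualitative sampling
#' enabled, an additional set of species receives a few specimens each
#' in a later collection year.
#'
#' @param pool a [generate_species_pool()] result.
#' @param config a [simulation_config()]; defaults to the pool's own.
#' @return object of class `synthetic_survey`: list with `sequences`
#'   (a [barcode_set()] of recovered barcodes), `metadata` (one row per
#'   attempted specimen, with a `recovered` column), `recovered_ids`,
#'   `truth` (specimen -> true species, with a `qualitative` flag),
#'   `sites`, `counts`, `pool`, `config`.
#' @export
sample_specimens <- function(pool, config = pool$config) {
  stopifnot(inherits(pool, "species_pool"))
  nsp <- config$n_species
  n_forest <- max(1L, min(config$n_sites - 1L,
                          round(config$n_sites * config$forested_fraction)))
  sites <- data.frame(
    site_id = sprintf("Site%02d", seq_len(config$n_sites)),
    site_type = rep(c("forested", "non-forested"),
                    c(n_forest, config$n_sites - n_forest)),
    stringsAsFactors = FALSE)
  substrates <- c("moss", "soil", "litter", "woody_debris", "lichen_Cladina",
                  "lichen_Peltigera", "lichen_Parmelia_Hypogymnia",
                  "pitfall")[seq_len(min(8L, config$n_substrates))]
  if (config$n_substrates > 8L)
    substrates <- c(substrates,
                    sprintf("substrate_%02d", 9:config$n_substrates))
  with_seed(config$seed + 1L, {
    abund <- switch(config$abundance_model,
      log_series = .rlogseries(nsp, config$abundance_param),
      lognormal = pmax(1L, round(stats::rlnorm(nsp, meanlog = 1,
                                               sdlog = config$abundance_param))))
    aff_type <- sample(c("forested", "non-forested"), nsp, replace = TRUE)
    aff_sub <- sample(substrates, nsp, replace = TRUE)
    sp_idx <- rep.int(seq_len(nsp), abund)
    n_spec <- length(sp_idx)
    p_aff <- (1 + config$turnover) / 2
    in_aff <- stats::runif(n_spec) < p_aff
    type <- ifelse(in_aff, aff_type[sp_idx],
                   ifelse(aff_type[sp_idx] == "forested",
                          "non-forested", "forested"))
    site_id <- vapply(type, function(tt)
      sample(sites$site_id[sites$site_type == tt], 1), "")
    sub_aff <- stats::runif(n_spec) < p_aff
    substrate <- ifelse(sub_aff, aff_sub[sp_idx], NA)
    needs <- which(is.na(substrate))
    substrate[needs] <- vapply(needs, function(i)
      sample(setdiff(substrates, aff_sub[sp_idx[i]]), 1), "")
    year <- rep(2010L, n_spec)
    method <- ifelse(substrate == "pitfall", "pitfall", "berlese")
    qualitative <- rep(FALSE, n_spec)

    if (isTRUE(config$qualitative$enabled)) {
      nq <- round(nsp * config$qualitative$species_fraction)
      q_species <- sample(seq_len(nsp), nq)
      q_counts <- sample.int(config$qualitative$max_specimens, nq,
                             replace = TRUE)
      q_idx <- rep.int(q_species, q_counts)
      q_sub <- if (is.null(config$qualitative$substrate))
        sample(substrates, length(q_idx), replace = TRUE)
      else rep(config$qualitative$substrate, length(q_idx))
      sp_idx <- c(sp_idx, q_idx)
      site_id <- c(site_id, sample(sites$site_id, length(q_idx),
                                   replace = TRUE))
      type <- c(type, sites$site_type[match(site_id[(n_spec + 1):length(sp_idx)],
                                            sites$site_id)])
      substrate <- c(substrate, q_sub)
      year <- c(year, rep(2011L, length(q_idx)))
      method <- c(method, rep("aspirator", length(q_idx)))
      qualitative <- c(qualitative, rep(TRUE, length(q_idx)))
      n_spec <- length(sp_idx)
    }

    tax <- pool$taxonomy[sp_idx, ]
    specimen_id <- sprintf("SPEC%06d", seq_len(n_spec))
    metadata <- data.frame(specimen_id = specimen_id,
                           order = tax$order, family = tax$family,
                           genus = tax$genus, site_id = site_id,
                           site_type = type, substrate = substrate,
                           method = method, year = year,
                           stringsAsFactors = FALSE)
    truth <- data.frame(specimen_id = specimen_id,
                        species_id = pool$taxonomy$species_id[sp_idx],
                        qualitative = qualitative, stringsAsFactors = FALSE)

    # sequencing dropout by order-specific success probability
    succ_p <- config$per_group_success[tax$order]
    recovered <- stats::runif(n_spec) < succ_p
    metadata$recovered <- recovered

    ref_chars <- strsplit(pool$sequences, "")
    n_trunc <- 0L; n_amb <- 0L
    seqs <- character(sum(recovered))
    rec_idx <- which(recovered)
    for (i in seq_along(rec_idx)) {
      chars <- ref_chars[[sp_idx[rec_idx[i]]]]
      k <- sample.int(config$max_intraspecific + 1L, 1L) - 1L
      chars <- .mutate_chars(chars, k)
      if (stats::runif(1) < config$truncation_prob) {
        len <- sample(config$truncation_range[1]:config$truncation_range[2], 1)
        start <- sample.int(length(chars) - len + 1L, 1L)
        chars <- chars[start:(start + len - 1L)]
        n_trunc <- n_trunc + 1L
      }
      if (stats::runif(1) < config$ambiguity_prob) {
        run <- min(length(chars),
                   sample(config$ambiguity_run[1]:config$ambiguity_run[2], 1))
        start <- sample.int(length(chars) - run + 1L, 1L)
        chars[start:(start + run - 1L)] <- "N"
        n_amb <- n_amb + 1L
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    names(seqs) <- specimen_id[rec_idx]
    counts <- list(drawn = n_spec, dropped = sum(!recovered),
                   emitted = sum(recovered), truncated = n_trunc,
                   ambiguity_injected = n_amb)
    structure(list(sequences = barcode_set(seqs), metadata = metadata,
                   recovered_ids = specimen_id[rec_idx], truth = truth,
                   sites = sites, counts = counts, pool = pool,
                   config = config),
              class = "synthetic_survey")
  })
}

#' @export
print.synthetic_survey <- function(x, ...) {
  cat("Synthetic barcode survey:", x$counts$drawn, "specimens drawn,",
      x$counts$emitted, "barcodes recovered\n")
  cat("  species pool:", x$config$n_species, "| sites:", x$config$n_sites,
      "| substrates:", x$config$n_substrates, "\n")
  cat("  artifacts: ", x$counts$truncated, " truncated, ",
      x$counts$ambiguity_injected, " with ambiguity runs\n", sep = "")
  invisible(x)
}

#' Write a synthetic survey to disk
#'
#' Emits the FASTA and metadata formats consumed by the readers, plus the
#' ground-truth table.
#'
#' @param survey a [sample_specimens()] result.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_survey <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "sequences.fasta"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_barcode_fasta(survey$sequences, paths["fasta"])
  write_specimen_metadata(survey$metadata, paths["metadata"])
  utils::write.table(survey$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

# Adjusted Rand index between two label vectors (Hubert & Arabie).
.adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

#' End-to-end ground-truth recovery report
#'
#' Checks the full pipeline against the simulator's ground truth:
#' (i) agreement between the MOTU partition and the true species labels
#' (adjusted Rand index; exactly 1 under an identifiable config),
#' (ii) the Chao1 estimate against the true pool richness, and
#' (iii) ANOSIM detection of the forested / non-forested structure.
#'
#' @param survey a [sample_specimens()] result.
#' @param partition optional precomputed [delineate_motus()] result for
#'   the MOTU-grade sequences; computed if missing.
#' @param thresholds a [qc_thresholds()].
#' @param n_permutations permutations for the ANOSIM check.
#' @param seed seed for the ANOSIM permutations.
#' @return object of class `truth_report`: list with `ari`,
#'   `exact_match`, `n_motus`, `n_true_species_observed`,
#'   `true_pool_richness`, `chao`, `anosim`.
#' @export
end_to_end_truth_check <- function(survey, partition = NULL,
                                   thresholds = qc_thresholds(),
                                   n_permutations = 999L, seed = NULL) {
  stopifnot(inherits(survey, "synthetic_survey"))
  keep <- passes_motu_grade(survey$sequences, thresholds)
  seqs <- survey$sequences[keep, ]
  class(seqs) <- c("barcode_set", "data.frame")
  if (is.null(partition))
    partition <- delineate_motus(seqs, threshold = survey$config$threshold)
  ids <- names(partition$assignment)
  true_sp <- survey$truth$species_id[match(ids, survey$truth$specimen_id)]
  ari <- .adjusted_rand(partition$assignment, true_sp)
  exact <- length(unique(true_sp)) == length(partition$motu_labels) &&
    isTRUE(all.equal(ari, 1))
  ch <- chao1(abundance_spectrum(partition$assignment))
  an <- tryCatch({
    cm <- community_matrix(survey$metadata, partition,
                           aggregate_by = "site", year = 2010L)
    anosim_test(bray_curtis_matrix(cm), attr(cm, "grouping"),
                n_permutations = n_permutations, seed = seed)
  }, error = function(e) NULL)
  structure(list(ari = ari, exact_match = exact,
                 n_motus = length(partition$motu_labels),
                 n_true_species_observed = length(unique(true_sp)),
                 true_pool_richness = survey$config$n_species,
                 chao = ch, anosim = an),
            class = "truth_report")
}

#' @export
print.truth_report <- function(x, ...) {
  cat("Ground-truth recovery:\n")
  cat(sprintf("  MOTUs: %d vs %d observed true species (ARI %.3f%s)\n",
              x$n_motus, x$n_true_species_observed, x$ari,
              if (x$exact_match) ", exact" else ""))
  cat(sprintf("  Chao1: %.1f (+/- %.1f) vs pool richness %d\n",
              x$chao$estimate, x$chao$se, x$true_pool_richness))
  if (!is.null(x$anosim))
    cat(sprintf("  ANOSIM site-type: R = %.3f, p = %.3g\n",
                x$anosim$R, x$anosim$p))
  invisible(x)
}
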