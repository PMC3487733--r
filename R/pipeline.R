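#' Run the full barcode biodiversity assessment
#'
#' Orchestrates the analysis stages on a set of recovered barcodes and
#' their specimen metadata: quality grading and sequencing-success
#' summary, MOTU delineation at the nucleotide-change threshold,
#' accumulation curves with terminal-slope completeness calls and Chao1
#' richness estimates (overall, per order, and per family-level analysis
#' group with "Others" pooling), optional checklist comparison, and
#' community-structure analysis (complete-linkage dendrograms on
#' Bray-Curtis dissimilarities of Hellinger-transformed site and
#' substrate matrices, ANOSIM on site type, mean dissimilarities).
#'
#' Metadata rows without a matching sequence are treated as failed
#' sequencing attempts and enter the success summary only.
#'
#' @param sequences a [barcode_set()] of recovered barcodes.
#' @param metadata specimen metadata (one row per attempted specimen).
#' @param threshold MOTU threshold in nucleotide changes (default 15).
#' @param thresholds a [qc_thresholds()].
#' @param iterations accumulation-curve iterations (default 1000).
#' @param permutations ANOSIM permutations (default 999).
#' @param slope_window terminal-slope window in specimens (default 10).
#' @param min_specimens,min_motus family analysis-group minima
#'   (defaults 100 specimens / 10 MOTUs, both exclusive).
#' @param checklist_reference optional named vector of reference
#'   checklist species counts per order.
#' @param community_year optional year filter selecting the systematic
#'   survey for community analysis.
#' @param community_transform `"hellinger"` (default) or `"raw"`:
#'   whether dendrogram dissimilarities are computed on transformed
#'   abundances. ANOSIM always uses raw-count Bray-Curtis.
#' @param dist_method distance method for [distance_matrix()].
#' @param seed optional master seed; all stochastic stages derive their
#'   seeds from it.
#' @param outdir optional directory; when given, all reports are written
#'   as delimited text plus Newick dendrograms, with a checksum manifest.
#' @return object of class `barcode_survey` (see Details), invisibly
#'   when `outdir` is given.
#' @export
barcode_survey <- function(sequences, metadata,
                           threshold = 15L,
                           thresholds = qc_thresholds(),
                           iterations = 1000L,
                           permutations = 999L,
                           slope_window = 10L,
                           min_specimens = 100L,
                           min_motus = 10L,
                           checklist_reference = NULL,
                           community_year = NULL,
                           community_transform = c("hellinger", "raw"),
                           dist_method = "auto",
                           seed = NULL,
                           outdir = NULL) {
  community_transform <- match.arg(community_transform)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(outdir)) {
        dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
        writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                   file.path(outdir, "FAILED"))
      }
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  metadata <- stage("validate", validate_specimen_metadata(metadata))
  stage("validate", {
    unknown <- setdiff(sequences$specimen_id, metadata$specimen_id)
    if (length(unknown))
      stop("sequence(s) without metadata: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  })

  qc <- stage("qc", {
    bin_ok <- passes_bin_grade(sequences, thresholds)
    motu_ok <- passes_motu_grade(sequences, thresholds)
    success <- summarize_success(metadata, sequences$specimen_id, "order")
    # low-expected-cell condition is carried on the result's own flag
    chisq <- if (nrow(success$per_group) >= 2)
      suppressWarnings(success_homogeneity_test(success$per_group)) else NULL
    ord <- metadata$order[match(sequences$specimen_id,
                                metadata$specimen_id)]
    grades_per_order <- data.frame(
      group = sort(unique(ord)),
      bin_grade = as.integer(tapply(bin_ok, ord, sum)),
      motu_grade = as.integer(tapply(motu_ok, ord, sum)),
      stringsAsFactors = FALSE)
    rownames(grades_per_order) <- NULL
    list(bin_grade = structure(bin_ok, names = sequences$specimen_id),
         motu_grade = structure(motu_ok, names = sequences$specimen_id),
         n_bin_grade = sum(bin_ok), n_motu_grade = sum(motu_ok),
         grades_per_order = grades_per_order,
         success = success, homogeneity = chisq)
  })

  partition <- stage("cluster", {
    keep <- sequences[qc$motu_grade, ]
    class(keep) <- c("barcode_set", "data.frame")
    delineate_motus(keep, threshold = threshold, method = dist_method)
  })
  motus <- stage("cluster", motu_summary(partition, metadata))

  analyzed_md <- metadata[metadata$specimen_id %in% names(partition$assignment), ]
  orders <- sort(unique(analyzed_md$order))

  richness <- stage("richness", {
    groups <- c(list(Total = names(partition$assignment)),
                stats::setNames(
                  lapply(orders, function(o)
                    analyzed_md$specimen_id[analyzed_md$order == o]),
                  orders))
    rows <- lapply(seq_along(groups), function(i) {
      ids <- groups[[i]]
      lab <- names(groups)[i]
      labels <- partition$assignment[ids]
      spec <- abundance_spectrum(labels, group_label = lab)
      curve <- accumulation_curve(labels, iterations = iterations,
                                  seed = if (is.null(seed)) NULL else seed + i,
                                  group_label = lab)
      ch <- chao1(spec)
      sl <- if (spec$N > slope_window) terminal_slope(curve, slope_window)
            else NULL
      fams <- length(unique(analyzed_md$family[match(ids, analyzed_md$specimen_id)]))
      list(curve = curve,
           row = data.frame(group = lab, motus = spec$S_obs, n = spec$N,
                            chao = ch$estimate, chao_se = ch$se,
                            slope = if (is.null(sl)) NA_real_
                                    else sl$terminal_slope,
                            category = if (is.null(sl)) NA_character_
                                       else sl$category,
                            n_families = fams, stringsAsFactors = FALSE))
    })
    report <- do.call(rbind, lapply(rows, `[[`, "row"))
    rownames(report) <- NULL
    list(report = report,
         curves = stats::setNames(lapply(rows, `[[`, "curve"), names(groups)))
  })

  family_report <- stage("richness", {
    ga <- group_for_analysis(analyzed_md, partition, min_specimens, min_motus)
    keys <- unique(ga[, c("order", "analysis_group")])
    rows <- lapply(seq_len(nrow(keys)), function(i) {
      sel <- ga$order == keys$order[i] & ga$analysis_group == keys$analysis_group[i]
      labels <- ga$motu[sel]
      sl <- if (length(labels) > slope_window) {
        cu <- accumulation_curve(labels, iterations = iterations,
                                 seed = if (is.null(seed)) NULL
                                        else seed + 100 + i,
                                 group_label = keys$analysis_group[i])
        terminal_slope(cu, slope_window)
      } else NULL
      data.frame(order = keys$order[i], group = keys$analysis_group[i],
                 motus = length(unique(labels)), n = length(labels),
                 slope = if (is.null(sl)) NA_real_ else sl$terminal_slope,
                 category = if (is.null(sl)) NA_character_ else sl$category,
                 pooled = grepl("^Others ", keys$analysis_group[i]),
                 stringsAsFactors = FALSE)
    })
    rep <- do.call(rbind, rows)
    rep <- rep[order(rep$order, rep$pooled, rep$group), ]
    rownames(rep) <- NULL
    rep
  })

  checklist <- if (!is.null(checklist_reference)) stage("checklist", {
    shared <- intersect(names(checklist_reference), orders)
    obs <- attr(motus, "motus_per_order")[shared]
    data.frame(order = shared,
               observed = as.integer(obs),
               reference = as.integer(checklist_reference[shared]),
               percent_change = percent_change(as.integer(obs),
                                               as.integer(checklist_reference[shared])),
               stringsAsFactors = FALSE)
  }) else NULL

  community <- stage("community", {
    out <- list()
    for (o in orders) {
      md_o <- analyzed_md[analyzed_md$order == o, ]
      for (agg in c("site", "substrate")) {
        res <- tryCatch({
          cm <- community_matrix(md_o, partition, aggregate_by = agg,
                                 year = community_year)
          if (nrow(cm) < 2) stop("fewer than 2 units")
          raw_bc <- bray_curtis_matrix(cm)
          dend_m <- if (community_transform == "hellinger")
            hellinger_transform(cm) else unclass(cm)
          dend <- complete_linkage(bray_curtis_matrix(dend_m))
          an <- if (agg == "site" &&
                    length(unique(attr(cm, "grouping"))) >= 2 &&
                    all(table(attr(cm, "grouping")) >= 2))
            anosim_test(raw_bc, attr(cm, "grouping"),
                        n_permutations = permutations,
                        seed = if (is.null(seed)) NULL else seed + 500)
          else NULL
          list(matrix = cm, dendrogram = dend, anosim = an,
               mean_bray_curtis = mean_dissimilarity(raw_bc))
        }, error = function(e) NULL)
        out[[paste(o, agg, sep = ".")]] <- res
      }
    }
    out
  })

  result <- structure(list(
    qc = qc, partition = partition, motus = motus,
    richness = richness$report, curves = richness$curves,
    family_report = family_report, checklist = checklist,
    community = community,
    params = list(threshold = threshold, thresholds = thresholds,
                  iterations = iterations, permutations = permutations,
                  slope_window = slope_window,
                  min_specimens = min_specimens, min_motus = min_motus,
                  community_year = community_year,
                  community_transform = community_transform,
                  seed = seed)),
    class = "barcode_survey")

  if (!is.null(outdir)) {
    stage("report", write_survey_reports(result, outdir))
    return(invisible(result))
  }
  result
}

# ---- report writing ----------------------------------------------------

.fmt1 <- function(x) sprintf("%.1f", x)
.fmt3 <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))

#' Write the report bundle of a survey
#'
#' Emits the delimited reports and Newick dendrograms for a fitted
#' survey, rounding as conventional in printed survey tables (success
#' rates to 1 decimal place, slopes to 3, Chao estimates to integers),
#' plus a manifest of MD5 checksums over all outputs.
#'
#' @param x a [barcode_survey()] result.
#' @param outdir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_survey_reports <- function(x, outdir) {
  stopifnot(inherits(x, "barcode_survey"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  wt <- function(df, name) {
    p <- file.path(outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }

  sg <- merge(x$qc$success$per_group, x$qc$grades_per_order,
              by = "group", all.x = TRUE)
  sg$bin_grade[is.na(sg$bin_grade)] <- 0L
  sg$motu_grade[is.na(sg$motu_grade)] <- 0L
  qc_df <- data.frame(order = sg$group, attempted = sg$attempted,
                      recovered = sg$recovered,
                      bin_grade = sg$bin_grade, motu_grade = sg$motu_grade,
                      success_pct = .fmt1(100 * sg$rate))
  tot <- x$qc$success
  qc_df <- rbind(qc_df, data.frame(order = "Total", attempted = tot$attempted,
                                   recovered = tot$recovered,
                                   bin_grade = x$qc$n_bin_grade,
                                   motu_grade = x$qc$n_motu_grade,
                                   success_pct = .fmt1(100 * tot$rate)))
  wt(qc_df, "qc_report.tsv")

  asn <- data.frame(specimen_id = names(x$partition$assignment),
                    motu = unname(x$partition$assignment))
  asn$motu_size <- x$partition$sizes[asn$motu]
  wt(asn, "motu_assignments.tsv")

  rr <- x$richness
  wt(data.frame(group = rr$group, motus = rr$motus, n = rr$n,
                chao = round_half_up(rr$chao),
                chao_se = round_half_up(rr$chao_se),
                slope = .fmt3(rr$slope), category = rr$category,
                n_families = rr$n_families),
     "richness_report.tsv")

  curves <- do.call(rbind, lapply(names(x$curves), function(g) {
    cv <- x$curves[[g]]$curve
    data.frame(group = g, n = cv$n, mean_S = round(cv$mean_S, 4),
               sd_S = round(cv$sd_S, 4))
  }))
  wt(curves, "accumulation_curves.tsv")

  fr <- x$family_report
  wt(data.frame(order = fr$order, group = fr$group, motus = fr$motus,
                n = fr$n, slope = .fmt3(fr$slope), category = fr$category),
     "family_report.tsv")

  if (!is.null(x$checklist)) wt(x$checklist, "checklist_comparison.tsv")

  an_rows <- list(); md_rows <- list()
  for (key in names(x$community)) {
    cs <- x$community[[key]]
    if (is.null(cs)) next
    ok <- strsplit(key, ".", fixed = TRUE)[[1]]
    p <- file.path(outdir, paste0("dendrogram_", ok[1], "_", ok[2], ".nwk"))
    write_newick(cs$dendrogram, p)
    paths[[basename(p)]] <- p
    md_rows[[key]] <- data.frame(order = ok[1], aggregation = ok[2],
                                 mean_bray_curtis = .fmt3(cs$mean_bray_curtis))
    if (!is.null(cs$anosim))
      an_rows[[key]] <- data.frame(order = ok[1], aggregation = ok[2],
                                   R = .fmt3(cs$anosim$R),
                                   p = signif(cs$anosim$p, 3),
                                   n_permutations = cs$anosim$n_permutations,
                                   seed = if (is.null(cs$anosim$seed)) NA
                                          else cs$anosim$seed)
  }
  if (length(an_rows)) wt(do.call(rbind, an_rows), "anosim_report.tsv")
  if (length(md_rows)) wt(do.call(rbind, md_rows), "mean_dissimilarity.tsv")

  cfg <- x$params
  cfg_lines <- vapply(names(cfg), function(nm)
    paste0(nm, ": ", paste(utils::capture.output(utils::str(cfg[[nm]], give.head = FALSE)),
                           collapse = " ")), "")
  p <- file.path(outdir, "config.txt")
  writeLines(cfg_lines, p)
  paths[["config.txt"]] <- p

  mf <- data.frame(file = names(paths),
                   md5 = unname(tools::md5sum(unlist(paths))))
  utils::write.table(mf, file.path(outdir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(unlist(paths))
}

#' @export
print.barcode_survey <- function(x, ...) {
  cat("DNA-barcode biodiversity survey\n")
  cat(sprintf("  sequencing success: %d / %d specimens (%.1f%%)\n",
              x$qc$success$recovered, x$qc$success$attempted,
              100 * x$qc$success$rate))
  cat(sprintf("  analysis-grade barcodes: %d (reference-grade: %d)\n",
              x$qc$n_motu_grade, x$qc$n_bin_grade))
  tot <- x$richness[x$richness$group == "Total", ]
  cat(sprintf("  MOTUs at threshold %d: %d from %d specimens\n",
              x$params$threshold, tot$motus, tot$n))
  cat(sprintf("  Chao1 richness: %.0f (+/- %.0f SE); terminal slope %s\n",
              tot$chao, tot$chao_se, .fmt3(tot$slope)))
  invisible(x)
}

#' @export
summary.barcode_survey <- function(object, ...) {
  cat("Richness by order:\n")
  rr <- object$richness
  rr$chao <- sprintf("%.0f (+/-%.0f)", rr$chao, rr$chao_se)
  rr$chao_se <- NULL
  rr$slope <- .fmt3(rr$slope)
  print(rr, row.names = FALSE)
  if (!is.null(object$checklist)) {
    cat("\nChecklist comparison:\n")
    print(object$checklist, row.names = FALSE)
  }
  an <- Filter(Negate(is.null),
               lapply(object$community, function(cs) cs$anosim))
  if (length(an)) {
    cat("\nANOSIM (forested vs non-forested):\n")
    for (k in names(an))
      cat(sprintf("  %s: R = %.3f, p = %.3g\n",
                  sub("\\.site$", "", k), an[[k]]$R, an[[k]]$p))
  }
  invisible(object)
}

#' @export
plot.barcode_survey <- function(x, ...) {
  cu <- x$curves
  cols <- seq_along(cu)
  xmax <- max(vapply(cu, function(c) c$N, numeric(1)))
  ymax <- max(vapply(cu, function(c) c$S_obs, numeric(1)))
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, ymax),
                 xlab = "Specimens", ylab = "MOTUs",
                 main = "MOTU accumulation", ...)
  for (i in seq_along(cu))
    graphics::lines(cu[[i]]$curve$n, cu[[i]]$curve$mean_S, col = cols[i])
  graphics::legend("bottomright", legend = names(cu), col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}

#' Compare a core survey against an augmented survey
#'
#' Quantifies the richness added by supplementary (e.g. qualitative)
#' sampling: per order and in total, the additional MOTUs and percent
#' increase over the core survey, and the same accounting for the Chao1
#' projections. Chao increases are computed as the difference of the two
#' surveys' estimates (an interpretation: pooled re-estimation is the
#' alternative reading). Both surveys must have used the same threshold
#' and QC settings.
#'
#' @param core,augmented [barcode_survey()] results.
#' @return data frame of class `survey_comparison` with columns `group`,
#'   `additional_motus`, `pct_increase`, `additional_chao`,
#'   `pct_increase_chao`.
#' @export
compare_surveys <- function(core, augmented) {
  stopifnot(inherits(core, "barcode_survey"),
            inherits(augmented, "barcode_survey"))
  if (core$params$threshold != augmented$params$threshold ||
      !identical(core$params$thresholds, augmented$params$thresholds))
    stop("surveys used different threshold or QC settings; ",
         "re-run one of them before comparing")
  groups <- union(core$richness$group, augmented$richness$group)
  rows <- lapply(groups, function(g) {
    rc <- core$richness[core$richness$group == g, ]
    ra <- augmented$richness[augmented$richness$group == g, ]
    s_core <- if (nrow(rc)) rc$motus else 0L
    s_aug <- if (nrow(ra)) ra$motus else 0L
    c_core <- if (nrow(rc)) rc$chao else 0
    c_aug <- if (nrow(ra)) ra$chao else 0
    ri <- richness_increase(s_core, max(s_core, s_aug))
    ci <- richness_increase(c_core, max(c_core, c_aug))
    data.frame(group = g,
               core_motus = s_core, augmented_motus = s_aug,
               additional_motus = ri$additional,
               pct_increase = ri$percent_increase,
               additional_chao = round_half_up(ci$additional),
               pct_increase_chao = ci$percent_increase,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("survey_comparison", "data.frame")
  out
}
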