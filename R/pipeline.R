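#' Run the full mock-community evaluation
#'
#' Drives the filtering and evaluation stages end to end for a two-marker
#' mock experiment: negative-control thresholds on the raw counts,
#' conversion to proportions, optional restriction to the design taxa
#' (reads of off-design taxa are dropped, as airborne contamination),
#' per-marker proportion thresholds with renormalization, the two-marker
#' median consensus with its own threshold, detection classification and
#' calibration fits per marker and for the median, and the marker
#' reliability ranking.
#'
#' @param rbcl,trnl [count_table()]s over the same samples.
#' @param design A [mixture_design()].
#' @param nc_rbcl,nc_trnl Optional negative-control count tables.
#' @param config A [filter_config()].
#' @param restrict_to_design Drop taxa not compatible with any design taxon
#'   before thresholding (default TRUE, the mock-analysis convention).
#' @param out_dir Optional directory; when given, detection summaries,
#'   calibration tables and the marker ranking are written there as TSV.
#' @return A list with `proportions` (raw, per marker), `filtered` (per
#'   marker + median), `detections` (per marker + median), `fits`,
#'   `ranking` and `config`.
#' @export
run_mock_eval <- function(rbcl, trnl, design, nc_rbcl = NULL,
                          nc_trnl = NULL, config = filter_config(),
                          restrict_to_design = TRUE, out_dir = NULL) {
  stopifnot(inherits(config, "filter_config"))
  if (config$nc_mode == "per_taxon_count") {
    rbcl <- apply_negative_control(rbcl, nc_rbcl)
    trnl <- apply_negative_control(trnl, nc_trnl)
  }
  if (restrict_to_design) {
    rbcl <- restrict_counts(rbcl, design)
    trnl <- restrict_counts(trnl, design)
  }
  props <- list(rbcL = to_proportions(rbcl), trnL = to_proportions(trnl))
  filtered <- list(
    rbcL = threshold_and_renormalize(props$rbcL, config$theta_marker),
    trnL = threshold_and_renormalize(props$trnL, config$theta_marker)
  )
  med <- median_consensus(props$rbcL, props$trnL, config$theta_median)
  detections <- list(
    rbcL = classify_detections(filtered$rbcL, design),
    trnL = classify_detections(filtered$trnL, design),
    median = classify_detections(med, design)
  )
  fits <- list(
    rbcL = fit_calibration(apply_flags(props$rbcL, filtered$rbcL), design),
    trnL = fit_calibration(apply_flags(props$trnL, filtered$trnL), design),
    median = fit_calibration(med, design)
  )
  ranking <- compare_markers(fits)
  out <- list(proportions = props,
              filtered = c(filtered, list(median = med)),
              detections = detections, fits = fits, ranking = ranking,
              config = config)
  if (!is.null(out_dir)) write_mock_outputs(out, out_dir)
  out
}

# Keep only count columns compatible with some design taxon (mock analysis
# removes off-design reads before thresholding).
restrict_counts <- function(counts, design) {
  des <- unique(as.data.frame(design)[c("family", "genus")])
  keep <- vapply(counts$taxa, function(lab) {
    any(vapply(seq_len(nrow(des)), function(i) {
      matches_design(lab, des$family[i], des$genus[i])
    }, logical(1)))
  }, logical(1))
  if (all(keep)) return(counts)
  count_table(counts$counts[, keep, drop = FALSE], counts$marker,
              taxa = counts$taxa[keep])
}

# Carry removal flags from a filtered table back onto the raw-proportion
# values (the calibration consumes raw proportions plus flags).
apply_flags <- function(raw, filtered) {
  proportion_table(raw$values, raw$marker, removed = filtered$removed,
                   taxa = raw$taxa)
}

write_mock_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (mk in names(res$detections)) {
    utils::write.table(
      res$detections[[mk]]$summary,
      file.path(out_dir, sprintf("detections_%s.tsv", mk)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  fits <- do.call(rbind, lapply(names(res$fits), function(mk) {
    cbind(marker = mk, summary(res$fits[[mk]]))
  }))
  utils::write.table(fits, file.path(out_dir, "calibration_fits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$ranking, file.path(out_dir, "marker_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (mk in names(res$filtered)) {
    write_proportion_table(
      res$filtered[[mk]],
      file.path(out_dir, sprintf("filtered_%s.tsv", mk)))
  }
  invisible(out_dir)
}

#' Run the nest-composition community analysis
#'
#' Applies the proportion threshold to a genus-level nest count table and
#' computes the community statistics: per-nest diversity records (richness,
#' Shannon log2, Chao1), Mann-Whitney comparisons of richness and diversity
#' between wasp species (and between localities within a species when both
#' are present), the pairwise Spearman correlation matrix, correspondence
#' analysis, the Euclidean-distance dendrogram (Newick), per-species
#' rarefaction curves, the bipartite species-by-plant summary, and - when
#' vegetation areas or a landscape flora survey are available - the
#' landscape regressions.
#'
#' @param counts A genus-level [count_table()], nests in rows.
#' @param metadata Data frame with columns `nest_id`, `wasp_species`,
#'   `locality` and optionally `vegetation_area`, aligned with the count
#'   rows by `nest_id`.
#' @param flora Optional nest-by-genus landscape survey count matrix.
#' @param config A [filter_config()] (only `theta_marker` is used).
#' @param out_dir Optional output directory for TSV/Newick artifacts.
#' @return A list with `proportions` (filtered matrix), `diversity`,
#'   `tests`, `spearman`, `ca`, `dendrogram`, `rarefaction`, `bipartite`
#'   and `regressions`.
#' @export
run_nest_analysis <- function(counts, metadata, flora = NULL,
                              config = filter_config(), out_dir = NULL) {
  stopifnot(inherits(counts, "count_table"))
  need <- c("nest_id", "wasp_species", "locality")
  stopifnot(all(need %in% names(metadata)))
  metadata <- metadata[match(rownames(counts$counts), metadata$nest_id), ]
  if (any(is.na(metadata$nest_id))) {
    stop("run_nest_analysis: metadata missing for some nests", call. = FALSE)
  }
  filtered <- threshold_and_renormalize(to_proportions(counts),
                                        config$theta_marker)
  m <- retained_values(filtered)
  m[is.na(m)] <- 0
  m <- m[, colSums(m) > 0, drop = FALSE]

  diversity <- do.call(rbind, lapply(rownames(m), function(id) {
    counts_i <- counts$counts[id, colnames(m)]
    counts_i[m[id, ] == 0] <- 0  # threshold-removed taxa do not count
    rec <- data.frame(nest_id = id,
                      s_obs = sum(m[id, ] > 0),
                      shannon = shannon(m[id, ][m[id, ] > 0]))
    rec$chao1 <- chao1(round(counts_i))$chao1
    rec
  }))
  diversity <- merge(diversity, metadata, by = "nest_id", sort = FALSE)

  tests <- list()
  sp <- unique(metadata$wasp_species)
  if (length(sp) == 2 && nrow(m) >= 2) {
    a <- diversity$wasp_species == sp[1]
    tests$richness_by_species <-
      mann_whitney(diversity$s_obs[a], diversity$s_obs[!a])
    tests$shannon_by_species <-
      mann_whitney(diversity$shannon[a], diversity$shannon[!a])
  }
  for (s in sp) {
    sub <- diversity[diversity$wasp_species == s, ]
    locs <- unique(sub$locality)
    if (length(locs) == 2) {
      a <- sub$locality == locs[1]
      tests[[paste0("richness_by_locality_", s)]] <-
        mann_whitney(sub$s_obs[a], sub$s_obs[!a])
      tests[[paste0("shannon_by_locality_", s)]] <-
        mann_whitney(sub$shannon[a], sub$shannon[!a])
    }
  }

  comparative <- nrow(m) >= 2
  if (!comparative) {
    warning("run_nest_analysis: fewer than 2 nests; only diversity computed",
            call. = FALSE)
  }
  res <- list(
    proportions = m,
    diversity = diversity,
    tests = tests,
    spearman = if (comparative) spearman_matrix(m),
    ca = if (comparative) correspondence_analysis(m),
    dendrogram = if (comparative) hierarchical_dendrogram(m),
    rarefaction = if (comparative) {
      out <- lapply(sp, function(s) {
        rows <- metadata$wasp_species == s
        if (sum(rows) >= 1) rarefaction_curve(m[rows, , drop = FALSE] > 0)
      })
      names(out) <- sp
      out
    },
    bipartite = if (comparative) bipartite_summary(m, metadata$wasp_species),
    config = config
  )
  regressions <- list()
  if ("vegetation_area" %in% names(metadata) && nrow(m) >= 3) {
    regressions$richness_vs_area <-
      landscape_regression(diversity$s_obs, diversity$vegetation_area)
    regressions$shannon_vs_area <-
      landscape_regression(diversity$shannon, diversity$vegetation_area)
  }
  if (!is.null(flora)) {
    flora <- flora[match(rownames(m), rownames(flora)), , drop = FALSE]
    land_div <- do.call(rbind, lapply(seq_len(nrow(flora)), function(i) {
      landscape_diversity(flora[i, ])
    }))
    res$landscape_diversity <- cbind(nest_id = rownames(m), land_div)
    if (nrow(m) >= 3) {
      regressions$shannon_vs_landscape_shannon <-
        landscape_regression(diversity$shannon, land_div$shannon)
      regressions$richness_vs_landscape_chao1 <-
        landscape_regression(diversity$s_obs, land_div$chao1)
    }
  }
  res$regressions <- regressions
  if (!is.null(out_dir)) write_nest_outputs(res, out_dir)
  res
}

write_nest_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE)
  wt(data.frame(nest_id = rownames(res$proportions), res$proportions,
                check.names = FALSE), "composition.tsv")
  wt(res$diversity, "diversity.tsv")
  if (!is.null(res$spearman)) {
    wt(data.frame(nest_id = rownames(res$spearman$rho), res$spearman$rho,
                  check.names = FALSE), "spearman_rho.tsv")
    wt(data.frame(nest_id = rownames(res$spearman$p), res$spearman$p,
                  check.names = FALSE), "spearman_p.tsv")
  }
  if (!is.null(res$ca)) {
    wt(data.frame(id = rownames(res$ca$row_coords), res$ca$row_coords,
                  check.names = FALSE), "ca_rows.tsv")
    wt(data.frame(id = rownames(res$ca$col_coords), res$ca$col_coords,
                  check.names = FALSE), "ca_cols.tsv")
  }
  if (!is.null(res$dendrogram)) {
    writeLines(res$dendrogram$newick, file.path(out_dir, "dendrogram.nwk"))
  }
  if (!is.null(res$rarefaction)) {
    rar <- do.call(rbind, lapply(names(res$rarefaction), function(g) {
      if (is.null(res$rarefaction[[g]])) return(NULL)
      cbind(group = g, res$rarefaction[[g]])
    }))
    wt(rar, "rarefaction.tsv")
  }
  if (length(res$regressions)) {
    wt(do.call(rbind, lapply(names(res$regressions), function(nm) {
      r <- res$regressions[[nm]]
      data.frame(regression = nm, slope = r$slope, intercept = r$intercept,
                 r_squared = r$r_squared, p_value = r$p_value)
    })), "regressions.tsv")
  }
  invisible(out_dir)
}
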