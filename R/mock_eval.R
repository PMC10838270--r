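# Match a retained table label to a design species: families must agree and
# the label must either be family-rank or share the design genus. A wrong
# congeneric species (e.g. Prunus mume called for Prunus salicina) still
# counts as detecting the design taxon, as does a family-rank call.
matches_design <- function(label, family, genus) {
  label$family == family && (label$rank == "family" || label$genus == genus)
}

#' Classify detections against a known mixture design
#'
#' Partitions each sample's retained taxa into true detections and false
#' positives, and the design taxa into detected and false negatives. A
#' design species counts as detected when at least one retained label is
#' compatible with it at genus level or above (same family and either a
#' family-rank call or the same genus).
#'
#' @param filtered A [proportion_table()] produced by the filtering step.
#' @param design A [mixture_design()]; every design sample must be present
#'   in the table.
#' @return An object of class `detection_report`: a list with `marker`,
#'   `per_sample` (named list with `detected`, `false_negatives`,
#'   `false_positives` character vectors) and `summary` (data frame with
#'   per-sample counts).
#' @export
classify_detections <- function(filtered, design) {
  stopifnot(inherits(filtered, "proportion_table"),
            inherits(design, "mixture_design"))
  samples <- design_samples(design)
  missing <- setdiff(samples, rownames(filtered$values))
  if (length(missing)) {
    stop("classify_detections: design sample(s) missing from table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  per_sample <- list()
  for (s in samples) {
    des <- design[design$sample == s, , drop = FALSE]
    vals <- filtered$values[s, ]
    keep <- !filtered$removed[s, ] & !is.na(vals) & vals > 0
    retained <- filtered$taxa[keep]
    det_mask <- vapply(seq_len(nrow(des)), function(i) {
      any(vapply(retained, matches_design, logical(1),
                 family = des$family[i], genus = des$genus[i]))
    }, logical(1))
    fp_mask <- vapply(retained, function(lab) {
      !any(vapply(seq_len(nrow(des)), function(i) {
        matches_design(lab, des$family[i], des$genus[i])
      }, logical(1)))
    }, logical(1))
    per_sample[[s]] <- list(
      detected = des$species[det_mask],
      false_negatives = des$species[!det_mask],
      false_positives = vapply(retained[fp_mask], function(l) l$name,
                               character(1))
    )
  }
  summary <- data.frame(
    sample = samples,
    n_design = vapply(samples, function(s)
      sum(design$sample == s), integer(1)),
    n_detected = vapply(per_sample, function(x)
      length(x$detected), integer(1)),
    n_false_negative = vapply(per_sample, function(x)
      length(x$false_negatives), integer(1)),
    n_false_positive = vapply(per_sample, function(x)
      length(x$false_positives), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(marker = filtered$marker, per_sample = per_sample,
                 summary = summary),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("<detection_report> marker=%s\n", x$marker))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Calibrate observed read proportions against true mixture proportions
#'
#' Fits the linear mixed-effects calibration
#' `observed = b0 + b1 * true + u_taxon + e` by REML, with a random
#' intercept per plant taxon pooled across mixtures. Observations are the
#' (sample, design taxon) cells of a filtered proportion table paired with
#' the design's true proportions; the observed side is renormalized over
#' retained cells per sample, while the true proportions are taken as given.
#' Removed cells either enter the fit as zero observations
#' (`removed = "zero"`, the default, matching how flagged cells are treated
#' in published calibrations of this design) or are excluded
#' (`removed = "exclude"`). When the mixed model cannot be fit (a single
#' taxon, or an error), the function falls back to ordinary least squares
#' with a warning and zero random-intercept variance.
#'
#' @param observed A [proportion_table()] on consensus-merged axes.
#' @param design A [mixture_design()].
#' @param removed `"zero"` or `"exclude"` (see above).
#' @param renormalize Renormalize retained observed values per sample
#'   before pairing (default TRUE).
#' @return An object of class `calibration_fit` with components
#'   `coefficients` (intercept, slope), `sigma_u2` (random-intercept
#'   variance), `sigma_e2` (residual variance), `r2_adjusted_ols` (adjusted
#'   R-squared of the OLS fit on the same pairs), `r2_marginal` (variance
#'   explained by the fixed effect alone), `r2_conditional`, `n`, `data`
#'   (the pairs), `model` and `method` (`"REML"` or `"OLS"`).
#' @seealso [compare_markers()], [classify_detections()]
#' @export
fit_calibration <- function(observed, design,
                            removed = c("zero", "exclude"),
                            renormalize = TRUE) {
  removed <- match.arg(removed)
  stopifnot(inherits(observed, "proportion_table"),
            inherits(design, "mixture_design"))
  pairs <- calibration_pairs(observed, design, removed, renormalize)
  if (nrow(pairs) < 3L) {
    stop("fit_calibration: need at least 3 observation pairs", call. = FALSE)
  }
  if (length(unique(pairs$taxon)) < 2L) {
    warning("fit_calibration: fewer than 2 taxa; falling back to OLS",
            call. = FALSE)
    return(calibration_from_ols(pairs))
  }
  fit <- tryCatch(
    suppressMessages(lme4::lmer(obs ~ true + (1 | taxon), data = pairs,
                                REML = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("fit_calibration: mixed model failed; falling back to OLS",
            call. = FALSE)
    return(calibration_from_ols(pairs))
  }
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vc$vcov[vc$grp == "taxon"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  ols <- stats::lm(obs ~ true, data = pairs)
  var_fixed <- stats::var(fe[[1]] + fe[[2]] * pairs$true)
  denom <- var_fixed + sigma_u2 + sigma_e2
  structure(
    list(coefficients = c(intercept = unname(fe[1]), slope = unname(fe[2])),
         sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
         r2_adjusted_ols = summary(ols)$adj.r.squared,
         r2_marginal = var_fixed / denom,
         r2_conditional = (var_fixed + sigma_u2) / denom,
         n = nrow(pairs), marker = observed$marker, data = pairs,
         model = fit, method = "REML"),
    class = "calibration_fit"
  )
}

# Build (sample, taxon, true, obs) pairs for the calibration.
calibration_pairs <- function(observed, design, removed, renormalize) {
  v <- observed$values
  rm <- observed$removed
  if (renormalize) {
    for (i in seq_len(nrow(v))) {
      keep <- !rm[i, ] & !is.na(v[i, ])
      total <- sum(v[i, keep])
      if (total > 0) v[i, keep] <- v[i, keep] / total
    }
  }
  rows <- lapply(seq_len(nrow(design)), function(i) {
    s <- design$sample[i]
    if (!s %in% rownames(v)) {
      stop("fit_calibration: design sample missing from table: ", s,
           call. = FALSE)
    }
    compat <- vapply(observed$taxa, matches_design, logical(1),
                     family = design$family[i], genus = design$genus[i])
    cols <- which(compat)
    ret <- cols[!rm[s, cols] & !is.na(v[s, cols])]
    if (length(ret)) {
      obs <- sum(v[s, ret])
    } else if (removed == "zero") {
      obs <- 0
    } else {
      return(NULL)
    }
    data.frame(sample = s, taxon = design$species[i],
               true = design$true[i], obs = obs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

calibration_from_ols <- function(pairs) {
  ols <- stats::lm(obs ~ true, data = pairs)
  co <- stats::coef(ols)
  s <- summary(ols)
  var_fixed <- stats::var(stats::fitted(ols))
  sigma_e2 <- s$sigma^2
  structure(
    list(coefficients = c(intercept = unname(co[1]), slope = unname(co[2])),
         sigma_u2 = 0, sigma_e2 = sigma_e2,
         r2_adjusted_ols = s$adj.r.squared,
         r2_marginal = var_fixed / (var_fixed + sigma_e2),
         r2_conditional = var_fixed / (var_fixed + sigma_e2),
         n = nrow(pairs), marker = NA_character_, data = pairs,
         model = ols, method = "OLS"),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<calibration_fit> %s, n=%d pairs (%d taxa)\n",
              x$method, x$n, length(unique(x$data$taxon))))
  cat(sprintf("  observed = %s + %s * true\n",
              format(x$coefficients[["intercept"]], digits = digits),
              format(x$coefficients[["slope"]], digits = digits)))
  cat(sprintf("  sigma_u2=%s sigma_e2=%s | R2(adj OLS)=%s R2(marginal)=%s\n",
              format(x$sigma_u2, digits = digits),
              format(x$sigma_e2, digits = digits),
              format(x$r2_adjusted_ols, digits = digits),
              format(x$r2_marginal, digits = digits)))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) object$coefficients

#' @export
summary.calibration_fit <- function(object, ...) {
  data.frame(
    method = object$method,
    intercept = object$coefficients[["intercept"]],
    slope = object$coefficients[["slope"]],
    sigma_u2 = object$sigma_u2,
    sigma_e2 = object$sigma_e2,
    r2_adjusted_ols = object$r2_adjusted_ols,
    r2_marginal = object$r2_marginal,
    r2_conditional = object$r2_conditional,
    n = object$n,
    row.names = NULL
  )
}

#' @export
predict.calibration_fit <- function(object, newdata = NULL, ...) {
  true <- if (is.null(newdata)) object$data$true else newdata$true
  object$coefficients[["intercept"]] + object$coefficients[["slope"]] * true
}

#' @export
residuals.calibration_fit <- function(object, ...) {
  object$data$obs - stats::predict(object)
}

#' Rank markers by quantitative reliability
#'
#' Orders a set of calibration fits by how close their slope is to the
#' ideal of 1 (smaller `|slope - 1|` first); ties are broken by higher
#' adjusted OLS R-squared, then by input order.
#'
#' @param fits Named list of [fit_calibration()] results (names are marker
#'   labels).
#' @return A data frame, one row per marker, in reliability order.
#' @export
compare_markers <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L, !is.null(names(fits)))
  df <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(marker = nm,
               slope = f$coefficients[["slope"]],
               intercept = f$coefficients[["intercept"]],
               abs_slope_error = abs(f$coefficients[["slope"]] - 1),
               r2_adjusted_ols = f$r2_adjusted_ols,
               r2_marginal = f$r2_marginal,
               stringsAsFactors = FALSE)
  }))
  ord <- order(df$abs_slope_error, -df$r2_adjusted_ols,
               seq_len(nrow(df)))
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
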