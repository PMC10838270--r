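#' Filtering configuration
#'
#' Thresholds of the sequence-count removal procedure: a per-marker
#' proportion threshold (default 0.01) applied to each marker's proportion
#' table, a lower threshold (default 0.0025) applied to the two-marker
#' median consensus, and the negative-control mode.
#'
#' @param theta_marker Per-marker proportion threshold in \[0, 1).
#' @param theta_median Median-consensus threshold; must not exceed
#'   `theta_marker`.
#' @param nc_mode `"per_taxon_count"` (each taxon's negative-control read
#'   count is a removal threshold for that taxon) or `"off"`.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(theta_marker = 0.01, theta_median = 0.0025,
                          nc_mode = c("per_taxon_count", "off")) {
  nc_mode <- match.arg(nc_mode)
  if (!(theta_median >= 0 && theta_median <= theta_marker &&
        theta_marker < 1)) {
    stop("filter_config: need 0 <= theta_median <= theta_marker < 1",
         call. = FALSE)
  }
  structure(list(theta_marker = theta_marker, theta_median = theta_median,
                 nc_mode = nc_mode),
            class = "filter_config")
}

#' @export
print.filter_config <- function(x, ...) {
  cat(sprintf("<filter_config> theta_marker=%g, theta_median=%g, nc=%s\n",
              x$theta_marker, x$theta_median, x$nc_mode))
  invisible(x)
}

# Internal: matching key for taxa across tables - most specific name plus
# family, so a family-rank label and a congeneric species stay distinct.
taxon_keys <- function(taxa) {
  vapply(taxa, function(t) paste(t$family, t$name, sep = "\r"), character(1))
}

#' Apply per-taxon negative-control removal thresholds
#'
#' The read count of each taxon in the no-template negative control is used
#' as a removal threshold: a sample cell whose count is less than or equal
#' to the control's count for that taxon is zeroed (the reads are deemed
#' indistinguishable from contamination). Taxa absent from the control are
#' untouched; an empty control (a control that yielded no reads) leaves the
#' table unchanged.
#'
#' @param counts A [count_table()].
#' @param nc A `count_table` with exactly one sample, same marker.
#' @return A `count_table` with thresholded counts.
#' @export
apply_negative_control <- function(counts, nc) {
  stopifnot(inherits(counts, "count_table"))
  if (is.null(nc)) return(counts)
  stopifnot(inherits(nc, "count_table"))
  if (nc$marker != counts$marker) {
    stop(sprintf("apply_negative_control: marker mismatch (%s vs %s)",
                 counts$marker, nc$marker), call. = FALSE)
  }
  if (nrow(nc$counts) != 1L) {
    stop("apply_negative_control: negative control must hold one sample",
         call. = FALSE)
  }
  nc_counts <- nc$counts[1, ]
  nc_counts <- nc_counts[nc_counts > 0]
  if (!length(nc_counts)) return(counts)
  keys <- taxon_keys(counts$taxa)
  nc_keys <- taxon_keys(nc$taxa)[nc$counts[1, ] > 0]
  m <- counts$counts
  for (j in seq_along(keys)) {
    i <- match(keys[j], nc_keys)
    if (!is.na(i)) {
      m[, j] <- ifelse(m[, j] <= nc_counts[i], 0, m[, j])
    }
  }
  count_table(m, counts$marker, counts$taxa)
}

#' Convert read counts to within-sample proportions
#'
#' Each sample's counts are divided by its total; samples with no reads are
#' flagged empty (their values stay 0).
#'
#' @param counts A [count_table()].
#' @return A [proportion_table()] whose non-empty rows sum to 1.
#' @export
to_proportions <- function(counts) {
  stopifnot(inherits(counts, "count_table"))
  totals <- rowSums(counts$counts)
  v <- counts$counts / ifelse(totals > 0, totals, 1)
  proportion_table(v, counts$marker, taxa = counts$taxa)
}

#' Remove low-proportion cells and renormalize
#'
#' Retained cells with value below `theta` are flagged removed and zeroed;
#' the remaining cells of each sample are renormalized to sum to 1. Already
#' removed cells stay removed, which makes the operation idempotent at a
#' fixed threshold. A sample losing all its cells is flagged empty with a
#' warning.
#'
#' @param props A [proportion_table()].
#' @param theta Proportion threshold in \[0, 1).
#' @return A `proportion_table`.
#' @export
threshold_and_renormalize <- function(props, theta) {
  stopifnot(inherits(props, "proportion_table"), theta >= 0, theta < 1)
  v <- props$values
  removed <- props$removed | (!is.na(v) & v < theta)
  v[removed & !is.na(v)] <- 0
  newly_empty <- character()
  for (i in seq_len(nrow(v))) {
    keep <- !removed[i, ] & !is.na(v[i, ])
    total <- sum(v[i, keep])
    if (total > 0) {
      v[i, keep] <- v[i, keep] / total
    } else if (!props$empty[i]) {
      newly_empty <- c(newly_empty, rownames(v)[i])
    }
  }
  if (length(newly_empty)) {
    warning("threshold_and_renormalize: all taxa removed in sample(s) ",
            paste(newly_empty, collapse = ", "), call. = FALSE)
  }
  proportion_table(v, props$marker, removed = removed, taxa = props$taxa)
}

#' Two-marker median-proportion consensus
#'
#' For taxa detected with both markers (nonzero raw proportion in each,
#' before any proportion threshold), the consensus value is the arithmetic
#' mean of the two markers' proportions, `(A + B) / 2`. Taxa detected by
#' only one marker are absent (`NA`). Consensus values below `theta_median`
#' are then flagged removed but keep their computed value (the convention
#' of printed consensus tables, where a removed cell shows its value with a
#' `(0)` mark). A cell counts as detected when its value is positive or
#' when it carries a removal flag with a stored value - tables transcribed
#' at fixed precision can hold detected cells whose proportion rounds to
#' zero. By default the surviving values are NOT renormalized: the
#' consensus is reported on the scale of the per-marker proportions,
#' mirroring how such tables are printed; set `renormalize = TRUE` to
#' rescale retained cells per sample.
#'
#' @param props_rbcl,props_trnl [proportion_table()]s over the same samples
#'   and the same consensus-merged taxon axes (see [consensus_label()]).
#' @param theta_median Removal threshold for the consensus values.
#' @param renormalize Renormalize retained cells per sample (default FALSE).
#' @return A `proportion_table` with `marker = "median"`.
#' @export
median_consensus <- function(props_rbcl, props_trnl, theta_median = 0.0025,
                             renormalize = FALSE) {
  stopifnot(inherits(props_rbcl, "proportion_table"),
            inherits(props_trnl, "proportion_table"))
  if (!identical(rownames(props_rbcl$values), rownames(props_trnl$values))) {
    stop("median_consensus: tables must cover the same samples",
         call. = FALSE)
  }
  if (!identical(taxon_keys(props_rbcl$taxa), taxon_keys(props_trnl$taxa))) {
    stop("median_consensus: taxon axes differ; merge labels first",
         call. = FALSE)
  }
  a <- props_rbcl$values
  b <- props_trnl$values
  det_a <- !is.na(a) & (a > 0 | props_rbcl$removed)
  det_b <- !is.na(b) & (b > 0 | props_trnl$removed)
  both <- det_a & det_b
  v <- matrix(NA_real_, nrow(a), ncol(a), dimnames = dimnames(a))
  v[both] <- (a[both] + b[both]) / 2
  removed <- !both | v < theta_median
  removed[is.na(removed)] <- TRUE
  out <- proportion_table(v, "median", removed = removed,
                          taxa = props_rbcl$taxa)
  if (renormalize) out <- threshold_and_renormalize(out, 0)
  out
}
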