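#' Per-marker read-count table
#'
#' Samples-by-taxa matrix of non-negative integer read counts for one
#' chloroplast marker. Rows are samples, columns are taxa; the taxa carry
#' full labels (see [taxon_label()]) in the `taxa` element, aligned with the
#' matrix columns.
#'
#' @param counts Numeric matrix of non-negative integers with unique row
#'   (sample) and column (taxon) names.
#' @param marker `"rbcL"` or `"trnL"`.
#' @param taxa Optional list of `taxon_label`s, one per column; parsed from
#'   the column names with [parse_taxon()] when omitted.
#' @return An object of class `count_table`.
#' @export
count_table <- function(counts, marker = c("rbcL", "trnL"), taxa = NULL) {
  marker <- match.arg(marker)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count_table: counts must have sample row names and taxon column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("count_table: duplicate sample ids", call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("count_table: counts must be non-negative and non-missing",
         call. = FALSE)
  }
  if (any(counts != round(counts))) {
    stop("count_table: counts must be integers", call. = FALSE)
  }
  if (is.null(taxa)) taxa <- lapply(colnames(counts), parse_taxon)
  stopifnot(length(taxa) == ncol(counts))
  colnames(counts) <- vapply(taxa, function(t) t$name, character(1))
  if (anyDuplicated(colnames(counts))) {
    stop("count_table: duplicate taxon columns", call. = FALSE)
  }
  structure(
    list(marker = marker, counts = counts, taxa = taxa),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> marker=%s, %d samples x %d taxa, %s reads\n",
              x$marker, nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_table <- function(x) dim(x$counts)

#' Per-marker proportion table with removal flags
#'
#' Same axes as a [count_table()] but holding real values in \[0, 1\] plus a
#' per-cell `removed` flag and a per-sample `empty` flag. `NA` values mark
#' cells that are absent from the table (for example taxa never detected in
#' a sample); removed cells keep their pre-removal value of 0 after
#' filtering. After renormalization the retained values of a non-empty
#' sample sum to 1 within 1e-9.
#'
#' @param values Numeric matrix in \[0,1\] (or `NA`) with sample row names
#'   and taxon column names.
#' @param marker `"rbcL"`, `"trnL"`, or `"median"` for the two-marker
#'   consensus table.
#' @param removed Logical matrix of the same shape; defaults to all-FALSE
#'   (with `NA` cells marked removed).
#' @param taxa As in [count_table()].
#' @return An object of class `proportion_table` with elements `marker`,
#'   `values`, `removed`, `empty` (logical per sample) and `taxa`.
#' @export
proportion_table <- function(values, marker = c("rbcL", "trnL", "median"),
                             removed = NULL, taxa = NULL) {
  marker <- match.arg(marker)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("proportion_table: values must have sample and taxon names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("proportion_table: duplicate sample ids", call. = FALSE)
  }
  if (any(values < -1e-12 | values > 1 + 1e-12, na.rm = TRUE)) {
    stop("proportion_table: values must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(removed)) {
    removed <- is.na(values)
  } else {
    removed <- as.matrix(removed)
    stopifnot(identical(dim(removed), dim(values)))
    removed <- removed | is.na(values)
  }
  dimnames(removed) <- dimnames(values)
  retained <- !removed & !is.na(values)
  empty <- rowSums(retained & values > 0, na.rm = TRUE) == 0
  if (is.null(taxa)) taxa <- lapply(colnames(values), parse_taxon)
  stopifnot(length(taxa) == ncol(values))
  colnames(values) <- vapply(taxa, function(t) t$name, character(1))
  colnames(removed) <- colnames(values)
  if (anyDuplicated(colnames(values))) {
    stop("proportion_table: duplicate taxon columns", call. = FALSE)
  }
  structure(
    list(marker = marker, values = values, removed = removed,
         empty = empty, taxa = taxa),
    class = "proportion_table"
  )
}

#' @export
print.proportion_table <- function(x, ...) {
  cat(sprintf(
    "<proportion_table> marker=%s, %d samples x %d taxa (%d cells removed, %d empty samples)\n",
    x$marker, nrow(x$values), ncol(x$values), sum(x$removed),
    sum(x$empty)))
  invisible(x)
}

#' @export
dim.proportion_table <- function(x) dim(x$values)

#' Retained values of a proportion table
#'
#' @param x A `proportion_table`.
#' @return The value matrix with removed and absent cells set to `NA`.
#' @export
retained_values <- function(x) {
  stopifnot(inherits(x, "proportion_table"))
  v <- x$values
  v[x$removed] <- NA_real_
  v
}

#' Known mixture design (true proportions)
#'
#' The composition of a set of mock samples: for each sample, the
#' species-level taxa it was assembled from and their true mass proportions.
#'
#' @param df Data frame with columns `sample`, `family`, `genus`, `species`
#'   and `true` (proportion in (0, 1\]).
#' @return An object of class `mixture_design`. A warning is issued for
#'   samples whose listed proportions do not sum to 1 (tolerance 1e-6);
#'   published designs occasionally contain such rounding slips and are kept
#'   as printed.
#' @export
mixture_design <- function(df) {
  needed <- c("sample", "family", "genus", "species", "true")
  if (!all(needed %in% names(df))) {
    stop("mixture_design: need columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$true <= 0 | df$true > 1)) {
    stop("mixture_design: true proportions must lie in (0, 1]", call. = FALSE)
  }
  if (anyDuplicated(df[c("sample", "species")])) {
    stop("mixture_design: duplicate (sample, species) rows", call. = FALSE)
  }
  sums <- tapply(df$true, df$sample, sum)
  off <- names(sums)[abs(sums - 1) > 1e-6]
  if (length(off)) {
    warning("mixture_design: true proportions do not sum to 1 in sample(s) ",
            paste(off, collapse = ", "), call. = FALSE)
  }
  df <- df[needed]
  rownames(df) <- NULL
  structure(df, class = c("mixture_design", "data.frame"))
}

#' @export
print.mixture_design <- function(x, ...) {
  cat(sprintf("<mixture_design> %d samples, %d taxa, %d cells\n",
              length(unique(x$sample)), length(unique(x$species)), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

# Internal: samples of a design, in order of first appearance.
design_samples <- function(design) unique(design$sample)
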