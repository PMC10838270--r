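#' Shannon-Wiener diversity (log base 2)
#'
#' `H = -sum(p_i * log2(p_i))` over the nonzero entries. Note the base-2
#' logarithm: many ecology packages default to the natural log, which gives
#' values smaller by a factor of `log(2)`. Counts are accepted and converted
#' to proportions.
#'
#' @param proportions Non-negative numeric vector (proportions or counts);
#'   zero entries are skipped.
#' @return H in bits; 0 for a single taxon, `log2(S)` for `S` equally
#'   abundant taxa.
#' @export
shannon <- function(proportions) {
  if (length(proportions) == 0L) {
    stop("shannon: empty abundance vector", call. = FALSE)
  }
  if (any(is.na(proportions)) || any(proportions < 0)) {
    stop("shannon: abundances must be non-negative and non-missing",
         call. = FALSE)
  }
  p <- proportions[proportions > 0]
  if (!length(p)) stop("shannon: all abundances are zero", call. = FALSE)
  p <- p / sum(p)
  -sum(p * log2(p))
}

#' Chao1 richness estimator
#'
#' `Chao1 = S_obs + a^2 / (2b)` where `a` is the number of taxa observed
#' exactly once (singletons) and `b` the number observed exactly twice
#' (doubletons). When there are no doubletons the bias-corrected form
#' `S_obs + a(a - 1) / (2(b + 1))` is used, since the classical formula is
#' undefined at `b = 0`.
#'
#' @param genus_counts Non-negative integer abundances.
#' @return A one-row data frame (class `diversity_record`) with columns
#'   `s_obs`, `singletons`, `doubletons`, `chao1`. Always `chao1 >= s_obs`.
#' @export
chao1 <- function(genus_counts) {
  if (any(is.na(genus_counts)) || any(genus_counts < 0) ||
      any(genus_counts != round(genus_counts))) {
    stop("chao1: counts must be non-negative integers", call. = FALSE)
  }
  s_obs <- sum(genus_counts > 0)
  a <- sum(genus_counts == 1)
  b <- sum(genus_counts == 2)
  est <- if (b > 0) s_obs + a^2 / (2 * b) else s_obs + a * (a - 1) / (2 * (b + 1))
  out <- data.frame(s_obs = s_obs, singletons = a, doubletons = b,
                    chao1 = est)
  class(out) <- c("diversity_record", "data.frame")
  out
}

#' Mann-Whitney U test (exact enumeration or normal approximation)
#'
#' The statistic follows the rank-sum-minus-offset convention,
#' `W = rank_sum(x) - n1 (n1 + 1) / 2`, so complete separation of `x` above
#' `y` gives `W = n1 * n2`. The exact two-sided p-value enumerates all
#' `choose(n1 + n2, n1)` label assignments and sums those at least as far
#' from `n1 n2 / 2` as observed; it is used when `n1 + n2 <= 12` and the
#' data are tie-free. Otherwise a normal approximation with tie-corrected
#' variance and continuity correction is used. Both p-values are reported
#' whenever the exact one is computable, since small published datasets are
#' often quoted with the approximate value.
#'
#' @param x,y Non-empty numeric samples.
#' @param method `"auto"` (default), `"exact"` or `"normal"`.
#' @return A list of class `mw_test`: `statistic` (W), `p.value`,
#'   `method`, and `p_exact` / `p_normal` where available.
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  exact_ok <- !ties && (n1 + n2) <= 12
  p_exact <- if (exact_ok || (method == "exact" && !ties)) {
    mw_exact_p(W, n1, n2)
  } else if (method == "exact" && ties) {
    # symmetric fallback under ties: enumeration on midranks
    mw_exact_p_ranks(r, n1, n2)
  } else {
    NA_real_
  }
  p_normal <- mw_normal_p(W, n1, n2, pooled)
  p <- switch(method,
    exact = p_exact,
    normal = p_normal,
    auto = if (exact_ok) p_exact else p_normal
  )
  structure(list(statistic = W, p.value = p,
                 method = if (method == "auto" && exact_ok) "exact"
                          else if (method == "auto") "normal" else method,
                 p_exact = p_exact, p_normal = p_normal,
                 n1 = n1, n2 = n2),
            class = "mw_test")
}

# Exact two-sided p by full enumeration over tie-free rank assignments.
mw_exact_p <- function(W, n1, n2) {
  combos <- utils::combn(n1 + n2, n1)
  Ws <- colSums(combos) - n1 * (n1 + 1) / 2
  mid <- n1 * n2 / 2
  mean(abs(Ws - mid) >= abs(W - mid) - 1e-9)
}

# Enumeration on the observed (mid)ranks, used for exact-with-ties requests.
mw_exact_p_ranks <- function(r, n1, n2) {
  combos <- utils::combn(n1 + n2, n1)
  offset <- n1 * (n1 + 1) / 2
  Ws <- apply(combos, 2, function(idx) sum(r[idx])) - offset
  W <- sum(r[seq_len(n1)]) - offset
  mid <- n1 * n2 / 2
  mean(abs(Ws - mid) >= abs(W - mid) - 1e-9)
}

# Normal approximation with tie-corrected variance and continuity correction.
mw_normal_p <- function(W, n1, n2, pooled) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(1)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(v)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' @export
print.mw_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U: W = %g (n1=%d, n2=%d), p = %.4g [%s]\n",
              x$statistic, x$n1, x$n2, x$p.value, x$method))
  if (!is.na(x$p_exact) && x$method != "exact") {
    cat(sprintf("  exact p = %.4g\n", x$p_exact))
  }
  if (x$method != "normal") {
    cat(sprintf("  normal-approximation p = %.4g\n", x$p_normal))
  }
  invisible(x)
}

#' Pairwise Spearman rank correlations between samples
#'
#' Rho is computed from Pearson correlation of midranks (equivalent to the
#' classical `1 - 6 sum(d^2) / (n(n^2-1))` formula for tie-free data);
#' p-values come from [stats::cor.test()] (exact for small tie-free vectors,
#' t-approximation otherwise). Samples must be aligned on the union taxon
#' set with absences coded 0. Constant rows yield `NA` with a warning.
#'
#' @param tables Numeric matrix, samples in rows, taxa in columns.
#' @return A list with symmetric matrices `rho` (unit diagonal) and `p`.
#' @export
spearman_matrix <- function(tables) {
  m <- as.matrix(tables)
  n <- nrow(m)
  ids <- rownames(m)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  rho <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  p <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  diag(rho) <- 1
  diag(p) <- 0
  constant <- apply(m, 1, function(x) stats::sd(x) == 0)
  if (any(constant)) {
    warning("spearman_matrix: constant composition in sample(s) ",
            paste(ids[constant], collapse = ", "),
            "; correlations undefined", call. = FALSE)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (constant[i] || constant[j]) next
      rho[i, j] <- rho[j, i] <-
        stats::cor(rank(m[i, ]), rank(m[j, ]))
      ct <- suppressWarnings(
        stats::cor.test(m[i, ], m[j, ], method = "spearman"))
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(rho = rho, p = p)
}

#' Correspondence analysis of a contingency table
#'
#' Classical CA: with correspondence matrix `P = X / N`, row and column
#' masses `r`, `c`, the standardized residuals
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` are decomposed by SVD and
#' principal coordinates are `D_r^{-1/2} U D` (rows) and `D_c^{-1/2} V D`
#' (columns). The total inertia `sum(d^2)` equals the table's chi-squared
#' statistic divided by `N`. Zero-margin rows or columns are dropped; a
#' table of exactly independent structure has zero inertia and no axes.
#'
#' @param table Non-negative matrix with a positive grand total.
#' @return A list of class `ca_result` with `row_coords`, `col_coords`
#'   (principal coordinates, axes in columns), `inertia` (per axis),
#'   `total_inertia` and `masses`.
#' @export
correspondence_analysis <- function(table) {
  x <- as.matrix(table)
  if (any(x < 0) || any(is.na(x))) {
    stop("correspondence_analysis: table must be non-negative", call. = FALSE)
  }
  N <- sum(x)
  if (N <= 0) {
    stop("correspondence_analysis: table total must be positive",
         call. = FALSE)
  }
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  P <- x / N
  r <- rowSums(P)
  cc <- colSums(P)
  S <- diag(1 / sqrt(r), nrow = length(r)) %*% (P - outer(r, cc)) %*%
    diag(1 / sqrt(cc), nrow = length(cc))
  sv <- svd(S)
  keep <- sv$d > 1e-10
  d <- sv$d[keep]
  if (!length(d)) {
    row_coords <- matrix(0, nrow(x), 0, dimnames = list(rownames(x), NULL))
    col_coords <- matrix(0, ncol(x), 0, dimnames = list(colnames(x), NULL))
    return(structure(list(row_coords = row_coords, col_coords = col_coords,
                          inertia = numeric(), total_inertia = 0,
                          masses = list(row = r, col = cc)),
                     class = "ca_result"))
  }
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  row_coords <- diag(1 / sqrt(r), nrow = length(r)) %*% U %*%
    diag(d, nrow = length(d))
  col_coords <- diag(1 / sqrt(cc), nrow = length(cc)) %*% V %*%
    diag(d, nrow = length(d))
  dimnames(row_coords) <- list(rownames(x), paste0("CA", seq_along(d)))
  dimnames(col_coords) <- list(colnames(x), paste0("CA", seq_along(d)))
  structure(list(row_coords = row_coords, col_coords = col_coords,
                 inertia = d^2, total_inertia = sum(d^2),
                 masses = list(row = r, col = cc)),
            class = "ca_result")
}

#' @export
print.ca_result <- function(x, ...) {
  cat(sprintf("<ca_result> %d x %d, %d axes, total inertia %.4g\n",
              nrow(x$row_coords), nrow(x$col_coords), length(x$inertia),
              x$total_inertia))
  invisible(x)
}

#' Euclidean-distance dendrogram of sample compositions
#'
#' Agglomerative clustering of the samples on Euclidean distances between
#' their composition (proportion) vectors, with the tree exported in Newick
#' format. The linkage is configurable (complete by default).
#'
#' @param tables Numeric matrix, samples in rows, taxa in columns (absences
#'   coded 0 on the union taxon set).
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return A list of class `dendrogram_result` with `hclust`, `phylo`
#'   (an [ape] tree) and `newick` (character).
#' @export
hierarchical_dendrogram <- function(tables, linkage = "complete") {
  m <- as.matrix(tables)
  if (nrow(m) < 2L) {
    stop("hierarchical_dendrogram: need at least 2 samples", call. = FALSE)
  }
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = phy,
                 newick = ape::write.tree(phy)),
            class = "dendrogram_result")
}

#' @export
print.dendrogram_result <- function(x, ...) {
  cat(sprintf("<dendrogram_result> %d tips (%s linkage)\n",
              length(x$hclust$order), x$hclust$method))
  cat(" ", x$newick, "\n")
  invisible(x)
}

#' Analytic sample-based rarefaction curve
#'
#' Expected taxon richness when `k` of the `N` samples are drawn without
#' replacement, computed exactly:
#' `E[S(k)] = sum_t (1 - choose(N - n_t, k) / choose(N, k))`, where `n_t`
#' is the number of samples containing taxon `t`. The curve is monotone
#' non-decreasing and concave, and reaches the observed total richness at
#' `k = N`.
#'
#' @param incidence Binary (or logical) matrix, samples in rows, taxa in
#'   columns; any positive entry counts as presence.
#' @return Data frame with columns `k` and `expected_richness`,
#'   `k = 1, ..., N`.
#' @export
rarefaction_curve <- function(incidence) {
  m <- as.matrix(incidence) > 0
  N <- nrow(m)
  if (N < 1L) stop("rarefaction_curve: no samples", call. = FALSE)
  n_t <- colSums(m)
  n_t <- n_t[n_t > 0]
  ks <- seq_len(N)
  expected <- vapply(ks, function(k) {
    # choose(N - n_t, k) = 0 when k > N - n_t; lchoose handles the rest
    miss <- ifelse(N - n_t >= k, exp(lchoose(N - n_t, k) - lchoose(N, k)), 0)
    sum(1 - miss)
  }, numeric(1))
  data.frame(k = ks, expected_richness = expected)
}

#' Aggregate compositions by group with shared/unique taxon sets
#'
#' Summarizes a nest-by-taxon proportion table per group (e.g. wasp
#' species): the group aggregate is the mean of its nests' proportion
#' vectors, and presence sets give the taxa shared between groups and
#' unique to each.
#'
#' @param tables Numeric matrix, nests in rows, taxa in columns
#'   (proportions; absences 0).
#' @param groups Factor or character vector assigning each nest (row) to a
#'   group.
#' @return A list with `aggregate` (group-by-taxon matrix of mean
#'   proportions), `presence` (named list of taxa present per group),
#'   `shared` (taxa present in more than one group) and `unique` (named
#'   list of taxa exclusive to each group).
#' @export
bipartite_summary <- function(tables, groups) {
  m <- as.matrix(tables)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(m))
  agg <- do.call(rbind, lapply(levels(groups), function(g) {
    colMeans(m[groups == g, , drop = FALSE])
  }))
  rownames(agg) <- levels(groups)
  presence <- lapply(levels(groups), function(g) {
    colnames(m)[colSums(m[groups == g, , drop = FALSE] > 0) > 0]
  })
  names(presence) <- levels(groups)
  all_taxa <- unique(unlist(presence))
  in_n <- vapply(all_taxa, function(t) {
    sum(vapply(presence, function(p) t %in% p, logical(1)))
  }, integer(1))
  shared <- all_taxa[in_n > 1]
  uniq <- lapply(levels(groups), function(g) {
    setdiff(presence[[g]], unlist(presence[setdiff(levels(groups), g)]))
  })
  names(uniq) <- levels(groups)
  list(aggregate = agg, presence = presence, shared = shared, unique = uniq)
}

#' Ordinary least-squares landscape regression
#'
#' Regresses a per-nest response (taxa richness or Shannon diversity) on a
#' landscape predictor (vegetation area within the foraging radius, or the
#' surrounding flora's diversity), reporting the slope, R-squared and the
#' two-sided p-value of the slope test.
#'
#' @param y Numeric response, one value per nest.
#' @param x Numeric predictor, same length; must vary.
#' @return A list with `slope`, `intercept`, `r_squared`, `p_value` and the
#'   underlying `lm` fit.
#' @export
landscape_regression <- function(y, x) {
  stopifnot(length(y) == length(x))
  if (length(y) < 3L) {
    stop("landscape_regression: need at least 3 nests", call. = FALSE)
  }
  if (stats::var(x) == 0) {
    stop("landscape_regression: predictor has zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = s$coefficients[2, 4],
       model = fit)
}

#' Genus-level diversity of the surrounding flora
#'
#' Chao1 richness and Shannon (log2) diversity of a landscape genus
#' abundance survey, e.g. the woody flora within the 100 m foraging radius
#' around a nest.
#'
#' @param flora_counts Named non-negative integer vector of genus counts.
#' @return A one-row `diversity_record` data frame with columns `s_obs`,
#'   `singletons`, `doubletons`, `chao1`, `shannon`.
#' @export
landscape_diversity <- function(flora_counts) {
  rec <- chao1(flora_counts)
  rec$shannon <- shannon(flora_counts)
  rec
}
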