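test_that("Shannon diversity uses log base 2 and behaves as an entropy", {
  expect_equal(shannon(1), 0)
  expect_equal(shannon(rep(0.25, 4)), 2)
  # independent direct summation for a two-taxon composition
  p <- c(0.886, 0.114)
  p <- p / sum(p)
  expect_equal(shannon(c(0.886, 0.114)),
               -(p[1] * log2(p[1]) + p[2] * log2(p[2])), tolerance = 1e-12)
  # permutation invariance and maximality at the uniform distribution
  set.seed(31)
  for (rep in 1:10) {
    v <- rexp(6)
    v <- v / sum(v)
    expect_equal(shannon(sample(v)), shannon(v), tolerance = 1e-12)
    expect_lte(shannon(v), log2(6) + 1e-12)
  }
  expect_equal(shannon(c(5, 0, 5)), 1)  # zeros skipped, counts accepted
  expect_error(shannon(numeric()), "empty")
  expect_error(shannon(c(0, 0)), "zero")
})

test_that("Chao1 handles singletons, doubletons and the b = 0 convention", {
  r <- chao1(c(5, 3, 2))
  expect_equal(r$s_obs, 3)
  expect_equal(r$singletons, 0)
  expect_equal(r$doubletons, 1)
  expect_equal(r$chao1, 3)

  r <- chao1(c(1, 1, 1, 1, 2, 2, 5, 5, 5, 5))
  expect_equal(r$s_obs, 10)
  expect_equal(r$chao1, 10 + 4^2 / (2 * 2))  # formula substitution

  # degenerate single singleton: bias-corrected form, still finite
  r <- chao1(1)
  expect_equal(r$chao1, 1)
  r <- chao1(c(1, 1, 3))
  expect_equal(r$chao1, 3 + 1 * 2 / 2)  # a(a-1)/(2(b+1)) with a=2, b=0

  set.seed(12)
  for (rep in 1:20) {
    counts <- rpois(8, 2)
    if (all(counts == 0)) next
    expect_gte(chao1(counts)$chao1, sum(counts > 0))
  }
  expect_error(chao1(c(-1, 2)), "non-negative")
})

test_that("Mann-Whitney W follows the rank-sum-minus-offset convention", {
  # complete separation, 3 vs 5: W = n1 * n2 = 15
  x <- c(1.32, 1.6, 1.95)
  y <- c(0.43, 0.5, 0.7, 0.8, 0.94)
  mw <- mann_whitney(x, y)
  expect_equal(mw$statistic, 15)
  expect_equal(mw$p_exact, 2 / 56, tolerance = 1e-12)
  # the normal approximation is the commonly quoted 0.037
  expect_equal(round(mw$p_normal, 3), 0.037)
  # complements: W_x + W_y = n1 * n2
  expect_equal(mw$statistic + mann_whitney(y, x)$statistic, 15)

  # agreement with the distribution-function oracle for all small designs
  set.seed(3)
  for (n1 in 1:5) {
    for (n2 in 1:5) {
      x <- sample(100, n1)
      y <- sample(100 + seq(101, 200), n2)  # tie-free by construction
      mw <- mann_whitney(x, y, method = "exact")
      ref <- stats::wilcox.test(x, y, exact = TRUE, correct = FALSE)
      expect_equal(mw$statistic, unname(ref$statistic))
      mid <- n1 * n2 / 2
      d <- abs(mw$statistic - mid)
      expected <- if (d == 0) 1 else {
        stats::pwilcox(mid - d, n1, n2) +
          1 - stats::pwilcox(ceiling(mid + d) - 1, n1, n2)
      }
      expect_equal(mw$p_exact, expected, tolerance = 1e-12)
    }
  }
})

test_that("tied data fall back to the corrected normal approximation", {
  x <- c(1, 1)
  y <- c(1, 1)
  mw <- mann_whitney(x, y)
  expect_equal(mw$statistic, 2)  # midranks put W at n1 n2 / 2
  expect_equal(mw$p.value, 1)
  expect_equal(mw$method, "normal")
  # tie-corrected variance matches wilcox.test's approximation
  set.seed(8)
  x <- sample(1:5, 8, replace = TRUE)
  y <- sample(2:6, 9, replace = TRUE)
  mw <- mann_whitney(x, y, method = "normal")
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mw$p_normal, ref$p.value, tolerance = 1e-9)
})

test_that("Spearman matrices agree with the rank-formula oracle", {
  m <- rbind(A = c(0.5, 0.3, 0.15, 0.05, 0),
             B = c(0.5, 0.3, 0.15, 0.05, 0),
             C = c(0, 0.05, 0.15, 0.3, 0.5))
  colnames(m) <- paste0("Gen", 1:5)
  sm <- spearman_matrix(m)
  expect_equal(sm$rho["A", "A"], 1)
  expect_equal(sm$rho["A", "B"], 1)    # identical composition
  expect_equal(sm$rho["A", "C"], -1)   # exact rank reversal
  expect_true(isSymmetric(sm$rho))

  set.seed(21)
  for (rep in 1:10) {
    a <- rexp(5)
    b <- rexp(5)
    rho <- spearman_matrix(rbind(a, b))$rho["a", "b"]
    d <- rank(a) - rank(b)
    n <- 5
    expect_equal(rho, 1 - 6 * sum(d^2) / (n * (n^2 - 1)), tolerance = 1e-12)
  }

  cm <- rbind(A = c(1, 1, 1), B = c(3, 2, 1))
  expect_warning(sm <- spearman_matrix(cm), "constant")
  expect_true(is.na(sm$rho["A", "B"]))
})

test_that("correspondence analysis reproduces chi-squared inertia", {
  set.seed(17)
  for (rep in 1:8) {
    x <- matrix(rpois(30, 8) + 1, 5, 6)
    dimnames(x) <- list(paste0("R", 1:5), paste0("C", 1:6))
    ca <- correspondence_analysis(x)
    chi2 <- suppressWarnings(stats::chisq.test(x)$statistic)
    expect_equal(ca$total_inertia, unname(chi2) / sum(x), tolerance = 1e-10)
    # row coordinates reproduce inertia through the masses
    expect_equal(sum(ca$masses$row * rowSums(ca$row_coords^2)),
                 ca$total_inertia, tolerance = 1e-10)
  }

  # independent cross-check against vegan's CA eigenvalues
  x <- matrix(rpois(42, 10) + 1, 6, 7,
              dimnames = list(paste0("R", 1:6), paste0("C", 1:7)))
  ca <- correspondence_analysis(x)
  eig <- vegan::cca(x)$CA$eig
  expect_equal(unname(ca$inertia[seq_along(eig)]), unname(eig),
               tolerance = 1e-8)

  # independence structure: zero inertia, no axes
  r <- c(0.2, 0.3, 0.5)
  cc <- c(0.1, 0.4, 0.5)
  indep <- outer(r, cc) * 1000
  dimnames(indep) <- list(paste0("R", 1:3), paste0("C", 1:3))
  ca0 <- correspondence_analysis(indep)
  expect_equal(ca0$total_inertia, 0)
  expect_equal(ncol(ca0$row_coords), 0L)

  # a 2x2 table has at most one axis
  x22 <- matrix(c(10, 2, 3, 9), 2, 2,
                dimnames = list(c("R1", "R2"), c("C1", "C2")))
  expect_equal(length(correspondence_analysis(x22)$inertia), 1L)
  expect_error(correspondence_analysis(matrix(-1, 1, 1)), "non-negative")
})

test_that("dendrograms join identical nests first and export Newick", {
  m <- rbind(N1 = c(0.5, 0.5, 0), N2 = c(0.5, 0.5, 0), N3 = c(0, 0, 1))
  colnames(m) <- paste0("Gen", 1:3)
  dres <- hierarchical_dendrogram(m)
  expect_equal(min(dres$hclust$height), 0)      # identical pair merges at 0
  expect_equal(max(dres$hclust$height),
               max(as.matrix(dist(m))))          # outlier joins last
  expect_match(dres$newick, "^\\(.*N3.*;$|^\\(.*;$")
  expect_s3_class(dres$phylo, "phylo")

  # cophenetic heights match a naive O(n^3) complete-linkage agglomeration
  set.seed(27)
  m <- matrix(runif(25), 5, 5,
              dimnames = list(paste0("N", 1:5), paste0("G", 1:5)))
  dres <- hierarchical_dendrogram(m, linkage = "complete")
  coph <- as.matrix(stats::cophenetic(dres$hclust))
  naive <- local({
    d <- as.matrix(dist(m))
    groups <- as.list(rownames(m))
    h <- matrix(NA_real_, 5, 5, dimnames = dimnames(d))
    while (length(groups) > 1) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(groups)) {
        for (j in seq_len(i - 1)) {
          link <- max(d[groups[[i]], groups[[j]]])
          if (link < best[1]) best <- c(link, i, j)
        }
      }
      gi <- groups[[best[2]]]
      gj <- groups[[best[3]]]
      h[gi, gj] <- best[1]
      h[gj, gi] <- best[1]
      groups[[best[3]]] <- c(gi, gj)
      groups[[best[2]]] <- NULL
    }
    diag(h) <- 0
    h
  })
  expect_equal(coph[rownames(naive), colnames(naive)],
               naive, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("analytic rarefaction matches resampling and is concave", {
  set.seed(19)
  inc <- matrix(rbinom(40, 1, 0.45), 5, 8,
                dimnames = list(paste0("N", 1:5), paste0("G", 1:8)))
  inc[, 1] <- 1  # one ubiquitous taxon
  curve <- rarefaction_curve(inc)
  expect_equal(curve$expected_richness[5], sum(colSums(inc) > 0))
  expect_true(all(diff(curve$expected_richness) >= -1e-12))  # monotone
  expect_true(all(diff(diff(curve$expected_richness)) <= 1e-12))  # concave

  # resampling oracle
  reps <- 2e4
  for (k in c(2, 4)) {
    sims <- replicate(reps, {
      rows <- sample(5, k)
      sum(colSums(inc[rows, , drop = FALSE]) > 0)
    })
    mc_se <- sd(sims) / sqrt(reps)
    expect_lt(abs(mean(sims) - curve$expected_richness[k]),
              4 * mc_se + 1e-9)
  }

  # a taxon present in every sample contributes exactly 1 at every k
  solo <- matrix(1, 4, 1, dimnames = list(paste0("N", 1:4), "G1"))
  expect_equal(rarefaction_curve(solo)$expected_richness, rep(1, 4))
})

test_that("bipartite summaries aggregate by group with shared/unique sets", {
  m <- rbind(N1 = c(0.6, 0.4, 0), N2 = c(0.2, 0.3, 0.5))
  colnames(m) <- c("Quercus", "Robinia", "Salix")
  bs <- bipartite_summary(m, c("mandarinus", "rothneyi"))
  expect_equal(bs$aggregate["mandarinus", ], m["N1", ])  # one nest per group
  expect_equal(bs$aggregate["rothneyi", ], m["N2", ])
  expect_setequal(bs$shared, c("Quercus", "Robinia"))
  expect_equal(bs$unique$rothneyi, "Salix")
  expect_length(bs$unique$mandarinus, 0)

  same <- rbind(N1 = c(0.5, 0.5), N2 = c(0.7, 0.3))
  colnames(same) <- c("Quercus", "Robinia")
  bs2 <- bipartite_summary(same, c("a", "b"))
  expect_length(unlist(bs2$unique), 0)

  # set-algebra oracle on a simulated study
  sim <- generate_nest_study(sim_params(seed = 6))
  props <- sim$counts$counts / rowSums(sim$counts$counts)
  bs3 <- bipartite_summary(props, sim$metadata$wasp_species)
  pa <- colnames(props)[colSums(
    props[sim$metadata$wasp_species == "mandarinus", , drop = FALSE]) > 0]
  pb <- colnames(props)[colSums(
    props[sim$metadata$wasp_species == "rothneyi", , drop = FALSE]) > 0]
  expect_setequal(bs3$shared, intersect(pa, pb))
  expect_setequal(bs3$unique$mandarinus, setdiff(pa, pb))
})

test_that("landscape regressions report slope, R-squared and a valid null", {
  x <- c(1, 2, 3, 4, 5)
  # noise-free input trips lm's perfect-fit caution, not under test
  r <- suppressWarnings(landscape_regression(2 * x, x))
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_error(landscape_regression(c(1, 2, 3), c(4, 4, 4)), "variance")
  expect_error(landscape_regression(c(1, 2), c(1, 2)), "3 nests")

  # under independence the slope p-value is uniform (KS check)
  set.seed(23)
  pvals <- replicate(500, {
    landscape_regression(rnorm(50), rnorm(50))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("landscape diversity combines Chao1 and Shannon at genus level", {
  rec <- landscape_diversity(c(Quercus = 1, Robinia = 1, Pinus = 2))
  expect_equal(rec$chao1, 3 + 2^2 / (2 * 1))  # a = 2 singletons, b = 1
  expect_equal(rec$shannon, shannon(c(1, 1, 2)))
  expect_equal(landscape_diversity(rep(3, 8))$shannon, 3)  # uniform 8 genera
})
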