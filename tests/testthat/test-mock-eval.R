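ref_design <- function() {
  mixture_design(data.frame(
    sample = c("S1", "S1", "S2", "S2"),
    family = c("Pinaceae", "Rosaceae", "Pinaceae", "Rosaceae"),
    genus = c("Pinus", "Prunus", "Pinus", "Prunus"),
    species = c("Pinus koreanus", "Prunus salicina",
                "Pinus koreanus", "Prunus salicina"),
    true = c(0.7, 0.3, 0.4, 0.6), stringsAsFactors = FALSE))
}

perfect_table <- function(design) {
  samples <- unique(design$sample)
  taxa <- unique(design$species)
  v <- matrix(NA_real_, length(samples), length(taxa),
              dimnames = list(samples, taxa))
  for (i in seq_len(nrow(design))) {
    v[design$sample[i], design$species[i]] <- design$true[i]
  }
  lineages <- lapply(unique(design$species), function(s) {
    row <- design[design$species == s, ][1, ]
    taxon_label(row$family, row$genus, row$species)
  })
  proportion_table(v, "rbcL", taxa = lineages)
}

test_that("detection accounting reproduces the reference-table counts", {
  fx <- load_table1_fixture()
  rep_r <- classify_detections(threshold_and_renormalize(fx$rbcl, 0.01),
                               fx$design)
  rep_t <- classify_detections(threshold_and_renormalize(fx$trnl, 0.01),
                               fx$design)
  with_fn_r <- rep_r$summary$sample[rep_r$summary$n_false_negative > 0]
  with_fn_t <- rep_t$summary$sample[rep_t$summary$n_false_negative > 0]
  expect_setequal(with_fn_r, c("PC5", "PC6", "PC7"))
  expect_setequal(with_fn_t, c("PC6", "PC7"))
  expect_equal(rep_t$summary$n_false_negative[rep_t$summary$sample == "PC7"],
               4L)
})

test_that("detections partition design taxa; perfect input has no errors", {
  design <- ref_design()
  rep <- classify_detections(perfect_table(design), design)
  expect_true(all(rep$summary$n_false_negative == 0))
  expect_true(all(rep$summary$n_false_positive == 0))

  fx <- load_table1_fixture()
  for (tb in list(fx$rbcl, fx$trnl)) {
    rep <- classify_detections(threshold_and_renormalize(tb, 0.01),
                               fx$design)
    expect_equal(rep$summary$n_detected + rep$summary$n_false_negative,
                 rep$summary$n_design)
    # false positives are never design taxa; false negatives always are
    for (s in names(rep$per_sample)) {
      des <- fx$design$species[fx$design$sample == s]
      expect_true(all(rep$per_sample[[s]]$false_negatives %in% des))
      expect_length(intersect(rep$per_sample[[s]]$false_positives, des), 0)
    }
  }

  missing <- perfect_table(design)
  expect_error(
    classify_detections(
      proportion_table(missing$values[1, , drop = FALSE], "rbcL",
                       taxa = missing$taxa), design),
    "missing")
})

test_that("family-rank and congeneric calls count as detections", {
  design <- mixture_design(data.frame(
    sample = "S1", family = "Anacardiaceae", genus = "Rhus",
    species = "Rhus chinensis", true = 1, stringsAsFactors = FALSE))
  v <- matrix(1, 1, 1, dimnames = list("S1", "Anacardiaceae"))
  tb <- proportion_table(v, "rbcL", taxa = list(taxon_label("Anacardiaceae")))
  rep <- classify_detections(tb, design)
  expect_equal(rep$summary$n_false_negative, 0L)
  expect_equal(rep$summary$n_false_positive, 0L)
})

test_that("calibration on exact observations recovers the identity line", {
  design <- ref_design()
  # degenerate noise-free input: the mixed model's gradient/Hessian checks
  # and the OLS summary legitimately complain, which is not under test
  fit <- suppressWarnings(fit_calibration(perfect_table(design), design))
  expect_equal(unname(coef(fit)["slope"]), 1, tolerance = 1e-6)
  expect_equal(unname(coef(fit)["intercept"]), 0, tolerance = 1e-6)
  expect_equal(fit$r2_adjusted_ols, 1, tolerance = 1e-9)
  expect_equal(predict(fit), fit$data$obs, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(unname(residuals(fit)), rep(0, 4), tolerance = 1e-6)
})

test_that("single-taxon data falls back to closed-form least squares", {
  # dilution-series style design: one taxon, partial proportions
  design <- suppressWarnings(mixture_design(data.frame(
    sample = c("S1", "S2", "S3"), family = "Pinaceae", genus = "Pinus",
    species = "Pinus koreanus", true = c(0.2, 0.5, 0.9),
    stringsAsFactors = FALSE)))
  v <- matrix(c(0.25, 0.45, 0.95), 3, 1,
              dimnames = list(c("S1", "S2", "S3"), "Pinus koreanus"))
  tb <- proportion_table(v, "rbcL",
                         taxa = list(taxon_label("Pinaceae", "Pinus",
                                                 "Pinus koreanus")))
  expect_warning(fit <- fit_calibration(tb, design, renormalize = FALSE),
                 "OLS")
  expect_equal(fit$method, "OLS")
  # closed-form OLS oracle
  x <- c(0.2, 0.5, 0.9)
  y <- c(0.25, 0.45, 0.95)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  b0 <- mean(y) - b1 * mean(x)
  expect_equal(unname(coef(fit)), c(b0, b1), tolerance = 1e-12)
  expect_equal(fit$sigma_u2, 0)
})

test_that("zero-filled and excluded removals give distinct, sane fits", {
  fx <- load_table1_fixture()
  fz <- fit_calibration(fx$rbcl, fx$design, removed = "zero")
  fe <- fit_calibration(fx$rbcl, fx$design, removed = "exclude")
  expect_equal(fz$n, nrow(fx$design))       # every design cell enters
  expect_lt(fe$n, fz$n)                     # flagged cells dropped
  expect_false(isTRUE(all.equal(coef(fz), coef(fe))))
  expect_gt(fz$sigma_u2, 0)
  expect_gt(fz$sigma_e2, 0)
  expect_true(fz$r2_marginal >= 0 && fz$r2_marginal <= 1)
  expect_gte(fz$r2_conditional, fz$r2_marginal)
})

test_that("an unbiased deep-coverage simulation brackets slope 1", {
  p <- sim_params(seed = 99, depth = 1e5, bias_sigma = 0, contam_rate = 0,
                  genus_tie_rate = 0, family_tie_rate = 0)
  sim <- generate_mock_experiment(p)
  res <- run_mock_eval(sim$rbcl, sim$trnl, sim$design,
                       nc_rbcl = sim$nc_rbcl, nc_trnl = sim$nc_trnl)
  fit <- res$fits$rbcL
  se <- sqrt(diag(as.matrix(vcov(fit$model)))[2])
  slope <- coef(fit)[["slope"]]
  expect_true(abs(slope - 1) <= 2 * se + 0.02)
})

test_that("markers rank by distance of their slope from 1", {
  mk_fit <- function(slope, r2 = 0.5) {
    structure(list(coefficients = c(intercept = 0.05, slope = slope),
                   sigma_u2 = 0.01, sigma_e2 = 0.02,
                   r2_adjusted_ols = r2, r2_marginal = r2,
                   r2_conditional = r2, n = 20,
                   data = data.frame(), model = NULL, method = "REML"),
              class = "calibration_fit")
  }
  ranking <- compare_markers(list(rbcL = mk_fit(0.67), median = mk_fit(0.53),
                                  trnL = mk_fit(0.41)))
  expect_equal(ranking$marker, c("rbcL", "median", "trnL"))
  # exact ties keep input order
  tied <- compare_markers(list(a = mk_fit(0.8), b = mk_fit(0.8)))
  expect_equal(tied$marker, c("a", "b"))
  single <- compare_markers(list(only = mk_fit(0.9)))
  expect_equal(nrow(single), 1L)
})
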