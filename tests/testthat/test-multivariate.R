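test_that("PCA matches an independent eigendecomposition of the correlation matrix", {
  m <- planted_sensitivity_matrix(n_conditions = 20, noise_sd = 0.4,
                                  seed = 13)
  p <- pca_gamma(m)
  x <- as.matrix(m[, p$measures])
  ev <- eigen(stats::cor(x), symmetric = TRUE)$values
  expect_equal(as.numeric(p$explained), ev / sum(ev), tolerance = 1e-10)
  # loadings rows are unit norm, fractions sum to 1, ordering non-increasing
  expect_equal(unname(rowSums(p$loadings^2)),
               rep(1, nrow(p$loadings)), tolerance = 1e-10)
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  expect_true(all(diff(as.numeric(p$explained)) <= 1e-12))
})

test_that("a rank-1 planting explains all variance on PC1", {
  m <- planted_sensitivity_matrix(n_conditions = 15, noise_sd = 0, seed = 2)
  p <- pca_gamma(m)
  expect_equal(as.numeric(p$explained[1]), 1, tolerance = 1e-9)
})

test_that("scores reconstruct the standardized matrix with all components", {
  m <- planted_sensitivity_matrix(n_conditions = 20, noise_sd = 0.3,
                                  seed = 4)
  p <- pca_gamma(m)
  x <- scale(as.matrix(m[, p$measures]))
  sc <- as.matrix(p$scores[, paste0("PC", seq_along(p$explained))])
  expect_lt(max(abs(sc %*% p$loadings - x)), 1e-10)
})

test_that("duplicated conditions get identical scores", {
  m <- planted_sensitivity_matrix(n_conditions = 8, seed = 6)
  m2 <- dplyr::bind_rows(m, m[3, ])
  p <- pca_gamma(m2)
  pcs <- paste0("PC", seq_along(p$explained))
  expect_equal(as.numeric(p$scores[9, pcs]), as.numeric(p$scores[3, pcs]))
})

test_that("degenerate inputs are handled as declared", {
  m <- planted_sensitivity_matrix(n_conditions = 10, seed = 3)
  m$rSPS <- 1   # zero-variance measure
  expect_warning(p <- pca_gamma(m), "zero-variance")
  expect_false("rSPS" %in% p$measures)

  m2 <- planted_sensitivity_matrix(n_conditions = 10, seed = 3)
  m2$F6P[4] <- NA
  expect_warning(p2 <- pca_gamma(m2), "excluded")
  expect_equal(nrow(p2$scores), 9)

  expect_error(pca_gamma(m[1, ]), "at least 2")
})

test_that("the sign convention pins the Suc loading non-positive", {
  m <- planted_sensitivity_matrix(n_conditions = 12, noise_sd = 0.3,
                                  seed = 8)
  p <- pca_gamma(m)
  suc <- p$loadings[, "Suc"]
  expect_true(all(suc <= 1e-12))
})

test_that("day-0 separation detects planted shifts and respects symmetries", {
  m <- planted_sensitivity_matrix(shift = 3, seed = 3)
  p <- pca_gamma(m)
  sep <- day0_separation(p)
  expect_gte(sep$statistic, 2.5)
  expect_false(sep$low_confidence)

  # invariance to a global sign flip of PC1
  p_flip <- p
  p_flip$scores$PC1 <- -p_flip$scores$PC1
  expect_equal(day0_separation(p_flip)$statistic, sep$statistic)

  # invariance to condition ordering
  perm <- sample(nrow(m))
  p_perm <- pca_gamma(m[perm, ])
  expect_equal(day0_separation(p_perm)$statistic, sep$statistic,
               tolerance = 1e-10)

  # grows monotonically with the planted shift
  stats <- vapply(c(1, 3, 6), function(sh) {
    day0_separation(pca_gamma(
      planted_sensitivity_matrix(shift = sh, seed = 3)))$statistic
  }, numeric(1))
  expect_true(all(diff(stats) > 0))

  # shuffled labels give a near-null statistic on average
  set.seed(99)
  null_stats <- vapply(1:200, function(i) {
    day0_separation(p, labels = sample(m$day))$statistic
  }, numeric(1))
  expect_lt(mean(null_stats), 0.25 * sep$statistic)

  # low-confidence flag when the day-0 group is a singleton
  labs <- m$day; labs[labs == 0] <- 7; labs[1] <- 0
  expect_true(day0_separation(p, labels = labs)$low_confidence)
})

test_that("the robustness test is deterministic and degenerates correctly", {
  m <- planted_sensitivity_matrix(shift = 3, seed = 3)
  r0 <- robustness_test(m, noise_level = 0, repetitions = 5, seed = 1)
  expect_equal(r0$preserved_fraction, 1)
  expect_equal(r0$mean_statistic, r0$baseline_statistic)

  r1 <- robustness_test(m, noise_level = 0.5, repetitions = 20, seed = 42)
  r2 <- robustness_test(m, noise_level = 0.5, repetitions = 20, seed = 42)
  expect_identical(r1, r2)
  expect_true(r1$preserved_fraction >= 0 && r1$preserved_fraction <= 1)
})

test_that("broom-style accessors expose loadings, scores and eigenvalues", {
  m <- planted_sensitivity_matrix(n_conditions = 10, seed = 5)
  p <- pca_gamma(m)
  td <- tidy(p, "loadings")
  expect_setequal(unique(td$measure), p$measures)
  expect_equal(nrow(tidy(p, "eigenvalues")), length(p$explained))
  expect_true("score" %in% names(tidy(p, "scores")))
  g <- glance(p)
  expect_equal(g$n_conditions, 10)
  expect_equal(g$pc1_pct, 100 * as.numeric(p$explained[1]))
})
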