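test_that("the default study design yields 25 reproducible conditions", {
  st <- generate_study(seed = 1)
  expect_equal(nrow(st$conditions), 25)
  expect_setequal(unique(st$conditions$genotype),
                  c("Col-0", "chs", "f3h", "bam3", "pgm1"))
  expect_setequal(unique(st$conditions$day), c(0, 1, 3, 7, 14))
  expect_true(all(st$steady_states$ss_residual < 1e-9))
  expect_true(all(st$conditions$k_STAdeg == 0))

  st_again <- generate_study(seed = 1)
  expect_identical(st$conditions, st_again$conditions)
  expect_identical(st$observations, st_again$observations)

  st_other <- generate_study(seed = 2)
  expect_false(identical(st$conditions, st_other$conditions))
})

test_that("zero observation noise returns the true steady states exactly", {
  st <- generate_study(n_genotypes = 2, n_days = 2, seed = 6, noise_cv = 0)
  for (i in seq_len(nrow(st$conditions))) {
    obs <- condition_observations(st, i)
    conc <- setNames(obs$value[match(metabolite_names(), obs$measure)],
                     metabolite_names())
    truth <- as_metabolite_state(st$steady_states[i, metabolite_names()])
    expect_identical(unname(conc), unname(truth))
  }
})

test_that("observation noise has the declared multiplicative structure", {
  st <- generate_study(seed = 31, noise_cv = 0.1)
  truth <- generate_study(seed = 31, noise_cv = 0)
  ratio <- st$observations$value / truth$observations$value
  # unbiased lognormal noise: mean ratio near 1, spread near the cv
  expect_equal(mean(ratio), 1, tolerance = 0.02)
  expect_equal(sd(log(ratio)), sqrt(log(1 + 0.1^2)), tolerance = 0.15)
  expect_equal(st$observations$sigma, 0.1 * st$observations$value)
})

test_that("genotype archetypes scale their affected constants", {
  st <- generate_study(seed = 3, noise_cv = 0)
  med <- st$conditions |>
    dplyr::group_by(genotype) |>
    dplyr::summarise(k_ANT = median(k_ANT), k_STA = median(k_STA))
  ref <- med[med$genotype == "Col-0", ]
  expect_lt(med$k_ANT[med$genotype == "chs"], 0.3 * ref$k_ANT)
  expect_lt(med$k_ANT[med$genotype == "f3h"], 0.3 * ref$k_ANT)
  expect_lt(med$k_STA[med$genotype == "pgm1"], 0.3 * ref$k_STA)
  expect_lt(med$k_STA[med$genotype == "bam3"], ref$k_STA)
})

test_that("planted matrices have exactly the declared structure", {
  expect_error(planted_sensitivity_matrix(n_conditions = 4, n_shifted = 9),
               "n_shifted")
  expect_error(planted_sensitivity_matrix(n_conditions = 1), "at least 2")

  m <- planted_sensitivity_matrix(n_conditions = 10, n_measures = 6,
                                  shift = 2, seed = 5)
  expect_equal(dim(m), c(10, 8))
  expect_true(all(as.matrix(m[, -(1:2)]) > 0))
  expect_equal(sum(m$day == 0), 5)

  # determinism
  expect_identical(m, planted_sensitivity_matrix(n_conditions = 10,
                                                 n_measures = 6,
                                                 shift = 2, seed = 5))
})

test_that("a null matrix shows no dominant component as conditions grow", {
  m <- planted_sensitivity_matrix(n_conditions = 300, n_measures = 10,
                                  shift = 0, noise_sd = 0.3, n_shifted = 5,
                                  seed = 9)
  # remove the rank-1 score component entirely: shift 0 still leaves the
  # common latent direction, so rebuild pure noise instead
  set.seed(9)
  noise <- tibble::as_tibble(as.data.frame(
    matrix(2 + rnorm(300 * 10, sd = 0.3), 300, 10)))
  names(noise) <- paste0("m", 1:10)
  noise$day <- m$day
  p <- pca_gamma(noise, measures = paste0("m", 1:10))
  # Marchenko-Pastur-style null: the top fraction stays near uniformity
  expect_lt(as.numeric(p$explained[1]), 0.2)
  expect_gt(as.numeric(p$explained[1]), 0.1 - 0.02)
})
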