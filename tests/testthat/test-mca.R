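test_that("finite differences reproduce the closed-form chain coefficients", {
  pars <- c(v0 = 2, k1 = 0.7, k2 = 1.3, k3 = 0.4)
  for (pn in names(pars)) {
    got <- carbsens:::.cc_fd_core(pars[[pn]], 1e-4, function(pv) {
      p2 <- pars; p2[pn] <- pv
      chain_measures(p2)
    })
    expect_equal(unname(got), unname(chain_cc_closed_form(pn)),
                 tolerance = 1e-6)
  }
})

test_that("both summation theorems hold on the reference realization", {
  rl <- toy_realization()
  cc <- full_mca(rl, parameters = rate_scaling_constants())
  chk <- summation_check(cc)
  expect_true(all(chk$abs_dev < 1e-4))
  expect_setequal(unique(chk$expected[chk$kind == "flux"]), 1)
  expect_setequal(unique(chk$expected[chk$kind == "concentration"]), 0)
})

test_that("the analytic implicit-function path cross-checks finite differences", {
  rl <- toy_realization()
  for (pn in c("f", "k_NPS", "Km_INV", "vmax_GLCK", "k_udp")) {
    fd <- control_coefficient(rl, pn, rel_step = 1e-4)
    an <- control_coefficient(rl, pn, method = "analytic")
    expect_equal(unname(fd), unname(an), tolerance = 1e-4)
  }
})

test_that("coefficients converge under step refinement", {
  rl <- toy_realization()
  c3 <- control_coefficient(rl, "f", rel_step = 1e-3)
  c4 <- control_coefficient(rl, "f", rel_step = 1e-4)
  big <- abs(c4) > 1e-3
  expect_equal(unname(c3[big] / c4[big]), rep(1, sum(big)),
               tolerance = 1e-3)
})

test_that("steps near admissible bounds stay two-sided", {
  q <- unclass(default_parameters())
  q["k_udp"] <- 0.49
  rl <- condition_realization(as_kinetic_params(q))
  # a multiplicative step of 5% would cross the k_udp upper bound of 0.5;
  # the step must shrink, not silently go one-sided, and still agree with a
  # small-step evaluation
  coarse <- control_coefficient(rl, "k_udp", X = "Glc", rel_step = 0.05)
  fine <- control_coefficient(rl, "k_udp", X = "Glc", rel_step = 1e-4)
  expect_true(is.finite(coarse))
  expect_equal(unname(coarse), unname(fine), tolerance = 0.05)
})

test_that("f controls Glc and Frc with opposite signs in the G6P-feedback regime", {
  rl <- condition_realization(regime_params())
  cc <- control_coefficient(rl, "f", X = c("Glc", "Frc"))
  expect_gt(cc[["Glc"]], 0)
  expect_lt(cc[["Frc"]], 0)
})

test_that("exceedance counts match a planted ground truth", {
  # synthetic long tensor with a known exceedance plan
  plan <- tidyr::expand_grid(genotype = c("A", "B"), day = c(0, 7),
                             parameter = c("p1", "p2", "p3"),
                             measure = c("m1", "m2"))
  set.seed(8)
  plan$value <- runif(nrow(plan), -1, 1)      # all below threshold
  planted <- list(A = 3, B = 5)
  for (g in names(planted)) {
    idx <- sample(which(plan$genotype == g), planted[[g]])
    plan$value[idx] <- sample(c(-1, 1), planted[[g]], TRUE) *
      runif(planted[[g]], 2, 4)
  }
  counts <- high_cc_frequency(plan, threshold = 1.5, group_by = "genotype")
  expect_equal(counts$n_exceed[match(c("A", "B"), counts$genotype)],
               c(3L, 5L))

  # trivial thresholds
  expect_true(all(high_cc_frequency(plan, Inf, "genotype")$n_exceed == 0))
  all_cnt <- high_cc_frequency(plan, 0, "day")
  nonzero <- plan |>
    dplyr::group_by(day) |>
    dplyr::summarise(n = sum(value != 0 & is.finite(value)))
  expect_equal(all_cnt$n_exceed, nonzero$n)

  # missing entries are excluded with a message
  plan$value[1] <- NA
  expect_message(high_cc_frequency(plan, 1.5, "genotype"), "excluded")
})

test_that("unknown parameters and measures are rejected", {
  rl <- toy_realization()
  expect_error(control_coefficient(rl, "k_STAdeg"), "perturbable")
  expect_error(control_coefficient(rl, "not_a_param"), "perturbable")
  expect_error(control_coefficient(rl, "f", X = "bogus"), "unknown measure")
})
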