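test_that("the sensitivity score evaluates its closed-form cases", {
  # proportional response: x changes exactly like the rate
  expect_equal(gamma_score(2, 2 * c(1.1, 0.8), 1, c(1.1, 0.8)), 0)
  # single perturbation, x doubles while the rate is unchanged
  expect_equal(gamma_score(1, 2, 1, 1), 1)
  # geometric mean of inner terms 1 and 2
  expect_equal(gamma_score(1, c(2, 4), 1, c(1, 1)), sqrt(2))

  expect_error(gamma_score(1, c(1, 2), 1, 1), "length")
  expect_error(gamma_score(0, 1, 1, 1), "positive")
  expect_error(gamma_score(1, -1, 1, 1), "positive")
})

test_that("the score has the geometric-mean symmetries", {
  set.seed(9)
  x0 <- 2; r0 <- 1.5
  xi <- runif(12, 0.5, 4); ri <- runif(12, 0.8, 1.3)
  g <- gamma_score(x0, xi, r0, ri)

  # order invariance
  perm <- sample(12)
  expect_equal(gamma_score(x0, xi[perm], r0, ri[perm]), g)
  # common rescaling of all x only enters through ratios
  expect_equal(gamma_score(x0 * 7, xi * 7, r0, ri), g)
  # doubling every inner fold change in log space doubles the score
  inner <- log2((xi / x0) * (r0 / ri))
  xi2 <- x0 * (ri / r0) * 2^(2 * inner)
  expect_equal(gamma_score(x0, xi2, r0, ri), 2 * g)
})

test_that("protocol validation rejects degenerate designs", {
  expect_error(perturbation_protocol(numeric(0)), "at least one")
  expect_error(perturbation_protocol(c(0.1, -1)), "> -1")
  expect_error(perturbation_protocol(0.1, pre_perturbation_time = 5,
                                     total_time = 4), "total_time")
  expect_warning(perturbation_protocol(c(0, 0.1)), "annihilates")
})

test_that("a zero relative change annihilates every measure's score", {
  rl <- toy_realization()
  prot <- suppressWarnings(perturbation_protocol(c(0, 0.2)))
  sw <- run_perturbation_sweep(rl, prot)
  expect_true(all(sw$gamma == 0))
})

test_that("sweep scores equal a literal re-computation from stored time courses", {
  rl <- toy_realization()
  prot <- perturbation_protocol(c(-0.2, -0.1, 0.1, 0.2))
  sw <- run_perturbation_sweep(rl, prot)

  # recompute each gamma step by step from the stored trajectories
  for (m in measure_names()) {
    inner <- vapply(seq_along(prot$relative_changes), function(i) {
      d <- prot$relative_changes[i]
      tc <- dplyr::filter(sw$timecourses,
                          .data$relative_change == d,
                          .data$time == prot$total_time)
      st <- as_metabolite_state(tc[, metabolite_names()])
      q <- unclass(rl$params); q["k_NPS"] <- q[["k_NPS"]] * (1 + d)
      vals <- c(st[c("F6P", "G6P", "Frc", "Glc", "Suc")],
                compute_fluxes(st, as_kinetic_params(q))[
                  c("rSPS", "rPGI", "rFRCK", "rGLCK", "r1", "rINV", "r2",
                    "rSTAsyn", "rANTHO")])
      names(vals) <- measure_names()
      abs(log2((vals[[m]] / sw$baseline[[m]]) / (1 + d)))
    }, numeric(1))
    expect_equal(unname(sw$gamma[m]), prod(inner)^(1 / length(inner)),
                 tolerance = 1e-12)
  }
})

test_that("sweeps are reproducible and first-order fluxes mirror their substrates", {
  rl <- toy_realization()
  prot <- perturbation_protocol(c(-0.1, 0.1))
  sw1 <- run_perturbation_sweep(rl, prot)
  sw2 <- run_perturbation_sweep(rl, prot)
  expect_identical(sw1$gamma, sw2$gamma)

  # r1 = k1*Suc, r2 ~ F6P, rSTAsyn ~ G6P, rANTHO ~ F6P pointwise, so their
  # perturbation-normalized fold changes coincide with their substrates'
  expect_equal(unname(sw1$gamma["r1"]), unname(sw1$gamma["Suc"]),
               tolerance = 1e-10)
  expect_equal(unname(sw1$gamma["rSTAsyn"]), unname(sw1$gamma["G6P"]),
               tolerance = 1e-10)
  expect_equal(unname(sw1$gamma["rANTHO"]), unname(sw1$gamma["F6P"]),
               tolerance = 1e-10)
  expect_equal(unname(sw1$gamma["r2"]), unname(sw1$gamma["F6P"]),
               tolerance = 1e-10)
})

test_that("long-readout sweeps converge to the relaxed steady-state ratios", {
  rl <- toy_realization()
  changes <- c(-0.2, 0.2)
  prot <- perturbation_protocol(changes, pre_perturbation_time = 2,
                                total_time = 2002)
  sw <- run_perturbation_sweep(rl, prot)

  # independent oracle: re-solve the steady state per perturbed influx
  gamma_ss <- vapply(measure_names(), function(m) {
    inner <- vapply(changes, function(d) {
      q <- unclass(rl$params); q["k_NPS"] <- q[["k_NPS"]] * (1 + d)
      ss <- find_steady_state(as_kinetic_params(q),
                              initial_guess = rl$steady_state)
      vals <- c(ss$state[c("F6P", "G6P", "Frc", "Glc", "Suc")],
                compute_fluxes(ss$state, as_kinetic_params(q))[
                  c("rSPS", "rPGI", "rFRCK", "rGLCK", "r1", "rINV", "r2",
                    "rSTAsyn", "rANTHO")])
      names(vals) <- measure_names()
      abs(log2((vals[[m]] / sw$baseline[[m]]) / (1 + d)))
    }, numeric(1))
    prod(inner)^(1 / length(inner))
  }, numeric(1))
  expect_equal(unname(sw$gamma), unname(gamma_ss), tolerance = 1e-4)
})

test_that("the high-light protocol applies one step and samples durations", {
  rl <- toy_realization()
  # no perturbation, no sensitivity
  g0 <- run_high_light_protocol(rl, step_fraction = 0)
  expect_true(all(g0 == 0))

  g <- run_high_light_protocol(rl, step_fraction = 0.25,
                               readout_times = c(3, 6))
  expect_true(all(is.finite(g) & g >= 0))

  # two-point re-computation oracle from the sampled states
  ro <- attr(g, "readouts")
  baseline <- carbsens:::.measures_at(rl$steady_state, rl$params)
  for (m in measure_names()) {
    inner <- abs(log2((ro[[m]] / baseline[[m]]) / 1.25))
    expect_equal(unname(g[m]), prod(inner)^(1 / 2), tolerance = 1e-12)
  }

  expect_error(run_high_light_protocol(rl, step_fraction = -1), "> -1")
  expect_error(run_high_light_protocol(rl, readout_times = numeric(0)),
               "readout_times")
})

test_that("sensitivity_sweep assembles the conditions-by-measures matrix", {
  st <- generate_study(n_genotypes = 2, n_days = 2, seed = 4)
  g <- sensitivity_sweep(st$conditions,
                         perturbation_protocol(c(-0.1, 0.1)))
  expect_equal(nrow(g), 4)
  expect_setequal(setdiff(names(g), c("genotype", "day")), measure_names())
  expect_true(all(as.matrix(g[, measure_names()]) >= 0))
})
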