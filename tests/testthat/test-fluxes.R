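test_that("limiting cases of the rate laws evaluate exactly", {
  p <- default_parameters()

  # zero substrate: every saturable and first-order flux vanishes, the
  # photosynthetic influx does not
  v0 <- compute_fluxes(setNames(rep(0, 5), metabolite_names()), p)
  expect_equal(unname(v0["rNPS"]), p[["k_NPS"]] / 6)
  expect_true(all(v0[setdiff(names(v0), "rNPS")] == 0))

  # hexose-equivalent scaling of the influx
  q <- unclass(p); q["k_NPS"] <- 6
  v <- compute_fluxes(c(F6P = 1, G6P = 1, Suc = 1, Frc = 1, Glc = 1),
                      as_kinetic_params(q))
  expect_equal(unname(v["rNPS"]), 1)

  # half-saturation of fructokinase with no inhibitor present
  s <- c(F6P = 0, G6P = 0, Suc = 0, Frc = p[["Km_FRCK"]], Glc = 0)
  expect_equal(unname(compute_fluxes(s, p)["rFRCK"]), p[["vmax_FRCK"]] / 2)

  # first-order sucrose export
  q <- unclass(p); q["k1_exp"] <- 0.1
  s <- c(F6P = 0, G6P = 0, Suc = 2, Frc = 0, Glc = 0)
  expect_equal(unname(compute_fluxes(s, as_kinetic_params(q))["r1"]), 0.2)
})

test_that("fluxes match an independent re-derivation of the rate laws", {
  # independently written rate laws (different style on purpose)
  oracle <- function(s, p) {
    with(as.list(c(s, p)), c(
      rNPS = k_NPS / 6,
      rSPS = (vmax_SPS * F6P * k_udp * G6P) /
        (Km_a_SPS * F6P + (Km_b_SPS + F6P) * k_udp * G6P +
           Ki_SPS * Km_a_SPS),
      rFRCK = vmax_FRCK * (Frc / (Km_FRCK + Frc)) / (1 + F6P / Ki_FRCK),
      rGLCK = vmax_GLCK * (Glc / (Km_GLCK + Glc)) / (1 + G6P / Ki_GLCK),
      rINV = (vmax_INV * Suc / (Km_INV * (1 + Frc / Ki_INV1) + Suc)) /
        (1 + Glc / Ki_INV2),
      rPGI1 = f * vmax_PGI * F6P / (Km_PGI + Km_PGI * G6P / Ki_PGI + F6P),
      rPGI2 = (1 - f) * vmax_PGI * G6P /
        (Km_PGI + Km_PGI * F6P / Ki_PGI + G6P),
      r1 = k1_exp * Suc,
      r2 = k2_exp * F6P,
      rSTAsyn = k_STA * G6P,
      rANTHO = k_ANT * F6P,
      rSTAdeg = k_STAdeg))
  }
  set.seed(11)
  for (i in 1:100) {
    s <- setNames(runif(5, 0, 50), metabolite_names())
    q <- unclass(default_parameters())
    pos <- setdiff(names(q), c("f", "k_udp", "k_STAdeg"))
    q[pos] <- q[pos] * exp(runif(length(pos), -1, 1))
    q["f"] <- runif(1); q["k_udp"] <- runif(1, 0.2, 0.5)
    q["k_STAdeg"] <- runif(1, 0, 0.5)
    p <- as_kinetic_params(q)
    got <- compute_fluxes(s, p)[flux_names()]
    want <- oracle(s, p)[flux_names()]
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-12)
  }
})

test_that("the reported rPGI measure follows the configured branch", {
  p <- default_parameters()
  s <- c(F6P = 3, G6P = 10, Suc = 5, Frc = 2, Glc = 2)
  v1 <- compute_fluxes(s, p, pgi_report = "rPGI1")
  v2 <- compute_fluxes(s, p, pgi_report = "rPGI2")
  vm <- compute_fluxes(s, p, pgi_report = "mean")
  expect_equal(unname(v1["rPGI"]), unname(v1["rPGI1"]))
  expect_equal(unname(v2["rPGI"]), unname(v2["rPGI2"]))
  expect_equal(unname(vm["rPGI"]),
               unname((v1["rPGI1"] + v1["rPGI2"]) / 2))
  expect_identical(attr(v2, "pgi_report"), "rPGI2")
})

test_that("fluxes are non-negative on random admissible states", {
  set.seed(5)
  p <- default_parameters()
  for (i in 1:25) {
    s <- setNames(runif(5, 0, 100), metabolite_names())
    expect_true(all(compute_fluxes(s, p) >= 0))
  }
  expect_error(compute_fluxes(c(F6P = -1, G6P = 0, Suc = 0, Frc = 0,
                                Glc = 0), p), "non-negative")
})
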