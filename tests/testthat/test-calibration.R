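test_that("constraint sets validate their structure", {
  expect_error(constraint_set(order_relations = list(
    c("Km_FRCK", ">", "Km_GLCK"), c("Km_GLCK", ">", "Km_FRCK"))), "cycle")
  expect_error(constraint_set(order_relations = list(
    c("Km_FRCK", ">=", "Km_GLCK"))), "triples")
  expect_error(constraint_set(order_relations = list(
    c("Km_FRCK", ">", "nothing"))), "unknown parameter")

  cs <- constraint_set(pgi_preset = "pgi_below_frck")
  expect_true(any(vapply(cs$order_relations,
                         function(r) r[1] == "Km_FRCK" && r[3] == "Km_PGI",
                         logical(1))))
  cs2 <- constraint_set(pgi_preset = "pgi_above_frck")
  expect_true(any(vapply(cs2$order_relations,
                         function(r) r[1] == "Km_PGI" && r[3] == "Km_FRCK",
                         logical(1))))

  b <- default_parameter_bounds()
  b$upper[b$parameter == "Km_FRCK"] <- 0.4   # below Km_GLCK's lower bound
  expect_error(constraint_set(bounds = b), "infeasible")
})

test_that("constraint reports name failing rules and offending values", {
  p <- setNames(as.numeric(default_parameters()),
                parameter_names())
  tbl <- dplyr::bind_cols(tibble::tibble(genotype = "Col-0", day = 0),
                          tibble::as_tibble_row(p))
  rep1 <- check_constraints(tbl)
  expect_true(all(rep1$pass))

  # second condition with a 10.5-fold Km_FRCK spread breaks cohesion;
  # scale Km_INV along so the ratio band is untouched
  q <- p
  q["Km_FRCK"] <- p[["Km_FRCK"]] / 10.5
  q["Km_INV"] <- p[["Km_INV"]] / 10.5
  q["Km_GLCK"] <- p[["Km_GLCK"]] / 10.5
  tbl2 <- dplyr::bind_rows(tbl,
                           dplyr::bind_cols(
                             tibble::tibble(genotype = "chs", day = 0),
                             tibble::as_tibble_row(q)))
  rep2 <- check_constraints(tbl2)
  bad <- rep2[!rep2$pass, ]
  expect_true("cohesion:Km_FRCK" %in% bad$rule)
  expect_match(bad$detail[bad$rule == "cohesion:Km_FRCK"], "spread")

  # an order violation is named per condition
  q2 <- p
  q2["Km_GLCK"] <- p[["Km_FRCK"]] * 2
  tbl3 <- dplyr::bind_cols(tibble::tibble(genotype = "f3h", day = 1),
                           tibble::as_tibble_row(q2))
  rep3 <- check_constraints(tbl3)
  expect_false(rep3$pass[rep3$rule == "Km_FRCK > Km_GLCK"])
})

test_that("generated studies always satisfy their constraint set", {
  for (sd in c(2, 12)) {
    st <- generate_study(n_genotypes = 3, n_days = 3, seed = sd)
    expect_true(all(check_constraints(st$conditions)$pass))
  }
})

test_that("noise-free observations are recovered to numerical precision", {
  st <- generate_study(seed = 7, noise_cv = 0)
  obs <- condition_observations(st, 1)
  fit <- fit_condition(obs, seed = 3, starts = 4)
  ss_obs <- setNames(obs$value[match(metabolite_names(), obs$measure)],
                     metabolite_names())
  expect_lt(max(abs(fit$steady_state - ss_obs) / ss_obs), 1e-6)
  # directly observed parameters come back exactly at zero noise
  truth <- as_kinetic_params(st$conditions[1, ])
  ident <- identified_params()
  expect_lt(max(abs(fit$params[ident] - truth[ident]) / truth[ident]), 1e-6)
})

test_that("fits respect bounds and order relations and are deterministic", {
  st <- generate_study(seed = 19, noise_cv = 0.05)
  obs <- condition_observations(st, 2)
  cs <- default_constraints()
  fit1 <- fit_condition(obs, cs, seed = 5, starts = 4)
  fit2 <- fit_condition(obs, cs, seed = 5, starts = 4)
  expect_identical(as.numeric(fit1$params), as.numeric(fit2$params))

  b <- cs$bounds
  est <- fit1$params[b$parameter]
  expect_true(all(est >= b$lower - 1e-12 & est <= b$upper + 1e-12))
  expect_gt(fit1$params[["Km_FRCK"]], fit1$params[["Km_GLCK"]])
  ratio <- fit1$params[["Km_INV"]] / fit1$params[["Km_FRCK"]]
  expect_true(ratio >= 1 / 3 && ratio <= 3)
  expect_true(all(fit1$constraint_report$pass))

  # the best score is never worse than any converged start's score
  expect_true(all(fit1$score <= fit1$starts$score + 1e-9, na.rm = TRUE))

  # broom-style accessors
  td <- tidy(fit1)
  expect_setequal(td$parameter, parameter_names())
  expect_equal(nrow(glance(fit1)), 1)
})

test_that("fit_study returns a valid parameter table over conditions", {
  st <- generate_study(n_genotypes = 2, n_days = 1, seed = 23,
                       noise_cv = 0.05)
  fits <- fit_study(st$observations, seed = 2, starts = 3)
  expect_equal(nrow(fits), 2)
  expect_silent(validate_parameter_table(
    dplyr::select(fits, -"fit_score", -"ss_residual")))
  expect_true(all(fits$ss_residual < 1e-8))
})

test_that("malformed observation sets are rejected before optimization", {
  st <- generate_study(n_genotypes = 1, n_days = 1, seed = 3)
  obs <- condition_observations(st, 1)
  expect_error(fit_condition(obs[obs$measure != "G6P", ]),
               "5 metabolite pools")
  obs_bad <- obs
  obs_bad$value[1] <- -1
  expect_error(fit_condition(obs_bad), "positive")
  expect_error(fit_condition(obs, constraints = list()), "constraint_set")
})
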