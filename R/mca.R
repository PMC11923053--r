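#' Control coefficient of a parameter over a steady-state measure
#'
#' Implements the scaled control coefficient C_p^X = dln(X)/dln(p) of a
#' relaxed system: the parameter is perturbed multiplicatively by
#' `(1 +/- rel_step)`, the steady state is re-solved for each side (warm
#' started from the base steady state), and the central difference of the
#' logarithms is returned. When multiplicative steps would leave the
#' admissible range given in `bounds` (e.g. `f` near 1), the step is shrunk
#' so the evaluation stays two-sided within bounds — never silently
#' one-sided.
#'
#' An analytic alternative (`method = "analytic"`) uses the
#' implicit-function theorem at the steady state: with A the Jacobian of the
#' right-hand side w.r.t. the state and b its derivative w.r.t. the
#' parameter, the state response is dx/dp = -A^{-1} b, and flux responses
#' follow by the chain rule. It serves as an independent cross-check of the
#' finite-difference path.
#'
#' @param realization A [condition_realization()].
#' @param p Parameter name (any model parameter except `k_STAdeg`).
#' @param X Measure name (one of [measure_names()]), or several.
#' @param rel_step Relative finite-difference step (default 1e-4).
#' @param method `"fd"` (steady-state re-solve, default) or `"analytic"`.
#' @param bounds Optional bounds tibble (`parameter`, `lower`, `upper`) used
#'   to shrink the step near admissible limits; defaults to the structural
#'   ranges of `f` and `k_udp` only.
#' @param control Steady-state solver settings for the re-solves.
#' @return Named numeric of control coefficients over `X` (NA where the
#'   measure is 0 at the base point, with a warning).
#' @export
control_coefficient <- function(realization, p, X = measure_names(),
                                rel_step = 1e-4,
                                method = c("fd", "analytic"),
                                bounds = NULL,
                                control = ss_control()) {
  method <- match.arg(method)
  stopifnot(inherits(realization, "ckm_realization"))
  if (!p %in% setdiff(parameter_names(), "k_STAdeg")) {
    abort(paste0("'", p, "' is not a perturbable model parameter"))
  }
  bad <- setdiff(X, measure_names())
  if (length(bad) > 0) {
    abort(paste0("unknown measure(s): ", paste(bad, collapse = ", ")))
  }
  if (method == "fd") {
    .cc_fd(realization, p, X, rel_step, bounds, control)
  } else {
    .cc_analytic(realization, p, X)
  }
}

# Structural admissible ranges used for step shrinking when no explicit
# bounds are supplied.
.structural_bounds <- function() {
  tibble::tibble(parameter = c("f", "k_udp"),
                 lower = c(0, 0.2), upper = c(1, 0.5))
}

.shrunk_step <- function(p_val, rel_step, lower, upper) {
  h <- rel_step
  if (is.finite(upper) && p_val * (1 + h) > upper) {
    h <- min(h, upper / p_val - 1)
  }
  if (is.finite(lower) && lower > 0 && p_val * (1 - h) < lower) {
    h <- min(h, 1 - lower / p_val)
  }
  if (h <= 0) {
    abort("cannot take a two-sided step within the admissible bounds")
  }
  h
}

# Central log-log finite difference shared by the model path and by
# oracle tests on generic systems: measure_fun(p_value) must return the
# (positive) measures of the relaxed system at that parameter value.
.cc_fd_core <- function(p_val, h, measure_fun) {
  m_plus <- measure_fun(p_val * (1 + h))
  m_minus <- measure_fun(p_val * (1 - h))
  (log(m_plus) - log(m_minus)) / (log(1 + h) - log(1 - h))
}

.cc_fd <- function(realization, p, X, rel_step, bounds, control) {
  pars <- realization$params
  p_val <- pars[[p]]
  if (p_val <= 0) abort(paste0("parameter '", p, "' must be > 0 for a log derivative"))
  b <- bounds %||% .structural_bounds()
  row <- b[b$parameter == p, ]
  h <- if (nrow(row) == 1) {
    .shrunk_step(p_val, rel_step, row$lower[1], row$upper[1])
  } else {
    rel_step
  }
  out <- .cc_fd_core(p_val, h, function(pv) {
    p2 <- pars
    p2[p] <- pv
    ss <- find_steady_state(as_kinetic_params(p2),
                            initial_guess = realization$steady_state,
                            control = control)
    .measures_at(ss$state, as_kinetic_params(p2))[X]
  })
  zero <- !is.finite(out)
  if (any(zero)) {
    warn(paste0("control coefficient undefined (measure non-positive) for: ",
                paste(X[zero], collapse = ", ")))
    out[zero] <- NA_real_
  }
  setNames(as.numeric(out), X)
}

.cc_analytic <- function(realization, p, X) {
  pars <- realization$params
  s <- realization$steady_state
  mode <- realization$mode %||% "scheme"
  A <- numDeriv::jacobian(function(x) .rhs_raw(x, pars, mode), s)
  bvec <- numDeriv::jacobian(function(pv) {
    p2 <- pars
    p2[p] <- pv
    .rhs_raw(s, p2, mode)
  }, pars[[p]])
  dxdp <- -solve(A, bvec)            # 5 x 1 state response
  meas <- .measures_at(s, pars)
  dmdx <- numDeriv::jacobian(function(x) {
    .measures_at(setNames(x, metabolite_names()), pars)
  }, s)
  dmdp_direct <- numDeriv::jacobian(function(pv) {
    p2 <- pars
    p2[p] <- pv
    .measures_at(s, as_kinetic_params_relaxed(p2))
  }, pars[[p]])
  dmdp <- dmdx %*% dxdp + dmdp_direct
  rownames(dmdp) <- measure_names()
  out <- (pars[[p]] / meas[X]) * dmdp[X, 1]
  out[!is.finite(out)] <- NA_real_
  setNames(as.numeric(out), X)
}

# During derivative evaluation a parameter may be nudged marginally outside
# its admissible range (e.g. f + eps above 1); bypass range validation there.
as_kinetic_params_relaxed <- function(p) {
  structure(setNames(as.numeric(p[parameter_names()]), parameter_names()),
            class = "ckm_params")
}

#' Full control-coefficient slice for one condition
#'
#' Applies [control_coefficient()] over the full parameter-by-measure grid
#' (all 24 perturbable parameters, i.e. everything except the fixed
#' `k_STAdeg`, against the 14 reported measures). Per-entry failures are
#' recorded as `NA` with the reason.
#'
#' @inheritParams control_coefficient
#' @param parameters Parameter names to perturb.
#' @param measures Measure names to evaluate.
#' @return A tibble: `genotype`, `day`, `parameter`, `measure`, `value`,
#'   `method`, `rel_step`.
#' @export
full_mca <- function(realization,
                     parameters = setdiff(parameter_names(), "k_STAdeg"),
                     measures = measure_names(),
                     rel_step = 1e-4, method = "fd",
                     bounds = NULL, control = ss_control()) {
  stopifnot(inherits(realization, "ckm_realization"))
  purrr::map_dfr(parameters, function(pp) {
    vals <- tryCatch(
      suppressWarnings(control_coefficient(realization, pp, measures,
                                           rel_step = rel_step,
                                           method = method, bounds = bounds,
                                           control = control)),
      error = function(e) setNames(rep(NA_real_, length(measures)), measures))
    tibble::tibble(genotype = realization$genotype, day = realization$day,
                   parameter = pp, measure = measures,
                   value = as.numeric(vals), method = method,
                   rel_step = rel_step)
  })
}

#' Control coefficients for a table of conditions
#'
#' @param param_tbl Parameter table (`genotype`, `day`, parameter columns).
#' @inheritParams full_mca
#' @return Long tibble over conditions, parameters and measures.
#' @export
mca_table <- function(param_tbl,
                      parameters = setdiff(parameter_names(), "k_STAdeg"),
                      measures = measure_names(),
                      rel_step = 1e-4, method = "fd",
                      bounds = NULL, control = ss_control()) {
  param_tbl <- validate_parameter_table(param_tbl)
  purrr::map_dfr(seq_len(nrow(param_tbl)), function(i) {
    rl <- condition_realization(as_kinetic_params(param_tbl[i, ]),
                                genotype = param_tbl$genotype[i],
                                day = param_tbl$day[i],
                                control = control)
    full_mca(rl, parameters, measures, rel_step, method, bounds, control)
  })
}

#' Frequency of high-magnitude control coefficients per group
#'
#' Counts control-coefficient entries whose magnitude exceeds a threshold
#' (default 1.5, the point below which most of the coefficient distribution
#' lies), aggregated per genotype or per day. Comparison is on absolute
#' values: negative coefficients of large magnitude indicate equally strong
#' control. Missing entries are excluded and their count reported via a
#' message.
#'
#' @param cc_tbl Long control-coefficient tibble from [mca_table()].
#' @param threshold Magnitude threshold (default 1.5).
#' @param group_by `"genotype"` or `"day"`.
#' @return A tibble with the grouping column and `n_exceed`.
#' @export
high_cc_frequency <- function(cc_tbl, threshold = 1.5,
                              group_by = c("genotype", "day")) {
  group_by <- match.arg(group_by)
  stopifnot(all(c("genotype", "day", "value") %in% names(cc_tbl)))
  n_missing <- sum(is.na(cc_tbl$value))
  if (n_missing > 0) {
    inform(paste0(n_missing, " missing control-coefficient entries excluded"))
  }
  cc_tbl |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::summarise(
      n_exceed = sum(abs(.data$value) > threshold, na.rm = TRUE),
      .groups = "drop")
}

#' Summation-theorem diagnostics for a control-coefficient slice
#'
#' For every steady-state flux, the control coefficients of the ten
#' rate-scaling constants (one per rate law) must sum to 1; for every
#' steady-state concentration they must sum to 0. Both identities follow
#' from the scaling law of the rate equations (multiplying all ten constants
#' by a common factor scales every flux by that factor and leaves the steady
#' state unchanged) and hold on any valid realization; their numerical
#' residual is the primary accuracy diagnostic of the MCA implementation.
#'
#' @param cc_tbl Long control-coefficient tibble containing at least the ten
#'   rate-scaling constants for each measure.
#' @return A tibble: `genotype`, `day`, `measure`, `kind`
#'   (concentration/flux), `cc_sum`, `expected`, `abs_dev`.
#' @export
summation_check <- function(cc_tbl) {
  rsc <- rate_scaling_constants()
  conc <- metabolite_names()
  cc_tbl |>
    dplyr::filter(.data$parameter %in% rsc) |>
    dplyr::group_by(.data$genotype, .data$day, .data$measure) |>
    dplyr::summarise(cc_sum = sum(.data$value), .groups = "drop") |>
    dplyr::mutate(
      kind = ifelse(.data$measure %in% conc, "concentration", "flux"),
      expected = ifelse(.data$kind == "flux", 1, 0),
      abs_dev = abs(.data$cc_sum - .data$expected))
}
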