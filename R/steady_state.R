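#' Control settings for the steady-state solver
#'
#' @param t_final Integration horizon (h) for the relaxation stage.
#' @param tol Absolute tolerance required of every single ODE component at
#'   the returned state (µmol gDW^-1 h^-1).
#' @param max_newton Maximum damped-Newton iterations in the refinement
#'   stage.
#' @param atol,rtol Integrator tolerances passed to [deSolve::lsoda()].
#' @param mode Equation variant, see [ode_rhs()].
#' @return A list of class `"ckm_ss_control"`.
#' @export
ss_control <- function(t_final = 1e4, tol = 1e-9, max_newton = 50L,
                       atol = 1e-10, rtol = 1e-10,
                       mode = "scheme") {
  structure(list(t_final = t_final, tol = tol, max_newton = max_newton,
                 atol = atol, rtol = rtol, mode = mode),
            class = "ckm_ss_control")
}

.newton_refine <- function(s, p, control) {
  mode <- control$mode
  f <- .rhs_raw(s, p, mode)
  for (it in seq_len(control$max_newton)) {
    if (max(abs(f)) < control$tol) break
    J <- numDeriv::jacobian(function(x) .rhs_raw(x, p, mode), s)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) break
    alpha <- 1
    repeat {
      s_new <- pmax(s - alpha * step, 0)
      f_new <- .rhs_raw(s_new, p, mode)
      if (sum(f_new^2) < sum(f^2) || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    if (sum(f_new^2) >= sum(f^2)) break
    s <- s_new; f <- f_new
  }
  list(state = s, residual = max(abs(f)))
}

#' Solve the model for a steady state
#'
#' Two-stage solver: the system is first relaxed by long-horizon integration
#' (default 1e4 h, [deSolve::lsoda()]) from `initial_guess`, then the
#' endpoint is refined by a damped Newton iteration on the right-hand side
#' with a numeric Jacobian. Convergence requires every individual ODE
#' component (not just a norm) to fall below `control$tol` (default 1e-9
#' µmol gDW^-1 h^-1).
#'
#' @param params Kinetic parameters.
#' @param initial_guess Starting metabolite state; defaults to 5 µmol gDW^-1
#'   in every pool.
#' @param control Solver settings from [ss_control()].
#' @param on_fail `"error"` (default) aborts with the final residual in the
#'   message; `"return"` gives back the non-converged result flagged with
#'   `converged = FALSE`.
#' @return A list of class `"ckm_steady"` with elements `state` (named
#'   numeric), `residual` (max abs RHS component), `converged`, `mode`.
#' @examples
#' ss <- find_steady_state(default_parameters())
#' ss$state
#' @export
find_steady_state <- function(params,
                              initial_guess = c(F6P = 5, G6P = 5, Suc = 5,
                                                Frc = 5, Glc = 5),
                              control = ss_control(),
                              on_fail = c("error", "return")) {
  on_fail <- match.arg(on_fail)
  p <- as_kinetic_params(params)
  s0 <- as_metabolite_state(initial_guess)

  # Relaxation stage. Skipped when the guess already satisfies the Newton
  # basin comfortably (residual tiny), which makes warm restarts cheap.
  f0 <- .rhs_raw(s0, p, control$mode)
  s <- s0
  if (max(abs(f0)) > 1e-4) {
    # partial integration is fine here: Newton refinement finishes the job
    # and the residual check below is what decides convergence
    sol <- suppressWarnings(deSolve::lsoda(
      y = s0, times = c(0, control$t_final),
      func = function(t, y, parms) list(.rhs_raw(pmax(y, 0), p, control$mode)),
      atol = control$atol, rtol = control$rtol, maxsteps = 50000))
    s <- pmax(as.numeric(sol[nrow(sol), 1 + seq_len(5)]), 0)
    names(s) <- metabolite_names()
  }

  ref <- .newton_refine(s, p, control)
  state <- setNames(pmax(ref$state, 0), metabolite_names())
  residual <- max(abs(.rhs_raw(state, p, control$mode)))
  converged <- residual < control$tol
  if (!converged && on_fail == "error") {
    abort(paste0("steady-state solver did not converge: final residual ",
                 format(residual, digits = 4), " exceeds tolerance ",
                 format(control$tol)))
  }
  structure(list(state = state, residual = residual, converged = converged,
                 mode = control$mode),
            class = "ckm_steady")
}

#' @export
print.ckm_steady <- function(x, ...) {
  cat("<steady state> residual", format(x$residual, digits = 3),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(x$state)
  invisible(x)
}

#' Bundle parameters with their steady state as one condition realization
#'
#' A condition realization is one genotype-by-day parameterization together
#' with the steady state it implies, the unit the downstream sensitivity and
#' control analyses operate on. Requires `k_STAdeg = 0` (condition
#' realizations represent midday steady states in which net starch turnover
#' is absorbed into `k_STA`).
#'
#' @param params Kinetic parameters (with `k_STAdeg = 0`).
#' @param genotype,day Condition labels (metadata only; mutant effects are
#'   carried entirely by the parameter values).
#' @param initial_guess,control Passed to [find_steady_state()].
#' @return A list of class `"ckm_realization"`: `genotype`, `day`, `params`,
#'   `steady_state`, `residual`, `mode`.
#' @export
condition_realization <- function(params, genotype = NA_character_,
                                  day = NA_real_,
                                  initial_guess = c(F6P = 5, G6P = 5,
                                                    Suc = 5, Frc = 5,
                                                    Glc = 5),
                                  control = ss_control()) {
  p <- as_kinetic_params(params)
  if (p[["k_STAdeg"]] != 0) {
    abort("condition realizations require k_STAdeg = 0")
  }
  ss <- find_steady_state(p, initial_guess, control)
  structure(list(genotype = genotype, day = day, params = p,
                 steady_state = ss$state, residual = ss$residual,
                 mode = control$mode),
            class = "ckm_realization")
}

#' @export
print.ckm_realization <- function(x, ...) {
  cat("<condition realization>", x$genotype, "day", x$day,
      "| residual", format(x$residual, digits = 3), "\n")
  print(x$steady_state)
  invisible(x)
}

#' Solve steady states for a table of conditions
#'
#' Takes a parameter table (one row per condition: `genotype`, `day` and the
#' 25 parameter columns) and appends the steady-state concentrations plus the
#' solver residual.
#'
#' @param param_tbl Parameter table, see [read_parameter_table()].
#' @param control Solver settings.
#' @return The input tibble with added columns `F6P, G6P, Suc, Frc, Glc` and
#'   `ss_residual`.
#' @export
add_steady_states <- function(param_tbl, control = ss_control()) {
  param_tbl <- validate_parameter_table(param_tbl)
  ss <- purrr::map(seq_len(nrow(param_tbl)), function(i) {
    find_steady_state(as_kinetic_params(param_tbl[i, ]), control = control)
  })
  states <- purrr::map_dfr(ss, ~ tibble::as_tibble_row(.x$state))
  dplyr::bind_cols(param_tbl, states,
                   tibble::tibble(ss_residual = purrr::map_dbl(ss, "residual")))
}

#' Simulate a time course, optionally with a net-photosynthesis step
#'
#' Integrates the model from `state0` over `times` (hours). When
#' `perturb_time` is given, `k_NPS` is rescaled by `perturb_factor` at that
#' instant (an instantaneous step, the protocol used for sensitivity
#' scoring).
#'
#' @param params Kinetic parameters.
#' @param state0 Initial metabolite state.
#' @param times Numeric vector of output times (h), starting at 0.
#' @param perturb_time Time (h) at which `k_NPS` is rescaled, or `NULL`.
#' @param perturb_factor Multiplicative factor applied to `k_NPS`.
#' @param mode Equation variant, see [ode_rhs()].
#' @param atol,rtol Integrator tolerances.
#' @return A tibble with columns `time`, `F6P`, `G6P`, `Suc`, `Frc`, `Glc`.
#' @export
simulate_timecourse <- function(params, state0, times,
                                perturb_time = NULL, perturb_factor = 1,
                                mode = "scheme",
                                atol = 1e-10, rtol = 1e-10) {
  p <- as_kinetic_params(params)
  s0 <- as_metabolite_state(state0)
  times <- sort(unique(as.numeric(times)))
  stopifnot(length(times) >= 2, times[1] >= 0)

  run <- function(p_use, y0, tt) {
    if (length(tt) == 1) {
      return(matrix(c(tt, y0), nrow = 1,
                    dimnames = list(NULL, c("time", metabolite_names()))))
    }
    sol <- deSolve::lsoda(
      y = y0, times = tt,
      func = function(t, y, parms) list(.rhs_raw(pmax(y, 0), p_use, mode)),
      atol = atol, rtol = rtol)
    colnames(sol) <- c("time", metabolite_names())
    sol
  }

  if (is.null(perturb_time) || perturb_factor == 1) {
    out <- run(p, s0, times)
  } else {
    stopifnot(perturb_time >= times[1], perturb_time <= times[length(times)])
    t_pre <- unique(c(times[times <= perturb_time], perturb_time))
    t_post <- unique(c(perturb_time, times[times > perturb_time]))
    pre <- run(p, s0, t_pre)
    p2 <- p
    p2["k_NPS"] <- p[["k_NPS"]] * perturb_factor
    y_mid <- setNames(as.numeric(pre[nrow(pre), -1]), metabolite_names())
    post <- run(as_kinetic_params(p2), y_mid, t_post)
    keep_pre <- pre[pre[, "time"] %in% times, , drop = FALSE]
    keep_post <- post[post[, "time"] %in% times[times > perturb_time], ,
                      drop = FALSE]
    out <- rbind(keep_pre, keep_post)
  }
  tibble::as_tibble(as.data.frame(out))
}
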