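#' Perturbation protocol for sensitivity scoring
#'
#' The default protocol mirrors the study design: net photosynthesis is
#' increased or decreased by 5 to 30 percent in 5 percent increments (N = 12
#' perturbations), each simulated as a 4 h time course in which the step is
#' applied after a 2 h pre-perturbation window; the perturbed value x_i of
#' every measure is read at the end of the window (2 h after the step).
#'
#' @param relative_changes Signed fractional changes of the net
#'   photosynthesis scale `k_NPS`. Must all be > -1; a change of exactly 0
#'   triggers a warning because its |log2(1)| = 0 inner term annihilates the
#'   geometric-mean score for every measure.
#' @param pre_perturbation_time Time (h) at which the step is applied.
#' @param total_time End of the simulated window (h); the readout time.
#' @return A list of class `"ckm_protocol"`.
#' @export
perturbation_protocol <- function(relative_changes =
                                    c(-6:-1, 1:6) * 0.05,
                                  pre_perturbation_time = 2,
                                  total_time = 4) {
  relative_changes <- as.numeric(relative_changes)
  if (length(relative_changes) < 1) {
    abort("at least one relative change is required")
  }
  if (any(relative_changes <= -1)) {
    abort("relative changes must be > -1 (nps cannot be negated)")
  }
  if (any(relative_changes == 0)) {
    warn(paste("a relative change of 0 contributes |log2(1)| = 0 and",
               "annihilates the geometric-mean score for every measure"))
  }
  if (!(total_time > pre_perturbation_time && pre_perturbation_time > 0)) {
    abort("must have total_time > pre_perturbation_time > 0")
  }
  structure(list(relative_changes = relative_changes,
                 pre_perturbation_time = pre_perturbation_time,
                 total_time = total_time),
            class = "ckm_protocol")
}

#' Sensitivity score of a measure under a set of perturbations
#'
#' The score is the geometric mean of the absolute log2
#' perturbation-normalized fold changes,
#' \deqn{\gamma = \sqrt[N]{\prod_i \left| \log_2\!\left(\frac{x_i}{x_0}\cdot
#'       \frac{r_0}{r_i}\right)\right|},}
#' where x_0 is the unperturbed value of the measure, x_i its value after
#' perturbation i, and r_i/r_0 the corresponding ratio of net photosynthesis
#' rates. A proportional response (x changing exactly like the rate) scores
#' 0; a measure that doubles while the rate is unchanged scores 1.
#'
#' @param x0 Unperturbed value (> 0).
#' @param xi_list Values after each perturbation (> 0), length N.
#' @param r0 Unperturbed rate (> 0).
#' @param ri_list Perturbed rates (> 0), length N.
#' @return Non-negative score.
#' @examples
#' gamma_score(1, 2, 1, 1)              # doubles, rate unchanged -> 1
#' gamma_score(1, c(2, 4), 1, c(1, 1))  # inner terms 1 and 2 -> sqrt(2)
#' @export
gamma_score <- function(x0, xi_list, r0, ri_list) {
  xi_list <- as.numeric(xi_list)
  ri_list <- as.numeric(ri_list)
  if (length(xi_list) != length(ri_list) || length(xi_list) < 1) {
    abort("xi_list and ri_list must have equal length >= 1")
  }
  vals <- c(x0, xi_list, r0, ri_list)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("all values entering the sensitivity score must be strictly positive")
  }
  inner <- abs(log2((xi_list / x0) * (r0 / ri_list)))
  prod(inner)^(1 / length(inner))
}

# Measures (concentrations + reported fluxes) at a state, perturbed params.
.measures_at <- function(state, params, pgi_report = "rPGI1") {
  v <- compute_fluxes(state, params, pgi_report = pgi_report)
  m <- c(state[c("F6P", "G6P", "Frc", "Glc", "Suc")],
         v[c("rSPS", "rPGI", "rFRCK", "rGLCK", "r1", "rINV", "r2",
             "rSTAsyn", "rANTHO")])
  names(m) <- measure_names()
  m
}

#' Run the net-photosynthesis perturbation sweep on one condition
#'
#' Starting from the condition's steady state, `k_NPS` is rescaled by each
#' relative change of the protocol at the pre-perturbation time, the system
#' is integrated to the end of the window, and all 14 measures (5
#' concentrations, 9 reported fluxes) are read out there. [gamma_score()] is
#' then applied per measure, with the unperturbed steady-state value as x_0
#' and the `k_NPS` ratio 1 + change as r_i/r_0 (identical to the rNPS ratio,
#' since rNPS = k_NPS/6). A measure that is non-positive at any readout is
#' reported as `NA` with a warning rather than silently clamped.
#'
#' @param realization A [condition_realization()].
#' @param protocol A [perturbation_protocol()].
#' @param pgi_report Which PGI branch the reported `rPGI` measure uses.
#' @param atol,rtol Integrator tolerances.
#' @return A list of class `"ckm_sweep"`: `gamma` (named numeric over the 14
#'   measures), `timecourses` (long tibble: `relative_change`, `time`,
#'   measure columns), `readouts` (tibble of x_i per measure and change),
#'   `baseline` (x_0), `protocol`, `genotype`, `day`.
#' @export
run_perturbation_sweep <- function(realization,
                                   protocol = perturbation_protocol(),
                                   pgi_report = "rPGI1",
                                   atol = 1e-10, rtol = 1e-10) {
  stopifnot(inherits(realization, "ckm_realization"))
  if (!inherits(protocol, "ckm_protocol")) {
    abort("protocol must be created with perturbation_protocol()")
  }
  p <- realization$params
  ss <- realization$steady_state
  mode <- realization$mode %||% "scheme"
  x0 <- .measures_at(ss, p, pgi_report)

  times <- sort(unique(c(seq(0, protocol$total_time, by = 0.1),
                         protocol$pre_perturbation_time,
                         protocol$total_time)))
  runs <- purrr::map(protocol$relative_changes, function(d) {
    if (d == 0) {
      # the system sits at steady state: the unperturbed trajectory is
      # constant, so the readout equals the baseline exactly and its inner
      # |log2| term is exactly 0 (the geometric-mean annihilator)
      tc <- tibble::as_tibble(
        cbind(time = times,
              matrix(ss, nrow = length(times), ncol = 5, byrow = TRUE,
                     dimnames = list(NULL, metabolite_names()))))
      return(list(tc = dplyr::mutate(tc, relative_change = d, .before = 1),
                  xi = x0))
    }
    tc <- simulate_timecourse(p, ss, times,
                              perturb_time = protocol$pre_perturbation_time,
                              perturb_factor = 1 + d, mode = mode,
                              atol = atol, rtol = rtol)
    p_i <- p
    p_i["k_NPS"] <- p[["k_NPS"]] * (1 + d)
    end_state <- as_metabolite_state(tc[nrow(tc), metabolite_names()])
    xi <- .measures_at(pmax(end_state, 0), as_kinetic_params(p_i), pgi_report)
    list(tc = dplyr::mutate(tc, relative_change = d, .before = 1),
         xi = xi)
  })

  readouts <- purrr::map_dfr(seq_along(runs), function(i) {
    tibble::as_tibble_row(runs[[i]]$xi) |>
      dplyr::mutate(relative_change = protocol$relative_changes[i],
                    .before = 1)
  })
  ri <- 1 + protocol$relative_changes

  gamma <- purrr::map_dbl(measure_names(), function(m) {
    xi <- readouts[[m]]
    if (any(!is.finite(xi)) || any(xi <= 0) || x0[[m]] <= 0) {
      return(NA_real_)
    }
    gamma_score(x0[[m]], xi, 1, ri)
  })
  names(gamma) <- measure_names()
  if (anyNA(gamma)) {
    warn(paste0("sensitivity undefined (non-positive readout) for: ",
                paste(names(gamma)[is.na(gamma)], collapse = ", ")))
  }

  structure(list(gamma = gamma,
                 timecourses = purrr::map_dfr(runs, "tc"),
                 readouts = readouts,
                 baseline = x0,
                 protocol = protocol,
                 genotype = realization$genotype,
                 day = realization$day,
                 pgi_report = pgi_report),
            class = "ckm_sweep")
}

#' @export
print.ckm_sweep <- function(x, ...) {
  cat("<nps perturbation sweep>", x$genotype, "day", x$day, "| N =",
      length(x$protocol$relative_changes), "\n")
  print(round(x$gamma, 4))
  invisible(x)
}

#' High-light exposure variant of the sensitivity score
#'
#' Emulates a shift to elevated light: `k_NPS` is stepped once by
#' `step_fraction` (default +25 percent, the modelled effect of raising light
#' from 100 to ~250 µmol m^-2 s^-1 at 4 °C) and the measures are sampled at
#' each readout time *after* the step (defaults 3 h and 6 h). The sampled
#' durations play the role of the perturbations i in [gamma_score()], with
#' r_i/r_0 = 1 + step_fraction for all of them.
#'
#' @param realization A [condition_realization()].
#' @param step_fraction Single signed fractional change of `k_NPS` (> -1).
#' @param readout_times Durations after the step (h) at which x_i is read.
#' @param pgi_report,atol,rtol As in [run_perturbation_sweep()].
#' @return Named numeric of gamma values over the 14 measures, with the
#'   sampled readouts in attribute `readouts`.
#' @export
run_high_light_protocol <- function(realization, step_fraction = 0.25,
                                    readout_times = c(3, 6),
                                    pgi_report = "rPGI1",
                                    atol = 1e-10, rtol = 1e-10) {
  stopifnot(inherits(realization, "ckm_realization"))
  if (length(step_fraction) != 1 || step_fraction <= -1) {
    abort("step_fraction must be a single value > -1")
  }
  readout_times <- sort(as.numeric(readout_times))
  if (length(readout_times) < 1 || any(readout_times <= 0)) {
    abort("readout_times must be positive durations after the step")
  }
  p <- realization$params
  ss <- realization$steady_state
  mode <- realization$mode %||% "scheme"
  x0 <- .measures_at(ss, p, pgi_report)

  if (step_fraction == 0) {
    gamma <- setNames(rep(0, length(measure_names())), measure_names())
    attr(gamma, "readouts") <- NULL
    return(gamma)
  }

  p_i <- p
  p_i["k_NPS"] <- p[["k_NPS"]] * (1 + step_fraction)
  tc <- simulate_timecourse(as_kinetic_params(p_i), ss,
                            times = c(0, readout_times),
                            mode = mode, atol = atol, rtol = rtol)
  readouts <- purrr::map_dfr(readout_times, function(tt) {
    st <- as_metabolite_state(tc[tc$time == tt, metabolite_names()])
    tibble::as_tibble_row(.measures_at(st, as_kinetic_params(p_i),
                                       pgi_report)) |>
      dplyr::mutate(duration = tt, .before = 1)
  })
  ri <- rep(1 + step_fraction, length(readout_times))
  gamma <- purrr::map_dbl(measure_names(), function(m) {
    xi <- readouts[[m]]
    if (any(!is.finite(xi)) || any(xi <= 0) || x0[[m]] <= 0) {
      return(NA_real_)
    }
    gamma_score(x0[[m]], xi, 1, ri)
  })
  names(gamma) <- measure_names()
  if (anyNA(gamma)) {
    warn(paste0("sensitivity undefined (non-positive readout) for: ",
                paste(names(gamma)[is.na(gamma)], collapse = ", ")))
  }
  attr(gamma, "readouts") <- readouts
  gamma
}

#' Sensitivity matrix over a table of conditions
#'
#' Applies [run_perturbation_sweep()] to every row of a parameter table and
#' assembles the conditions-by-measures sensitivity matrix (the input of
#' [pca_gamma()]).
#'
#' @param param_tbl Parameter table (`genotype`, `day`, 25 parameter
#'   columns), e.g. from [generate_study()] or [read_parameter_table()].
#' @param protocol A [perturbation_protocol()].
#' @param pgi_report Which PGI branch the reported `rPGI` measure uses.
#' @param control Steady-state solver settings.
#' @return A tibble with columns `genotype`, `day` and the 14 measures,
#'   carrying the protocol in attribute `protocol`.
#' @export
sensitivity_sweep <- function(param_tbl, protocol = perturbation_protocol(),
                              pgi_report = "rPGI1",
                              control = ss_control()) {
  param_tbl <- validate_parameter_table(param_tbl)
  rows <- purrr::map_dfr(seq_len(nrow(param_tbl)), function(i) {
    rl <- condition_realization(as_kinetic_params(param_tbl[i, ]),
                                genotype = param_tbl$genotype[i],
                                day = param_tbl$day[i],
                                control = control)
    sw <- run_perturbation_sweep(rl, protocol, pgi_report = pgi_report)
    dplyr::bind_cols(tibble::tibble(genotype = rl$genotype, day = rl$day),
                     tibble::as_tibble_row(sw$gamma))
  })
  attr(rows, "protocol") <- protocol
  attr(rows, "pgi_report") <- pgi_report
  rows
}
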