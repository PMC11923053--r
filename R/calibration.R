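#' Constraint set for parameter calibration
#'
#' Bundles the box bounds (Km and Ki values share common bounds across all
#' conditions), the literature-derived order relations between Km symbols,
#' the "Km_INV similar or close to Km_FRCK" ratio band, and the
#' cross-condition cohesion factor (all fitted Km/Ki values of one symbol
#' must lie within one order of magnitude across conditions).
#'
#' The literature relation involving Km_PGI is contradictory as printed in
#' its source ("Km_FRCK > Km_PGI > Km_FRCK"); only the unambiguous relation
#' Km_FRCK > Km_GLCK ships as default, and both readings of the PGI relation
#' are available as explicit presets: `pgi_preset = "pgi_below_frck"` adds
#' (Km_FRCK > Km_PGI), `"pgi_above_frck"` adds (Km_PGI > Km_FRCK).
#'
#' @param bounds Tibble `parameter`, `lower`, `upper`
#'   (default [default_parameter_bounds()]).
#' @param order_relations List of `c(A, ">", B)` triples over parameter
#'   names. Must be acyclic.
#' @param ratio_bands Named list; each entry `list(num =, den =, band =
#'   c(lo, hi))` constrains `num/den` to the band. Default keeps Km_INV
#'   within a factor 3 of Km_FRCK.
#' @param cohesion_factor Maximum allowed max/min spread of each Km/Ki
#'   symbol across conditions (default 10).
#' @param pgi_preset `"none"` (default), `"pgi_below_frck"` or
#'   `"pgi_above_frck"`.
#' @return A list of class `"ckm_constraints"`.
#' @export
constraint_set <- function(bounds = default_parameter_bounds(),
                           order_relations = list(c("Km_FRCK", ">", "Km_GLCK")),
                           ratio_bands = list(
                             Km_INV_vs_Km_FRCK = list(num = "Km_INV",
                                                      den = "Km_FRCK",
                                                      band = c(1 / 3, 3))),
                           cohesion_factor = 10,
                           pgi_preset = c("none", "pgi_below_frck",
                                          "pgi_above_frck")) {
  pgi_preset <- match.arg(pgi_preset)
  if (pgi_preset == "pgi_below_frck") {
    order_relations <- c(order_relations, list(c("Km_FRCK", ">", "Km_PGI")))
  } else if (pgi_preset == "pgi_above_frck") {
    order_relations <- c(order_relations, list(c("Km_PGI", ">", "Km_FRCK")))
  }
  stopifnot(all(c("parameter", "lower", "upper") %in% names(bounds)))
  for (rel in order_relations) {
    if (length(rel) != 3 || rel[2] != ">") {
      abort("order relations must be triples c(A, '>', B)")
    }
    if (!all(rel[c(1, 3)] %in% bounds$parameter)) {
      abort(paste0("order relation names unknown parameter: ",
                   paste(rel[c(1, 3)], collapse = ", ")))
    }
  }
  if (length(order_relations) > 0) {
    edges <- do.call(rbind, lapply(order_relations,
                                   function(r) c(r[1], r[3])))
    g <- igraph::graph_from_data_frame(as.data.frame(edges), directed = TRUE)
    if (!igraph::is_dag(g)) abort("order relations contain a cycle")
  }
  # feasibility: for A > B the admissible boxes must overlap appropriately
  for (rel in order_relations) {
    ua <- bounds$upper[bounds$parameter == rel[1]]
    lb <- bounds$lower[bounds$parameter == rel[3]]
    if (ua <= lb) {
      abort(paste0("infeasible order relation ", rel[1], " > ", rel[3],
                   " under the declared bounds"))
    }
  }
  if (cohesion_factor < 1) abort("cohesion_factor must be >= 1")
  structure(list(bounds = bounds, order_relations = order_relations,
                 ratio_bands = ratio_bands,
                 cohesion_factor = cohesion_factor,
                 pgi_preset = pgi_preset),
            class = "ckm_constraints")
}

#' @rdname constraint_set
#' @export
default_constraints <- function() constraint_set()

.relations_ok <- function(p, constraints) {
  ok <- vapply(constraints$order_relations,
               function(r) p[[r[1]]] > p[[r[3]]], logical(1))
  bands <- vapply(constraints$ratio_bands, function(b) {
    ratio <- p[[b$num]] / p[[b$den]]
    ratio >= b$band[1] && ratio <= b$band[2]
  }, logical(1))
  all(ok) && all(bands)
}

#' Check calibration constraints on a set of condition parameterizations
#'
#' Verifies, per condition, the bounds and order relations (including ratio
#' bands) and, across conditions, the cohesion rule that each Km/Ki symbol
#' spans at most `cohesion_factor` (default one order of magnitude) between
#' its smallest and largest fitted value. A pure report; nothing errors.
#'
#' @param param_tbl Parameter table (one row per condition).
#' @param constraints A [constraint_set()].
#' @return A tibble: `rule`, `scope` (condition label or "across-conditions"),
#'   `pass`, `detail` (offending values where failing).
#' @export
check_constraints <- function(param_tbl, constraints = default_constraints()) {
  param_tbl <- validate_parameter_table(param_tbl)
  lab <- paste0(param_tbl$genotype, ":day", param_tbl$day)
  out <- list()

  b <- constraints$bounds
  for (i in seq_len(nrow(param_tbl))) {
    p <- as_kinetic_params(param_tbl[i, ])
    inb <- p[b$parameter] >= b$lower & p[b$parameter] <= b$upper
    out[[length(out) + 1]] <- tibble::tibble(
      rule = "bounds", scope = lab[i], pass = all(inb),
      detail = if (all(inb)) "" else
        paste(b$parameter[!inb], collapse = ", "))
    for (rel in constraints$order_relations) {
      ok <- p[[rel[1]]] > p[[rel[3]]]
      out[[length(out) + 1]] <- tibble::tibble(
        rule = paste(rel[1], ">", rel[3]), scope = lab[i], pass = ok,
        detail = if (ok) "" else
          paste0(rel[1], "=", signif(p[[rel[1]]], 4), ", ",
                 rel[3], "=", signif(p[[rel[3]]], 4)))
    }
    for (nm in names(constraints$ratio_bands)) {
      bd <- constraints$ratio_bands[[nm]]
      ratio <- p[[bd$num]] / p[[bd$den]]
      ok <- ratio >= bd$band[1] && ratio <= bd$band[2]
      out[[length(out) + 1]] <- tibble::tibble(
        rule = nm, scope = lab[i], pass = ok,
        detail = if (ok) "" else paste0("ratio=", signif(ratio, 4)))
    }
  }

  km_ki <- grep("^(Km|Ki)", parameter_names(), value = TRUE)
  for (sym in km_ki) {
    vals <- param_tbl[[sym]]
    spread <- max(vals) / min(vals)
    ok <- spread <= constraints$cohesion_factor
    out[[length(out) + 1]] <- tibble::tibble(
      rule = paste0("cohesion:", sym), scope = "across-conditions",
      pass = ok,
      detail = if (ok) "" else paste0("spread=", signif(spread, 4)))
  }
  dplyr::bind_rows(out)
}

# ---------------------------------------------------------------------------
# Fitting

.free_params <- function() setdiff(parameter_names(), "k_STAdeg")

# Observation tables are long: columns measure, value, sigma (+ optional
# condition metadata). Recognized measures: the five pools, flux targets
# rNPS and rSTAsyn, and enzyme-activity observations named after the vmax
# parameters they measure.
.obs_split <- function(observations) {
  stopifnot(all(c("measure", "value") %in% names(observations)))
  if (!"sigma" %in% names(observations)) observations$sigma <- NA_real_
  conc <- observations[observations$measure %in% metabolite_names(), ]
  if (nrow(conc) != 5) {
    abort("observations must contain exactly the 5 metabolite pools")
  }
  if (any(observations$value <= 0)) {
    abort("all observations must be positive")
  }
  list(conc = conc,
       flux = observations[observations$measure %in% c("rNPS", "rSTAsyn"), ],
       act = observations[observations$measure %in%
                            grep("^vmax", parameter_names(), value = TRUE), ])
}

# cv used for log-residual weighting, floored so zero-noise data stays finite
.obs_cv <- function(obs, floor = 0.02) {
  cv <- obs$sigma / obs$value
  cv[!is.finite(cv) | cv <= 0] <- floor
  pmax(cv, floor)
}

.fit_residuals <- function(theta, free, fixed, obs, mode, w_ss = 100,
                           w_order = 100, constraints = NULL,
                           ridge = NULL) {
  p <- fixed
  p[free] <- theta
  s <- setNames(obs$conc_value, obs$conc_measure)[metabolite_names()]
  rhs <- .rhs_raw(s, p, mode)
  scale <- max(p[["k_NPS"]] / 6, 1e-6)
  res <- w_ss * rhs / scale

  if (nrow(obs$flux) > 0) {
    fl <- compute_fluxes(s, as_kinetic_params_relaxed(p))
    res <- c(res, log(pmax(fl[obs$flux$measure], 1e-12) / obs$flux$value) /
               obs$flux_cv)
  }
  if (nrow(obs$act) > 0) {
    res <- c(res, log(p[obs$act$measure] / obs$act$value) / obs$act_cv)
  }
  if (!is.null(constraints)) {
    for (rel in constraints$order_relations) {
      # hinge with a 10% separation margin: a flat penalty at equality would
      # let the optimum sit exactly on the (strict) relation boundary
      gap <- log(p[[rel[1]]]) - log(p[[rel[3]]])
      res <- c(res, w_order * min(gap - log(1.1), 0))
    }
    for (bd in constraints$ratio_bands) {
      lr <- log(p[[bd$num]] / p[[bd$den]])
      res <- c(res, w_order * max(lr - log(bd$band[2]), 0),
               w_order * min(lr - log(bd$band[1]), 0))
    }
  }
  if (!is.null(ridge)) {
    # mild shrinkage of every free parameter towards the (log) box centre:
    # keeps the least-squares problem over-determined and selects a unique
    # representative of the under-identified directions
    res <- c(res, ridge$w * (log(theta) - ridge$center) / ridge$range)
  }
  unname(res)
}

# Draw multi-start points: Latin hypercube in the log-bound box, resampled
# (with budget) until order relations and ratio bands hold.
.draw_starts <- function(n, free, constraints) {
  b <- constraints$bounds
  lo <- setNames(b$lower, b$parameter)[free]
  hi <- setNames(b$upper, b$parameter)[free]
  draw <- function(n) {
    u <- lhs::randomLHS(n, length(free))
    th <- t(apply(u, 1, function(r) exp(log(lo) + r * (log(hi) - log(lo)))))
    colnames(th) <- free
    th
  }
  starts <- draw(n * 4)
  ok <- apply(starts, 1, function(r) .relations_ok(as.list(r), constraints))
  starts <- starts[ok, , drop = FALSE]
  tries <- 0
  while (nrow(starts) < n && tries < 20) {
    more <- draw(n * 4)
    ok <- apply(more, 1, function(r) .relations_ok(as.list(r), constraints))
    starts <- rbind(starts, more[ok, , drop = FALSE])
    tries <- tries + 1
  }
  if (nrow(starts) < 1) {
    abort("could not draw constraint-respecting starting points; check feasibility")
  }
  starts[seq_len(min(n, nrow(starts))), , drop = FALSE]
}

#' Fit one condition's parameters under the steady-state assumption
#'
#' Bounded multi-start least squares (Levenberg-Marquardt via
#' [minpack.lm::nls.lm()]) implementing the per-condition calibration
#' strategy: parameters are sought such that the observed metabolite pools
#' constitute a steady state of the model, while weighted log-residuals pull
#' the nps-derived influx (`rNPS` target), the starch net-balance rate
#' (`rSTAsyn` target) and any enzyme-activity observations (named after the
#' vmax parameter they measure) towards their observed values. Optimization
#' runs on the log scale (observations span orders of magnitude); weights
#' default to 1/cv per observation; order relations and ratio bands are
#' enforced via hinge penalties and re-checked on the returned optimum.
#' `k_STAdeg` is fixed at 0. Multi-start points are Latin-hypercube draws
#' within the (log) bounds, resampled to respect the order relations; one
#' additional data-informed start seeds `k_NPS`, `k_STA` and the vmax values
#' from the corresponding observations. Deterministic given `seed`.
#'
#' The fitted steady state is obtained by re-solving the model at the
#' optimum (warm-started from the observed pools) and the reported score is
#' the weighted sum of squared log-residuals between that steady state and
#' the observations, plus the target residuals.
#'
#' @param observations Long tibble for one condition: columns `measure`,
#'   `value`, `sigma` (replicate dispersion; may be 0/NA for noise-free
#'   data). Must contain all five pools; `rNPS`, `rSTAsyn` and
#'   `vmax_*` activity rows are optional but sharpen identifiability.
#' @param constraints A [constraint_set()]; validated before optimization.
#' @param seed Integer seed controlling the multi-start design.
#' @param starts Number of optimization starts (default 50).
#' @param mode Equation variant, see [ode_rhs()].
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param w_ss Weight of the (scaled) steady-state residuals.
#' @return A list of class `"ckm_fit"`: `params` (fitted `"ckm_params"`),
#'   `score`, `steady_state`, `ss_residual`, `converged`,
#'   `constraint_report`, `starts` (per-start diagnostics tibble), `seed`.
#' @export
fit_condition <- function(observations, constraints = default_constraints(),
                          seed = 1L, starts = 50L, mode = "scheme",
                          maxiter = 120L, w_ss = 100) {
  constraints <- if (inherits(constraints, "ckm_constraints")) constraints
  else abort("constraints must be a constraint_set()")
  sp <- .obs_split(observations)
  obs <- list(conc_measure = sp$conc$measure, conc_value = sp$conc$value,
              flux = sp$flux, act = sp$act,
              flux_cv = .obs_cv(sp$flux), act_cv = .obs_cv(sp$act))
  free <- .free_params()
  b <- constraints$bounds
  lo <- setNames(b$lower, b$parameter)[free]
  hi <- setNames(b$upper, b$parameter)[free]
  fixed <- setNames(rep(0, length(parameter_names())), parameter_names())

  set.seed(seed)
  th0 <- .draw_starts(starts, free, constraints)
  # data-informed start: centre of the box with directly observed scales;
  # Km values separated so the order relations hold strictly from the start
  informed <- exp((log(lo) + log(hi)) / 2)
  informed["f"] <- 0.5
  informed["k_udp"] <- 0.35
  informed["Km_GLCK"] <- 2
  informed["Km_FRCK"] <- 5
  informed["Km_INV"] <- 5
  if ("rNPS" %in% obs$flux$measure) {
    informed["k_NPS"] <- min(max(6 * obs$flux$value[obs$flux$measure == "rNPS"],
                                 lo["k_NPS"]), hi["k_NPS"])
  }
  if ("rSTAsyn" %in% obs$flux$measure) {
    g6p <- obs$conc_value[obs$conc_measure == "G6P"]
    informed["k_STA"] <- min(max(obs$flux$value[obs$flux$measure == "rSTAsyn"] / g6p,
                                 lo["k_STA"]), hi["k_STA"])
  }
  for (i in seq_len(nrow(obs$act))) {
    nm <- obs$act$measure[i]
    informed[nm] <- min(max(obs$act$value[i], lo[nm]), hi[nm])
  }
  if (.relations_ok(as.list(informed), constraints)) {
    th0 <- rbind(informed[free], th0)
  }

  ridge <- list(center = (log(lo) + log(hi)) / 2,
                range = pmax(log(hi) - log(lo), 1e-6),
                w = 0.002)

  run_start <- function(theta0) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = log(theta0),
        fn = function(lt) .fit_residuals(exp(lt), free, fixed, obs, mode,
                                         w_ss = w_ss,
                                         constraints = constraints,
                                         ridge = ridge),
        lower = log(lo), upper = log(hi),
        control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                             ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    theta <- exp(fit$par)
    p <- fixed
    p[free] <- theta
    if (!.relations_ok(as.list(p), constraints)) return(NULL)
    ss <- tryCatch(
      find_steady_state(as_kinetic_params_relaxed(p),
                        initial_guess = setNames(obs$conc_value,
                                                 obs$conc_measure),
                        control = ss_control(mode = mode),
                        on_fail = "return"),
      error = function(e) NULL)
    if (is.null(ss) || !ss$converged) return(NULL)
    conc_res <- log(pmax(ss$state[obs$conc_measure], 1e-12) / obs$conc_value)
    score <- sum((conc_res / 0.05)^2) +
      sum(.fit_residuals(theta, free, fixed, obs, mode, w_ss = 0,
                         constraints = NULL)[-(1:5)]^2)
    list(params = p, ss = ss, score = score,
         lm_info = fit$info, lm_dev = fit$deviance)
  }

  results <- purrr::map(seq_len(nrow(th0)),
                        function(i) run_start(th0[i, ]))
  diag_tbl <- tibble::tibble(
    start = seq_along(results),
    converged = !purrr::map_lgl(results, is.null),
    score = purrr::map_dbl(results, ~ if (is.null(.x)) NA_real_ else .x$score))
  results <- purrr::compact(results)
  if (length(results) == 0) {
    abort(paste0("all ", nrow(th0), " optimization starts failed; ",
                 "per-start diagnostics: ",
                 paste(utils::capture.output(print(diag_tbl)), collapse = "\n")))
  }
  best <- results[[which.min(purrr::map_dbl(results, "score"))]]
  params <- as_kinetic_params(best$params)
  one_row <- dplyr::bind_cols(tibble::tibble(genotype = "fit", day = 0),
                              tibble::as_tibble_row(setNames(
                                as.numeric(params), names(params))))
  structure(list(params = params, score = best$score,
                 steady_state = best$ss$state,
                 ss_residual = best$ss$residual,
                 converged = best$ss$converged,
                 constraint_report = check_constraints(
                   one_row, constraints),
                 starts = diag_tbl, seed = seed, mode = mode),
            class = "ckm_fit")
}

#' @export
print.ckm_fit <- function(x, ...) {
  cat("<condition fit> score", format(x$score, digits = 4),
      "| steady-state residual", format(x$ss_residual, digits = 3), "\n")
  invisible(x)
}

#' @method tidy ckm_fit
#' @export
tidy.ckm_fit <- function(x, ...) {
  b <- default_parameter_bounds()
  tibble::tibble(parameter = names(x$params),
                 estimate = as.numeric(x$params)) |>
    dplyr::left_join(b, by = "parameter") |>
    dplyr::mutate(at_bound = .data$estimate <= .data$lower * (1 + 1e-8) |
                    .data$estimate >= .data$upper * (1 - 1e-8))
}

#' @method glance ckm_fit
#' @export
glance.ckm_fit <- function(x, ...) {
  tibble::tibble(score = x$score, ss_residual = x$ss_residual,
                 converged = x$converged,
                 n_starts = nrow(x$starts),
                 n_starts_converged = sum(x$starts$converged),
                 seed = x$seed)
}

#' Fit every condition of an observation table
#'
#' Applies [fit_condition()] per condition (grouping on `genotype` and
#' `day`) and returns the fitted parameters in the same parameter-table
#' format the rest of the package consumes, plus fit scores. Per-condition
#' seeds are derived deterministically from `seed`.
#'
#' @param observations Long tibble with columns `genotype`, `day`,
#'   `measure`, `value`, `sigma`.
#' @inheritParams fit_condition
#' @return A tibble: `genotype`, `day`, 25 parameter columns, `fit_score`,
#'   `ss_residual`.
#' @export
fit_study <- function(observations, constraints = default_constraints(),
                      seed = 1L, starts = 50L, mode = "scheme",
                      maxiter = 120L) {
  stopifnot(all(c("genotype", "day", "measure", "value") %in%
                  names(observations)))
  conds <- dplyr::distinct(observations, .data$genotype, .data$day)
  purrr::map_dfr(seq_len(nrow(conds)), function(i) {
    oo <- dplyr::filter(observations,
                        .data$genotype == conds$genotype[i],
                        .data$day == conds$day[i])
    fit <- fit_condition(oo, constraints,
                         seed = (seed + 7919L * i) %% .Machine$integer.max,
                         starts = starts, mode = mode, maxiter = maxiter)
    dplyr::bind_cols(
      tibble::tibble(genotype = conds$genotype[i], day = conds$day[i]),
      tibble::as_tibble_row(setNames(as.numeric(fit$params),
                                     names(fit$params))),
      tibble::tibble(fit_score = fit$score, ss_residual = fit$ss_residual))
  })
}
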