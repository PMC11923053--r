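#' Names of the model's metabolite pools, parameters, fluxes and measures
#'
#' The model tracks five pools (F6P, G6P, Suc, Frc, Glc; µmol gDW^-1) and
#' twelve reactions. `measure_names()` lists the 14 reported measures used by
#' the sensitivity and PCA layers: the five concentrations plus nine reported
#' fluxes (the phosphoglucoisomerase pair is reported as a single "rPGI"
#' column, see [compute_fluxes()]). `rate_scaling_constants()` lists the ten
#' constants that scale one rate law each; they are the basis of the
#' summation-theorem checks in [full_mca()].
#'
#' @return A character vector of names.
#' @export
metabolite_names <- function() c("F6P", "G6P", "Suc", "Frc", "Glc")

#' @rdname metabolite_names
#' @export
parameter_names <- function() {
  c("k_NPS",
    "vmax_SPS", "Km_a_SPS", "Km_b_SPS", "Ki_SPS", "k_udp",
    "vmax_FRCK", "Km_FRCK", "Ki_FRCK",
    "vmax_GLCK", "Km_GLCK", "Ki_GLCK",
    "vmax_INV", "Km_INV", "Ki_INV1", "Ki_INV2",
    "vmax_PGI", "Km_PGI", "Ki_PGI", "f",
    "k1_exp", "k2_exp", "k_STA", "k_ANT", "k_STAdeg")
}

#' @rdname metabolite_names
#' @export
flux_names <- function() {
  c("rNPS", "rSPS", "rFRCK", "rGLCK", "rINV", "rPGI1", "rPGI2",
    "r1", "r2", "rSTAsyn", "rANTHO", "rSTAdeg")
}

#' @rdname metabolite_names
#' @export
measure_names <- function() {
  c("F6P", "G6P", "Frc", "Glc", "Suc",
    "rSPS", "rPGI", "rFRCK", "rGLCK", "r1", "rINV", "r2",
    "rSTAsyn", "rANTHO")
}

#' @rdname metabolite_names
#' @export
rate_scaling_constants <- function() {
  c("k_NPS", "vmax_SPS", "vmax_FRCK", "vmax_GLCK", "vmax_INV", "vmax_PGI",
    "k1_exp", "k2_exp", "k_STA", "k_ANT")
}

# Parameters for which strict positivity is required. f, k_udp and k_STAdeg
# have their own admissible ranges; k_NPS may be 0 (zero net photosynthesis,
# e.g. darkness) even though fitted conditions always have k_NPS > 0.
.positive_params <- function() {
  setdiff(parameter_names(), c("f", "k_udp", "k_STAdeg", "k_NPS"))
}

#' Coerce and validate a kinetic parameter set
#'
#' Accepts a named numeric vector, a named list, or a one-row data frame
#' containing all 25 model parameters (see [parameter_names()]). Validation
#' enforces: every vmax/Km/Ki/k strictly positive, `k_STAdeg >= 0`,
#' `0 <= f <= 1` and `0.2 <= k_udp <= 0.5` (the admissible range for the
#' fraction of G6P feeding the sucrose-phosphate-synthase reaction).
#'
#' @param x Named numeric vector, named list, or one-row data frame.
#' @return A named numeric vector in canonical parameter order, classed
#'   `"ckm_params"`.
#' @examples
#' p <- as_kinetic_params(default_parameters())
#' @export
as_kinetic_params <- function(x) {
  if (inherits(x, "ckm_params")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1) {
      abort("a parameter data frame must have exactly one row")
    }
    x <- as.list(x[, intersect(names(x), parameter_names()), drop = FALSE])
  }
  x <- unlist(x)
  missing <- setdiff(parameter_names(), names(x))
  if (length(missing) > 0) {
    abort(paste0("missing model parameter(s): ",
                 paste(missing, collapse = ", ")))
  }
  p <- as.numeric(x[parameter_names()])
  names(p) <- parameter_names()
  validate_kinetic_params(p)
  structure(p, class = "ckm_params")
}

validate_kinetic_params <- function(p) {
  if (any(!is.finite(p))) {
    abort(paste0("non-finite parameter(s): ",
                 paste(names(p)[!is.finite(p)], collapse = ", ")))
  }
  pos <- .positive_params()
  bad <- pos[p[pos] <= 0]
  if (length(bad) > 0) {
    abort(paste0("parameter(s) must be strictly positive: ",
                 paste(bad, collapse = ", ")))
  }
  if (p[["k_STAdeg"]] < 0) abort("k_STAdeg must be >= 0")
  if (p[["k_NPS"]] < 0) abort("k_NPS must be >= 0")
  if (p[["f"]] < 0 || p[["f"]] > 1) abort("f must lie in [0, 1]")
  if (p[["k_udp"]] < 0.2 || p[["k_udp"]] > 0.5) {
    abort("k_udp must lie in [0.2, 0.5]")
  }
  invisible(p)
}

#' @export
print.ckm_params <- function(x, ...) {
  cat("<kinetic parameters>\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' A plausible reference parameterization
#'
#' A hand-chosen parameter set used as the base point of the synthetic-study
#' generator and in examples. It yields an interior positive steady state
#' with pool sizes of a few to a few tens of µmol gDW^-1 and a net
#' photosynthetic influx rNPS = k_NPS/6 of 20 µmol gDW^-1 h^-1 — the order of
#' magnitude of leaf-tissue measurements. It is not a published fit.
#'
#' @return A `"ckm_params"` vector.
#' @export
default_parameters <- function() {
  as_kinetic_params(c(
    k_NPS = 120,
    vmax_SPS = 40, Km_a_SPS = 2, Km_b_SPS = 4, Ki_SPS = 5, k_udp = 0.35,
    vmax_FRCK = 30, Km_FRCK = 5, Ki_FRCK = 6,
    vmax_GLCK = 40, Km_GLCK = 2, Ki_GLCK = 12,
    vmax_INV = 40, Km_INV = 8, Ki_INV1 = 8, Ki_INV2 = 8,
    vmax_PGI = 80, Km_PGI = 3, Ki_PGI = 10, f = 0.6,
    k1_exp = 0.6, k2_exp = 0.9, k_STA = 0.8, k_ANT = 0.25,
    k_STAdeg = 0))
}

#' Default admissible parameter bounds
#'
#' Box bounds used by the calibration and the synthetic generator. All Km/Ki
#' values share common bounds across conditions (the calibration strategy
#' restricts them to a common range); `k_STAdeg` is fixed at 0 for
#' steady-state condition realizations.
#'
#' @return A tibble with columns `parameter`, `lower`, `upper`.
#' @export
default_parameter_bounds <- function() {
  pn <- parameter_names()
  lower <- setNames(rep(NA_real_, length(pn)), pn)
  upper <- lower
  km_ki <- grep("^(Km|Ki)", pn, value = TRUE)
  vmax <- grep("^vmax", pn, value = TRUE)
  lower[km_ki] <- 0.5;  upper[km_ki] <- 50
  lower[vmax] <- 5;     upper[vmax] <- 200
  lower["k_NPS"] <- 30; upper["k_NPS"] <- 300
  firstord <- c("k1_exp", "k2_exp", "k_STA", "k_ANT")
  lower[firstord] <- 0.01; upper[firstord] <- 5
  lower["f"] <- 0.05;   upper["f"] <- 0.95
  lower["k_udp"] <- 0.2; upper["k_udp"] <- 0.5
  lower["k_STAdeg"] <- 0; upper["k_STAdeg"] <- 0
  tibble::tibble(parameter = pn,
                 lower = as.numeric(lower[pn]),
                 upper = as.numeric(upper[pn]))
}

as_metabolite_state <- function(x) {
  if (is.data.frame(x)) x <- unlist(x[1, metabolite_names()])
  x <- unlist(x)
  if (is.null(names(x)) && length(x) == 5L) names(x) <- metabolite_names()
  missing <- setdiff(metabolite_names(), names(x))
  if (length(missing) > 0) {
    abort(paste0("missing metabolite(s): ", paste(missing, collapse = ", ")))
  }
  s <- as.numeric(x[metabolite_names()])
  names(s) <- metabolite_names()
  if (any(!is.finite(s))) abort("metabolite state must be finite")
  if (any(s < 0)) abort("metabolite state must be non-negative")
  s
}
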