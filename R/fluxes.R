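#' Evaluate all reaction fluxes at a metabolite state
#'
#' Implements the model's rate laws. The net photosynthetic influx is
#' `rNPS = k_NPS / 6` (hexose equivalents of CO2 fixation). Sucrose-phosphate
#' synthase (rSPS) is a lumped two-substrate law on F6P and the fraction
#' `k_udp` of G6P (UDP-glucose is not an explicit pool). Fructokinase (rFRCK)
#' and glucokinase (rGLCK) are Michaelis-Menten laws with non-competitive
#' product feedback by F6P and G6P respectively. Invertase (rINV) cleaves Suc
#' and is inhibited by both products (competitive by Frc, non-competitive by
#' Glc). The phosphoglucoisomerase pair is split into a F6P-consuming branch
#' rPGI1 (weight `f`) and a G6P-side branch rPGI2 (weight `1 - f`), each
#' saturable in its own substrate and inhibited by the opposite hexose
#' phosphate; the pair is implemented verbatim, with no mass-conservation
#' correction, because condition parameterizations are fitted to this form.
#' r1 (`k1_exp * Suc`) is sucrose export to sink organs, r2 (`k2_exp * F6P`)
#' the export of F6P to other pathways, rSTAsyn (`k_STA * G6P`) lumped starch
#' synthesis and rANTHO (`k_ANT * F6P`) the lumped flux into anthocyanins.
#' Starch degradation rSTAdeg has no rate equation; it is the constant
#' parameter `k_STAdeg` (0 in steady-state condition realizations).
#'
#' The reported measure `rPGI` (a single column in sensitivity matrices and
#' control-coefficient tables) is `rPGI1` by default; set `pgi_report` to
#' `"rPGI2"` or `"mean"` for the alternatives. The choice is recorded in the
#' `pgi_report` attribute of the result.
#'
#' @param state Metabolite state: named numeric with entries F6P, G6P, Suc,
#'   Frc, Glc (µmol gDW^-1), all finite and non-negative.
#' @param params Kinetic parameters, see [as_kinetic_params()].
#' @param pgi_report Which PGI branch the reported `rPGI` measure refers to.
#' @return Named numeric vector of the twelve fluxes plus the derived `rPGI`
#'   (µmol gDW^-1 h^-1), with attribute `pgi_report`.
#' @examples
#' compute_fluxes(c(F6P = 2, G6P = 10, Suc = 20, Frc = 3, Glc = 3),
#'                default_parameters())
#' @export
compute_fluxes <- function(state, params,
                           pgi_report = c("rPGI1", "rPGI2", "mean")) {
  pgi_report <- match.arg(pgi_report)
  p <- as_kinetic_params(params)
  s <- as_metabolite_state(state)
  F6P <- s[["F6P"]]; G6P <- s[["G6P"]]; Suc <- s[["Suc"]]
  Frc <- s[["Frc"]]; Glc <- s[["Glc"]]

  rNPS <- p[["k_NPS"]] / 6
  rSPS <- p[["vmax_SPS"]] * F6P * p[["k_udp"]] * G6P /
    (p[["Km_a_SPS"]] * F6P +
       (p[["Km_b_SPS"]] + F6P) * p[["k_udp"]] * G6P +
       p[["Ki_SPS"]] * p[["Km_a_SPS"]])
  rFRCK <- p[["vmax_FRCK"]] * Frc /
    ((p[["Km_FRCK"]] + Frc) * (1 + F6P / p[["Ki_FRCK"]]))
  rGLCK <- p[["vmax_GLCK"]] * Glc /
    ((p[["Km_GLCK"]] + Glc) * (1 + G6P / p[["Ki_GLCK"]]))
  rINV <- p[["vmax_INV"]] * Suc /
    ((p[["Km_INV"]] * (1 + Frc / p[["Ki_INV1"]]) + Suc) *
       (1 + Glc / p[["Ki_INV2"]]))
  rPGI1 <- p[["vmax_PGI"]] * F6P /
    (p[["Km_PGI"]] * (1 + G6P / p[["Ki_PGI"]]) + F6P) * p[["f"]]
  rPGI2 <- p[["vmax_PGI"]] * G6P /
    (p[["Km_PGI"]] * (1 + F6P / p[["Ki_PGI"]]) + G6P) * (1 - p[["f"]])
  r1 <- p[["k1_exp"]] * Suc
  r2 <- p[["k2_exp"]] * F6P
  rSTAsyn <- p[["k_STA"]] * G6P
  rANTHO <- p[["k_ANT"]] * F6P
  rSTAdeg <- p[["k_STAdeg"]]

  v <- c(rNPS = rNPS, rSPS = rSPS, rFRCK = rFRCK, rGLCK = rGLCK,
         rINV = rINV, rPGI1 = rPGI1, rPGI2 = rPGI2, r1 = r1, r2 = r2,
         rSTAsyn = rSTAsyn, rANTHO = rANTHO, rSTAdeg = rSTAdeg)
  v <- c(v, rPGI = switch(pgi_report,
                          rPGI1 = rPGI1,
                          rPGI2 = rPGI2,
                          mean = (rPGI1 + rPGI2) / 2))
  attr(v, "pgi_report") <- pgi_report
  v
}

#' Right-hand side of the model's differential equations
#'
#' Assembles the five time derivatives from [compute_fluxes()]:
#' \deqn{dF6P/dt = rNPS - rSPS - rPGI1 - rANTHO - r2 + rFRCK}
#' \deqn{dG6P/dt = rPGI2 - rSPS - rSTAsyn + rGLCK}
#' \deqn{dFrc/dt = rINV - rFRCK}
#' \deqn{dGlc/dt = rINV - rGLCK + rSTAdeg}
#' The sucrose balance has two variants. The default `mode = "scheme"`
#' follows the reaction scheme, in which r1 = k1_exp * Suc is the sucrose
#' export: \eqn{dSuc/dt = rSPS - r1 - rINV}. `mode = "as_printed"` instead
#' uses \eqn{dSuc/dt = rSPS - r2 - rINV}, the literal published typography in
#' which the F6P export symbol r2 appears in the sucrose balance and r1
#' appears in no balance at all. Both are provided because the discrepancy
#' cannot be resolved from the model definition alone; all shipped defaults
#' use `"scheme"`.
#'
#' @inheritParams compute_fluxes
#' @param mode `"scheme"` (default) or `"as_printed"`; see Details.
#' @return Named numeric vector of the five time derivatives
#'   (µmol gDW^-1 h^-1).
#' @export
ode_rhs <- function(state, params, mode = c("scheme", "as_printed")) {
  if (is.character(mode)) {
    mode <- mode[1]
    if (!mode %in% c("scheme", "as_printed")) {
      abort(paste0("unknown equation-variant mode: '", mode,
                   "' (use 'scheme' or 'as_printed')"))
    }
  } else {
    abort("mode must be a character flag")
  }
  v <- compute_fluxes(state, params)
  suc_drain <- if (mode == "scheme") v[["r1"]] else v[["r2"]]
  c(F6P = v[["rNPS"]] - v[["rSPS"]] - v[["rPGI1"]] - v[["rANTHO"]] -
      v[["r2"]] + v[["rFRCK"]],
    G6P = v[["rPGI2"]] - v[["rSPS"]] - v[["rSTAsyn"]] + v[["rGLCK"]],
    Suc = v[["rSPS"]] - suc_drain - v[["rINV"]],
    Frc = v[["rINV"]] - v[["rFRCK"]],
    Glc = v[["rINV"]] - v[["rGLCK"]] + v[["rSTAdeg"]])
}

# Unchecked fast path used inside integrators/solvers (no coercion,
# no validation; state may transiently dip below zero inside a solver).
.rhs_raw <- function(s, p, mode = "scheme") {
  F6P <- s[1L]; G6P <- s[2L]; Suc <- s[3L]; Frc <- s[4L]; Glc <- s[5L]
  rNPS <- p[["k_NPS"]] / 6
  rSPS <- p[["vmax_SPS"]] * F6P * p[["k_udp"]] * G6P /
    (p[["Km_a_SPS"]] * F6P +
       (p[["Km_b_SPS"]] + F6P) * p[["k_udp"]] * G6P +
       p[["Ki_SPS"]] * p[["Km_a_SPS"]])
  rFRCK <- p[["vmax_FRCK"]] * Frc /
    ((p[["Km_FRCK"]] + Frc) * (1 + F6P / p[["Ki_FRCK"]]))
  rGLCK <- p[["vmax_GLCK"]] * Glc /
    ((p[["Km_GLCK"]] + Glc) * (1 + G6P / p[["Ki_GLCK"]]))
  rINV <- p[["vmax_INV"]] * Suc /
    ((p[["Km_INV"]] * (1 + Frc / p[["Ki_INV1"]]) + Suc) *
       (1 + Glc / p[["Ki_INV2"]]))
  rPGI1 <- p[["vmax_PGI"]] * F6P /
    (p[["Km_PGI"]] * (1 + G6P / p[["Ki_PGI"]]) + F6P) * p[["f"]]
  rPGI2 <- p[["vmax_PGI"]] * G6P /
    (p[["Km_PGI"]] * (1 + F6P / p[["Ki_PGI"]]) + G6P) * (1 - p[["f"]])
  r1 <- p[["k1_exp"]] * Suc
  r2 <- p[["k2_exp"]] * F6P
  rSTAsyn <- p[["k_STA"]] * G6P
  rANTHO <- p[["k_ANT"]] * F6P
  suc_drain <- if (mode == "scheme") r1 else r2
  c(rNPS - rSPS - rPGI1 - rANTHO - r2 + rFRCK,
    rPGI2 - rSPS - rSTAsyn + rGLCK,
    rSPS - suc_drain - rINV,
    rINV - rFRCK,
    rINV - rGLCK + p[["k_STAdeg"]])
}
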