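# Shared fixtures, built in code.

# A cached realization of the reference parameterization.
toy_realization <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- condition_realization(default_parameters(),
                                      genotype = "Col-0", day = 0)
    }
    cache
  }
})

# A parameterization in the G6P-feedback regime (strong hexose-phosphate
# inhibition of PGI, strong G6P feedback on glucokinase, strong Glc
# inhibition of invertase, low f): raising f raises Glc and depletes Frc.
regime_params <- function() {
  p <- unclass(default_parameters())
  p[c("Ki_PGI", "Ki_GLCK", "Ki_INV2", "f", "k_STA", "vmax_PGI")] <-
    c(2.3, 0.83, 1.94, 0.24, 0.28, 38.5)
  as_kinetic_params(p)
}

# Three-step linear chain x1 -> x2 -> x3 -> out with constant influx v0:
# steady state x1 = v0/k1, x2 = v0/k2, x3 = v0/k3, throughput flux J = v0.
# Used as the closed-form oracle for the finite-difference control
# coefficients. The solver deliberately goes through numerical relaxation
# (not the closed form) so the oracle exercises the same protocol as the
# model path.
chain_measures <- function(pars) {
  rhs <- function(t, y, parms) {
    list(c(parms[["v0"]] - parms[["k1"]] * y[1],
           parms[["k1"]] * y[1] - parms[["k2"]] * y[2],
           parms[["k2"]] * y[2] - parms[["k3"]] * y[3]))
  }
  sol <- deSolve::lsoda(y = c(1, 1, 1), times = c(0, 2e4), func = rhs,
                        parms = pars, atol = 1e-13, rtol = 1e-13)
  y <- as.numeric(sol[nrow(sol), 2:4])
  c(x1 = y[1], x2 = y[2], x3 = y[3], J = pars[["k3"]] * y[3])
}

# Closed-form control coefficients of the chain.
chain_cc_closed_form <- function(p_name) {
  switch(p_name,
         v0 = c(x1 = 1, x2 = 1, x3 = 1, J = 1),
         k1 = c(x1 = -1, x2 = 0, x3 = 0, J = 0),
         k2 = c(x1 = 0, x2 = -1, x3 = 0, J = 0),
         k3 = c(x1 = 0, x2 = 0, x3 = -1, J = 0))
}

# Observations of one condition from a study, as fit_condition() expects.
condition_observations <- function(study, i) {
  dplyr::filter(study$observations,
                .data$genotype == study$conditions$genotype[i],
                .data$day == study$conditions$day[i])
}

# Parameters the study's observation design identifies directly.
identified_params <- function() {
  c("k_NPS", "k_STA", grep("^vmax", parameter_names(), value = TRUE))
}
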