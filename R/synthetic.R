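#' Generate a synthetic acclimation study
#'
#' Emulates the study design the analysis pipeline assumes: a grid of
#' genotypes by sampling days (default 5 x 5 = 25 condition realizations),
#' each with its own parameter set, steady state, and noisy observations.
#'
#' Construction per condition, starting from [default_parameters()]:
#' * all Km/Ki symbols receive a shared log10 jitter (±0.35) plus a small
#'   per-symbol jitter (±0.1), capping every symbol's cross-condition spread
#'   well below the cohesion factor of 10 while preserving the order
#'   relations (Km_FRCK > Km_GLCK; Km_INV within a factor 3 of Km_FRCK);
#' * vmax values, first-order constants and `k_NPS` receive independent
#'   log10 jitter;
#' * a smooth log-linear day drift lowers `k_NPS` (net photosynthesis
#'   declines in the cold) and raises vmax values (enzyme capacity
#'   increases during acclimation);
#' * genotype-effect multipliers scale single constants: flavonoid-mutant
#'   archetypes (`chs`, `f3h`) get 0.1 x `k_ANT`, the starch-synthesis
#'   archetype (`pgm1`) 0.1 x `k_STA`, the starch-retrieval archetype
#'   (`bam3`) 0.5 x `k_STA`. A fixture convention, not published values.
#'
#' Observations are the five steady-state pools plus the flux targets `rNPS`
#' and `rSTAsyn` and enzyme-activity observations of the five vmax
#' parameters, each multiplied by independent unbiased lognormal noise with
#' coefficient of variation `noise_cv` (default 0.1, the scale of 4-6
#' replicate dispersion); `sigma = noise_cv * value` is reported as the
#' dispersion. `noise_cv = 0` returns the true values exactly.
#'
#' @param n_genotypes,n_days Grid size (defaults 5 and 5).
#' @param constraints A [constraint_set()]; every generated parameter set
#'   satisfies it (guarded by construction and asserted).
#' @param noise_cv Observation coefficient of variation.
#' @param seed Integer seed; the study is fully reproducible from it.
#' @param base_params Base parameter set the jitters act on.
#' @param redraw_budget Redraws allowed per condition if a draw has no
#'   steady state.
#' @return A list of class `"ckm_study"`: `conditions` (parameter table:
#'   `genotype`, `day`, 25 parameter columns), `steady_states` (tibble with
#'   pools and solver residual), `observations` (long tibble: `genotype`,
#'   `day`, `measure`, `value`, `sigma`, `unit`), `config`.
#' @export
generate_study <- function(n_genotypes = 5, n_days = 5,
                           constraints = default_constraints(),
                           noise_cv = 0.1, seed = 1L,
                           base_params = default_parameters(),
                           redraw_budget = 10L) {
  stopifnot(n_genotypes >= 1, n_days >= 1, noise_cv >= 0)
  genotypes <- c("Col-0", "chs", "f3h", "bam3", "pgm1")
  genotypes <- if (n_genotypes <= 5) genotypes[seq_len(n_genotypes)]
  else c(genotypes, paste0("geno", seq_len(n_genotypes - 5)))
  days <- c(0, 1, 3, 7, 14)
  days <- if (n_days <= 5) days[seq_len(n_days)]
  else c(days, seq(21, by = 7, length.out = n_days - 5))

  effect <- list(
    "chs" = c(k_ANT = 0.1), "f3h" = c(k_ANT = 0.1),
    "pgm1" = c(k_STA = 0.1), "bam3" = c(k_STA = 0.5))

  set.seed(seed)
  km_ki <- grep("^(Km|Ki)", parameter_names(), value = TRUE)
  vmaxes <- grep("^vmax", parameter_names(), value = TRUE)
  firstord <- c("k1_exp", "k2_exp", "k_STA", "k_ANT")
  max_day <- max(days, 1)

  grid <- tidyr::expand_grid(genotype = genotypes, day = days)
  b <- constraints$bounds
  lo <- setNames(b$lower, b$parameter)
  hi <- setNames(b$upper, b$parameter)

  draw_condition <- function(genotype, day) {
    p <- setNames(as.numeric(base_params), names(base_params))
    u_shared <- runif(1, -0.35, 0.35)
    p[km_ki] <- p[km_ki] * 10^(u_shared + runif(length(km_ki), -0.1, 0.1))
    p[vmaxes] <- p[vmaxes] * 10^runif(length(vmaxes), -0.15, 0.15)
    p[firstord] <- p[firstord] * 10^runif(length(firstord), -0.2, 0.2)
    p["k_NPS"] <- p[["k_NPS"]] * 10^runif(1, -0.15, 0.15)
    p["f"] <- min(max(p[["f"]] + runif(1, -0.2, 0.2), lo["f"]), hi["f"])
    p["k_udp"] <- min(max(p[["k_udp"]] + runif(1, -0.1, 0.1),
                          lo["k_udp"]), hi["k_udp"])
    # acclimation drift: nps down, enzyme capacity up
    p["k_NPS"] <- p[["k_NPS"]] * 10^(-0.25 * day / max_day)
    p[vmaxes] <- p[vmaxes] * 10^(0.1 * day / max_day)
    mult <- effect[[genotype]]
    if (!is.null(mult)) p[names(mult)] <- p[names(mult)] * mult
    p <- pmin(pmax(p, lo[names(p)]), hi[names(p)])
    p["k_STAdeg"] <- 0
    p
  }

  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    for (try in seq_len(redraw_budget)) {
      p <- draw_condition(grid$genotype[i], grid$day[i])
      ss <- tryCatch(
        find_steady_state(as_kinetic_params(p), on_fail = "return"),
        error = function(e) NULL)
      if (!is.null(ss) && ss$converged && all(ss$state > 1e-8)) {
        return(list(p = p, ss = ss))
      }
    }
    abort(paste0("no steady state found for condition ", grid$genotype[i],
                 " day ", grid$day[i], " within the redraw budget"))
  })

  conditions <- dplyr::bind_cols(
    grid, purrr::map_dfr(rows, ~ tibble::as_tibble_row(.x$p)))
  steady_states <- dplyr::bind_cols(
    grid,
    purrr::map_dfr(rows, ~ tibble::as_tibble_row(.x$ss$state)),
    tibble::tibble(ss_residual = purrr::map_dbl(rows, ~ .x$ss$residual)))

  rep_check <- check_constraints(conditions, constraints)
  if (!all(rep_check$pass)) {
    abort("internal error: generated study violates its constraint set")
  }

  observations <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    p <- rows[[i]]$p
    s <- rows[[i]]$ss$state
    fl <- compute_fluxes(s, as_kinetic_params(p))
    truth <- c(s,
               rNPS = unname(fl[["rNPS"]]), rSTAsyn = unname(fl[["rSTAsyn"]]),
               setNames(p[vmaxes], vmaxes))
    unit <- c(rep("umol/gDW", 5), rep("umol/gDW/h", 2 + length(vmaxes)))
    noisy <- if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      truth * rlnorm(length(truth), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else truth
    tibble::tibble(genotype = grid$genotype[i], day = grid$day[i],
                   measure = names(truth), value = as.numeric(noisy),
                   sigma = noise_cv * as.numeric(noisy), unit = unit)
  })

  structure(list(conditions = conditions, steady_states = steady_states,
                 observations = observations,
                 config = list(seed = seed, noise_cv = noise_cv,
                               n_genotypes = n_genotypes, n_days = n_days,
                               genotype_effects = effect,
                               cohesion_factor = constraints$cohesion_factor)),
            class = "ckm_study")
}

#' @export
print.ckm_study <- function(x, ...) {
  cat("<synthetic study>", nrow(x$conditions), "conditions (",
      x$config$n_genotypes, "genotypes x", x$config$n_days, "days ), seed",
      x$config$seed, ", noise cv", x$config$noise_cv, "\n")
  invisible(x)
}

#' Sensitivity matrix with planted low-rank structure
#'
#' Builds a conditions-by-measures matrix with exactly declared structure,
#' the fixture for the PCA and day-0 separation tests: a rank-1 component
#' along a fixed unit direction, an optional shift of the first
#' `n_shifted` conditions (labelled day 0) along that direction, plus
#' isotropic Gaussian noise. A positive base level keeps all entries
#' positive, as sensitivity scores must be.
#'
#' @param n_conditions,n_measures Matrix dimensions.
#' @param shift Planted day-0 shift along the dominant direction, in units
#'   of the (unit) latent score's standard deviation.
#' @param noise_sd Standard deviation of the added isotropic noise
#'   (0 = exactly rank 1 after centring).
#' @param n_shifted Number of leading conditions labelled day 0 and shifted.
#' @param base Positive base level added to all entries. Because the
#'   robustness test applies *multiplicative* noise, the base level sets the
#'   noise magnitude relative to the planted structure; the default keeps the
#'   two at the proportion typical of model-derived sensitivity matrices.
#' @param seed Integer seed.
#' @return A tibble with columns `genotype`, `day` (0 for the shifted block,
#'   7 otherwise) and `n_measures` measure columns (the 14 canonical measure
#'   names when `n_measures = 14`).
#' @export
planted_sensitivity_matrix <- function(n_conditions = 25, n_measures = 14,
                                       shift = 3, noise_sd = 0.1,
                                       n_shifted = 5, base = 2, seed = 1L) {
  if (n_conditions < 2 || n_measures < 2) {
    abort("need at least 2 conditions and 2 measures")
  }
  if (n_shifted > n_conditions) {
    abort("n_shifted cannot exceed n_conditions")
  }
  set.seed(seed)
  v <- rep(1 / sqrt(n_measures), n_measures)
  score <- rnorm(n_conditions)
  score[seq_len(n_shifted)] <- score[seq_len(n_shifted)] + shift
  m <- base + outer(score, v) +
    matrix(rnorm(n_conditions * n_measures, sd = noise_sd),
           n_conditions, n_measures)
  m <- pmax(m, 1e-6)
  cols <- if (n_measures == length(measure_names())) measure_names()
  else paste0("m", seq_len(n_measures))
  out <- tibble::as_tibble(as.data.frame(m))
  names(out) <- cols
  dplyr::bind_cols(
    tibble::tibble(genotype = paste0("c", seq_len(n_conditions)),
                   day = ifelse(seq_len(n_conditions) <= n_shifted, 0, 7)),
    out)
}
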