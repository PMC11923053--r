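#' Configuration of a full pipeline run
#'
#' A serializable run configuration: together with its inputs it determines
#' every pipeline output bit-for-bit (up to floating-point caveats of the
#' underlying solvers). Either `parameter_table` (path to an existing
#' condition parameter table) or `synthetic` (settings for
#' [generate_study()]) supplies the conditions.
#'
#' @param output_dir Directory for all artifacts (created if needed).
#' @param seed Integer seed for every stochastic stage.
#' @param parameter_table Optional path to a parameter table.
#' @param synthetic List of [generate_study()] arguments used when no
#'   parameter table is given (defaults to the 5 x 5 study design).
#' @param mode Equation variant, see [ode_rhs()].
#' @param protocol Perturbation protocol settings
#'   (list: `relative_changes`, `pre_perturbation_time`, `total_time`).
#' @param mca List: `rel_step`, `threshold`.
#' @param pca List: `robustness_noise`, `robustness_reps`,
#'   `threshold_frac`.
#' @param pgi_report Reported PGI branch, see [compute_fluxes()].
#' @return A list of class `"ckm_config"`.
#' @export
run_config <- function(output_dir = tempfile("carbsens_run_"),
                       seed = 1L,
                       parameter_table = NULL,
                       synthetic = list(n_genotypes = 5, n_days = 5,
                                        noise_cv = 0.1),
                       mode = "scheme",
                       protocol = list(relative_changes = c(-6:-1, 1:6) * 0.05,
                                       pre_perturbation_time = 2,
                                       total_time = 4),
                       mca = list(rel_step = 1e-4, threshold = 1.5),
                       pca = list(robustness_noise = 0.5,
                                  robustness_reps = 100,
                                  threshold_frac = 0.5),
                       pgi_report = "rPGI1") {
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 parameter_table = parameter_table, synthetic = synthetic,
                 mode = mode, protocol = protocol, mca = mca, pca = pca,
                 pgi_report = pgi_report),
            class = "ckm_config")
}

#' @rdname run_config
#' @param path A YAML or JSON configuration file with the fields above.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, raw)
}

.write_stage <- function(tbl, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(tbl, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes all stages in order — condition parameters (read or
#' synthesized), steady states, nps perturbation sweep and sensitivity
#' matrix, metabolic control analysis with exceedance summaries, PCA with
#' day-0 separation, and the noise-robustness test — writing every
#' intermediate as a delimited-text artifact plus a machine-readable JSON
#' manifest (package version, seed, config hash, artifact list). Stages
#' only communicate through files; a stage failure retains the partial
#' outputs, writes a failure manifest and raises a classed error.
#'
#' @param config A [run_config()] (or a path accepted by
#'   [read_run_config()]).
#' @return Invisibly, the manifest as a list (`output_dir`, `artifacts`,
#'   `results` with headline numbers).
#' @export
run_full_pipeline <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "ckm_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- list()
  manifest_path <- file.path(config$output_dir, "manifest.json")
  stage <- "setup"

  fail <- function(e) {
    jsonlite::write_json(
      list(status = "failed", stage = stage,
           message = conditionMessage(e),
           artifacts = artifacts),
      manifest_path, auto_unbox = TRUE, pretty = TRUE)
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)), class = "ckm_pipeline_error")
  }

  result <- tryCatch({
    stage <- "parameters"
    if (!is.null(config$parameter_table)) {
      param_tbl <- read_parameter_table(config$parameter_table)
    } else {
      study <- do.call(generate_study,
                       c(config$synthetic, list(seed = config$seed)))
      param_tbl <- study$conditions
      artifacts$observations <-
        .write_stage(study$observations, config$output_dir,
                     "observations.csv")
    }
    artifacts$parameters <-
      .write_stage(param_tbl, config$output_dir, "parameters.csv")

    stage <- "steady_states"
    ss_tbl <- add_steady_states(param_tbl,
                                control = ss_control(mode = config$mode))
    artifacts$steady_states <- .write_stage(
      dplyr::select(ss_tbl, "genotype", "day",
                    dplyr::all_of(metabolite_names()), "ss_residual"),
      config$output_dir, "steady_states.csv")

    stage <- "sensitivity"
    protocol <- do.call(perturbation_protocol, config$protocol)
    gamma_tbl <- sensitivity_sweep(param_tbl, protocol,
                                   pgi_report = config$pgi_report,
                                   control = ss_control(mode = config$mode))
    artifacts$sensitivity <-
      .write_stage(gamma_tbl, config$output_dir, "sensitivity_matrix.csv")

    stage <- "mca"
    cc_tbl <- mca_table(param_tbl, rel_step = config$mca$rel_step,
                        control = ss_control(mode = config$mode))
    artifacts$control_coefficients <-
      .write_stage(cc_tbl, config$output_dir, "control_coefficients.csv")
    by_gen <- high_cc_frequency(cc_tbl, config$mca$threshold, "genotype")
    by_day <- high_cc_frequency(cc_tbl, config$mca$threshold, "day")
    artifacts$exceedance_by_genotype <-
      .write_stage(by_gen, config$output_dir, "exceedance_by_genotype.csv")
    artifacts$exceedance_by_day <-
      .write_stage(by_day, config$output_dir, "exceedance_by_day.csv")

    stage <- "pca"
    pca <- pca_gamma(gamma_tbl)
    artifacts$pca_loadings <- .write_stage(
      tidy(pca, "loadings"), config$output_dir, "pca_loadings.csv")
    artifacts$pca_explained <- .write_stage(
      tidy(pca, "eigenvalues"), config$output_dir, "pca_explained.csv")
    artifacts$pca_scores <-
      .write_stage(pca$scores, config$output_dir, "pca_scores.csv")
    sep <- day0_separation(pca)

    stage <- "robustness"
    rob <- robustness_test(gamma_tbl,
                           noise_level = config$pca$robustness_noise,
                           repetitions = config$pca$robustness_reps,
                           seed = config$seed,
                           threshold_frac = config$pca$threshold_frac)
    artifacts$robustness <-
      .write_stage(rob, config$output_dir, "robustness.csv")

    stage <- "manifest"
    list(param_tbl = param_tbl, pca = pca, sep = sep, rob = rob,
         by_day = by_day)
  }, error = fail)

  cfg_for_hash <- unclass(config)
  cfg_for_hash$output_dir <- NULL
  manifest <- list(
    status = "ok",
    package = "carbsens",
    version = as.character(packageVersion("carbsens")),
    seed = config$seed,
    config_hash = digest::digest(cfg_for_hash),
    n_conditions = nrow(result$param_tbl),
    artifacts = artifacts,
    results = list(
      pc1_pct = 100 * as.numeric(result$pca$explained[1]),
      pc2_pct = 100 * as.numeric(result$pca$explained[2]),
      day0_separation = result$sep$statistic,
      robustness_preserved_fraction = result$rob$preserved_fraction,
      exceedance_by_day = as.list(setNames(result$by_day$n_exceed,
                                           result$by_day$day))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(manifest, list(output_dir = config$output_dir)))
}

#' Recompute the headline pipeline quantities from a parameter table
#'
#' Convenience wrapper that takes a condition parameter table (for example
#' a published supplementary parameter set written in the format of
#' [read_parameter_table()]), runs the perturbation sweep and control
#' analysis on it, and returns the quantities the study design reports:
#' PCA explained-variance percentages, component loadings, the per-day
#' frequency of control coefficients above the threshold, and the ratio of
#' `f`'s mean absolute parameter control coefficient to the strongest other
#' parameter.
#'
#' @param param_tbl Parameter table or path to one.
#' @param protocol Perturbation protocol.
#' @param threshold Control-coefficient magnitude threshold (default 1.5).
#' @param pgi_report Reported PGI branch.
#' @param mode Equation variant.
#' @return A list: `explained_pct` (named numeric), `loadings`,
#'   `exceedance_by_day`, `exceedance_by_genotype`, `f_dominance_ratio`,
#'   `gamma`, `cc`.
#' @export
reproduce_published_analysis <- function(param_tbl,
                                         protocol = perturbation_protocol(),
                                         threshold = 1.5,
                                         pgi_report = "rPGI1",
                                         mode = "scheme") {
  if (is.character(param_tbl)) param_tbl <- read_parameter_table(param_tbl)
  param_tbl <- validate_parameter_table(param_tbl)
  ctrl <- ss_control(mode = mode)
  gamma_tbl <- sensitivity_sweep(param_tbl, protocol,
                                 pgi_report = pgi_report, control = ctrl)
  pca <- pca_gamma(gamma_tbl)
  cc_tbl <- mca_table(param_tbl, control = ctrl)
  mean_abs <- cc_tbl |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean_abs_cc = mean(abs(.data$value)), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_abs_cc))
  f_val <- mean_abs$mean_abs_cc[mean_abs$parameter == "f"]
  other_max <- max(mean_abs$mean_abs_cc[mean_abs$parameter != "f"])
  list(explained_pct = 100 * pca$explained,
       loadings = pca$loadings,
       exceedance_by_day = high_cc_frequency(cc_tbl, threshold, "day"),
       exceedance_by_genotype = high_cc_frequency(cc_tbl, threshold,
                                                  "genotype"),
       f_dominance_ratio = f_val / other_max,
       gamma = gamma_tbl,
       cc = cc_tbl,
       pca = pca)
}
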