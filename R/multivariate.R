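#' Standardized PCA of a sensitivity matrix
#'
#' Column-standardizes the conditions-by-measures sensitivity matrix (each
#' measure to mean 0, sd 1) and computes principal components by singular
#' value decomposition, ordered by explained variance. Explained-variance
#' fractions are computed over all components and sum to 1. Component signs
#' are fixed by a declared convention so loadings are comparable across
#' runs: each component is flipped, if necessary, so its Suc loading is
#' non-positive (falling back to making the largest-magnitude loading
#' negative when the Suc loading is numerically zero, or when Suc is not
#' among the measures). Conditions with missing entries are excluded with a
#' warning (imputing a sensitivity would fabricate one); zero-variance
#' measures are dropped with a warning since they cannot be standardized.
#'
#' @param gamma_tbl Tibble with metadata columns (e.g. `genotype`, `day`)
#'   and the measure columns; all non-metadata numeric columns are used
#'   unless `measures` is given.
#' @param measures Optional character vector naming the measure columns.
#' @return An object of class `"gamma_pca"`: `loadings` (components x
#'   measures matrix, rows unit norm), `explained` (fractions per
#'   component), `sdev`, `scores` (tibble: metadata + PC columns),
#'   `measures`, `dropped_measures`, `dropped_conditions`, `sign_flipped`.
#' @export
pca_gamma <- function(gamma_tbl, measures = NULL) {
  stopifnot(is.data.frame(gamma_tbl))
  meta_cols <- intersect(c("genotype", "day", "condition"), names(gamma_tbl))
  if (is.null(measures)) {
    measures <- setdiff(names(gamma_tbl), meta_cols)
    measures <- measures[vapply(gamma_tbl[measures], is.numeric, logical(1))]
  }
  if (length(measures) < 2) abort("need at least 2 measure columns")
  x <- as.matrix(gamma_tbl[, measures, drop = FALSE])

  incomplete <- !stats::complete.cases(x)
  if (any(incomplete)) {
    warn(paste0(sum(incomplete),
                " condition(s) with missing sensitivities excluded from PCA"))
    x <- x[!incomplete, , drop = FALSE]
  }
  if (nrow(x) < 2) abort("PCA needs at least 2 complete conditions")

  sds <- apply(x, 2, sd)
  dropped <- measures[sds == 0]
  if (length(dropped) > 0) {
    warn(paste0("zero-variance measure(s) dropped: ",
                paste(dropped, collapse = ", ")))
    keep <- measures[sds > 0]
  } else keep <- measures
  x <- x[, keep, drop = FALSE]

  pc <- prcomp(x, center = TRUE, scale. = TRUE)
  rot <- pc$rotation                       # measures x components
  scores <- pc$x

  flipped <- logical(ncol(rot))
  anchor <- if ("Suc" %in% keep) "Suc" else NULL
  for (j in seq_len(ncol(rot))) {
    a <- if (!is.null(anchor)) rot[anchor, j] else 0
    if (abs(a) > 1e-12) {
      if (a > 0) flipped[j] <- TRUE
    } else {
      k <- which.max(abs(rot[, j]))
      if (rot[k, j] > 0) flipped[j] <- TRUE
    }
    if (flipped[j]) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }

  explained <- pc$sdev^2 / sum(pc$sdev^2)
  meta <- gamma_tbl[!incomplete, meta_cols, drop = FALSE]
  structure(list(loadings = t(rot),
                 explained = setNames(explained, colnames(rot)),
                 sdev = pc$sdev,
                 scores = dplyr::bind_cols(
                   tibble::as_tibble(meta),
                   tibble::as_tibble(as.data.frame(scores))),
                 measures = keep,
                 dropped_measures = dropped,
                 dropped_conditions = which(incomplete),
                 sign_flipped = flipped,
                 sign_convention = "Suc loading <= 0 where nonzero"),
            class = "gamma_pca")
}

#' @export
print.gamma_pca <- function(x, ...) {
  cat("<sensitivity PCA>", length(x$measures), "measures,",
      nrow(x$scores), "conditions\n")
  ev <- round(100 * x$explained[seq_len(min(4, length(x$explained)))], 2)
  cat("explained variance (%):", paste(names(ev), ev, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn pca_gamma Broom-style accessors: `tidy()` returns loadings
#'   (`matrix = "loadings"`), scores, or eigenvalue fractions in long form.
#' @param x A `gamma_pca` object.
#' @param matrix One of `"loadings"`, `"scores"`, `"eigenvalues"`.
#' @param ... Unused.
#' @method tidy gamma_pca
#' @export
tidy.gamma_pca <- function(x, matrix = c("loadings", "scores",
                                         "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "loadings") {
    as.data.frame(t(x$loadings)) |>
      tibble::rownames_to_column("measure") |>
      tidyr::pivot_longer(-"measure", names_to = "component",
                          values_to = "loading") |>
      tibble::as_tibble()
  } else if (matrix == "scores") {
    tidyr::pivot_longer(x$scores,
                        dplyr::starts_with("PC"),
                        names_to = "component", values_to = "score")
  } else {
    tibble::tibble(component = names(x$explained),
                   explained_fraction = as.numeric(x$explained),
                   sdev = x$sdev)
  }
}

#' @describeIn pca_gamma `glance()` one-row summary with the leading
#'   explained-variance percentages.
#' @method glance gamma_pca
#' @export
glance.gamma_pca <- function(x, ...) {
  ev <- as.numeric(x$explained)
  tibble::tibble(n_conditions = nrow(x$scores),
                 n_measures = length(x$measures),
                 pc1_pct = 100 * ev[1],
                 pc2_pct = 100 * ev[2],
                 pc3_pct = if (length(ev) >= 3) 100 * ev[3] else NA_real_,
                 pc4_pct = if (length(ev) >= 4) 100 * ev[4] else NA_real_)
}

#' Day-0 separation along the first principal component
#'
#' Quantifies how far the day-0 conditions sit from all other days along
#' PC1: the absolute difference between the day-0 score centroid and the
#' pooled other-day centroid, divided by the pooled within-group standard
#' deviation of the PC1 scores, plus the mean silhouette width of the
#' two-group partition on PC1. Invariant to condition ordering and to the
#' PC sign convention.
#'
#' @param pca A [pca_gamma()] result whose `scores` carry a day column, or
#'   supply `labels` explicitly.
#' @param labels Optional vector of day labels per condition (in score
#'   row order); defaults to the `day` column of the scores.
#' @param day0 The label identifying the reference day (default 0).
#' @return One-row tibble: `statistic`, `silhouette`, `n_day0`, `n_other`,
#'   `low_confidence` (TRUE when either group has fewer than 2 members).
#' @export
day0_separation <- function(pca, labels = NULL, day0 = 0) {
  stopifnot(inherits(pca, "gamma_pca"))
  if (is.null(labels)) {
    if (!"day" %in% names(pca$scores)) {
      abort("no day labels available; supply `labels`")
    }
    labels <- pca$scores$day
  }
  if (length(labels) != nrow(pca$scores)) {
    abort("labels must have one entry per condition")
  }
  pc1 <- pca$scores$PC1
  g0 <- pc1[labels == day0]
  g1 <- pc1[labels != day0]
  if (length(g0) == 0 || length(g1) == 0) {
    abort("both the day-0 group and the rest must be non-empty")
  }
  low_conf <- length(g0) < 2 || length(g1) < 2
  n0 <- length(g0); n1 <- length(g1)
  pooled_var <- (sum((g0 - mean(g0))^2) + sum((g1 - mean(g1))^2)) /
    max(n0 + n1 - 2, 1)
  stat <- abs(mean(g0) - mean(g1)) / sqrt(max(pooled_var, 1e-300))
  sil <- if (low_conf) NA_real_ else {
    cl <- ifelse(labels == day0, 1L, 2L)
    mean(cluster::silhouette(cl, dist(pc1))[, "sil_width"])
  }
  tibble::tibble(statistic = stat, silhouette = sil,
                 n_day0 = n0, n_other = n1,
                 low_confidence = low_conf)
}

#' Noise-robustness of the day-0 separation
#'
#' Repeats the standardized PCA and [day0_separation()] after multiplying
#' every sensitivity entry by independent lognormal noise whose central 95
#' percent spans `1 +/- noise_level` (the default 0.5 reflects the
#' worst-case model-versus-data deviations of isolated measures), and
#' reports the fraction of repetitions in which the separation statistic
#' stays above `threshold_frac` of its unperturbed value. Deterministic
#' given `seed`.
#'
#' @param gamma_tbl Sensitivity tibble as for [pca_gamma()].
#' @param noise_level Fractional half-width of the noise factor's central
#'   95 percent interval; 0 means no noise.
#' @param repetitions Number of noisy repetitions (>= 1).
#' @param seed Integer seed.
#' @param threshold_frac Preservation threshold as a fraction of the
#'   unperturbed separation statistic (default 0.5).
#' @param measures,day0 Passed through to [pca_gamma()] /
#'   [day0_separation()].
#' @return One-row tibble: `preserved_fraction`, `baseline_statistic`,
#'   `mean_statistic`, `repetitions`, `noise_level`, `threshold_frac`.
#' @export
robustness_test <- function(gamma_tbl, noise_level = 0.5,
                            repetitions = 100, seed = 1L,
                            threshold_frac = 0.5, measures = NULL,
                            day0 = 0) {
  stopifnot(repetitions >= 1, noise_level >= 0)
  base_pca <- pca_gamma(gamma_tbl, measures)
  base_stat <- day0_separation(base_pca, day0 = day0)$statistic
  meas <- base_pca$measures
  sdlog <- if (noise_level > 0) log(1 + noise_level) / qnorm(0.975) else 0

  set.seed(seed)
  stats_r <- purrr::map_dbl(seq_len(repetitions), function(r) {
    noisy <- gamma_tbl
    if (sdlog > 0) {
      for (m in meas) {
        noisy[[m]] <- noisy[[m]] *
          rlnorm(nrow(noisy), meanlog = 0, sdlog = sdlog)
      }
    }
    day0_separation(pca_gamma(noisy, meas), day0 = day0)$statistic
  })
  tibble::tibble(
    preserved_fraction = mean(stats_r >= threshold_frac * base_stat),
    baseline_statistic = base_stat,
    mean_statistic = mean(stats_r),
    repetitions = repetitions,
    noise_level = noise_level,
    threshold_frac = threshold_frac)
}
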