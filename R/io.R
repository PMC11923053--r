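#' Read and write condition parameter tables
#'
#' The canonical exchange format for condition parameterizations: one row
#' per genotype-by-day condition, a `genotype` and a `day` column, and one
#' column per model parameter using the canonical names of
#' [parameter_names()]. Delimited text is UTF-8, comma-separated with a
#' header row and "." as decimal mark; an equivalent JSON representation
#' (array of condition objects) is selected by the `.json` file extension.
#' The reader validates completeness (missing columns are named in the
#' error) and parameter ranges.
#'
#' @param path File path; `.json` selects JSON, anything else delimited
#'   text.
#' @return `read_parameter_table()`: a validated tibble.
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  }
  validate_parameter_table(tbl)
}

#' @rdname read_parameter_table
#' @param param_tbl Parameter table to write.
#' @param path Output file path.
#' @export
write_parameter_table <- function(param_tbl, path) {
  param_tbl <- validate_parameter_table(param_tbl)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(param_tbl, path, digits = NA, auto_unbox = FALSE)
  } else {
    utils::write.csv(param_tbl, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname read_parameter_table
#' @export
validate_parameter_table <- function(param_tbl) {
  if (!is.data.frame(param_tbl)) abort("parameter table must be a data frame")
  missing <- setdiff(c("genotype", "day", parameter_names()),
                     names(param_tbl))
  if (length(missing) > 0) {
    abort(paste0("parameter table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(param_tbl) < 1) abort("parameter table has no conditions")
  for (i in seq_len(nrow(param_tbl))) as_kinetic_params(param_tbl[i, ])
  tibble::as_tibble(param_tbl)
}

#' Read and write observation tables
#'
#' Long per-condition observations: columns `genotype`, `day`, `measure`,
#' `value`, `sigma` (replicate dispersion) and optionally `unit`. Measures
#' are the five pools (µmol gDW^-1), the flux targets `rNPS` and `rSTAsyn`
#' (µmol gDW^-1 h^-1), and enzyme activities named after the vmax parameter
#' they measure.
#'
#' @param path File path (`.json` or delimited text, as in
#'   [read_parameter_table()]).
#' @return A tibble.
#' @export
read_observation_table <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
  }
  missing <- setdiff(c("genotype", "day", "measure", "value"), names(tbl))
  if (length(missing) > 0) {
    abort(paste0("observation table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  tbl
}

#' @rdname read_observation_table
#' @param obs_tbl Observation table to write.
#' @export
write_observation_table <- function(obs_tbl, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obs_tbl, path, digits = NA, auto_unbox = FALSE)
  } else {
    utils::write.csv(obs_tbl, path, row.names = FALSE)
  }
  invisible(path)
}
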