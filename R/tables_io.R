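#' Read a light/heavy intensity table
#'
#' Reads the CSV of integrated MS peak intensities for the light and heavy
#' isotopologues of each analyte, one row per sample x fraction x time point.
#' Columns: `sample_id, genotype, replicate, analyte, fraction, time_min,
#' intensity_light, intensity_heavy`. The `fraction` column uses a controlled
#' vocabulary: `soluble`, `protein`, `total` (labeling time courses),
#' `cytosol_B`, `vacuole_C` (copper-chloride permeabilization), `medium`,
#' `cell_pellet` (export controls).
#'
#' @param path Path to the CSV file.
#' @param config A [caa_config()]; labeling rows must use its sampling
#'   schedule.
#' @return A tibble of validated intensity records.
#' @export
read_intensity_table <- function(path, config = caa_config()) {
  df <- read_caa_csv(path, c(
    sample_id = "c", genotype = "c", replicate = "i", analyte = "c",
    fraction = "c", time_min = "d", intensity_light = "d",
    intensity_heavy = "d"
  ))

  bad_frac <- which(!df$fraction %in% FRACTION_TOKENS)
  if (length(bad_frac) > 0) {
    abort(sprintf(
      "unknown fraction token(s) %s in row(s) %s of '%s'",
      paste(unique(df$fraction[bad_frac]), collapse = ", "),
      paste(bad_frac, collapse = ", "), path
    ), class = "caaflux_validation_error")
  }
  validate_rows(df$replicate >= 1, "replicate must be a positive integer", path)
  validate_rows(df$time_min >= 0, "time_min must be >= 0", path)
  validate_rows(df$intensity_light >= 0, "negative intensity_light", path)
  validate_rows(df$intensity_heavy >= 0, "negative intensity_heavy", path)

  labeling <- df$fraction %in% LABELING_FRACTIONS
  validate_rows(!labeling | df$intensity_light + df$intensity_heavy > 0,
                "both intensities zero on a labeling row", path)
  validate_rows(!labeling | df$time_min %in% config$time_points_min,
                "time_min outside the configured labeling schedule", path)

  dplyr::arrange(df, .data$genotype, .data$replicate, .data$analyte,
                 .data$fraction, .data$time_min)
}

#' Read a calibration-standards table
#'
#' Equimolar light/heavy dilution series per analyte. Columns: `analyte,
#' concentration_mM, intensity_light, intensity_heavy`.
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated standard records.
#' @export
read_standards_table <- function(path) {
  df <- read_caa_csv(path, c(
    analyte = "c", concentration_mM = "d",
    intensity_light = "d", intensity_heavy = "d"
  ))
  validate_rows(df$concentration_mM > 0, "concentration_mM must be > 0", path)
  validate_rows(df$intensity_light > 0, "standard intensity_light must be > 0", path)
  validate_rows(df$intensity_heavy > 0, "standard intensity_heavy must be > 0", path)
  dplyr::arrange(df, .data$analyte, .data$concentration_mM)
}

#' Read an OD600 growth table
#'
#' Columns: `sample_id, time_min, od600`. Each culture's series is returned
#' sorted by time; duplicate (sample, time) rows are rejected.
#'
#' @param path Path to the CSV file.
#' @return A tibble of growth points.
#' @export
read_growth_table <- function(path) {
  df <- read_caa_csv(path, c(sample_id = "c", time_min = "d", od600 = "d"))
  validate_rows(df$time_min >= 0, "time_min must be >= 0", path)
  validate_rows(df$od600 > 0, "od600 must be > 0", path)
  dup <- duplicated(df[c("sample_id", "time_min")])
  if (any(dup)) {
    abort(sprintf("duplicate (sample_id, time_min) row(s) %s in '%s'",
                  paste(which(dup), collapse = ", "), path),
          class = "caaflux_validation_error")
  }
  dplyr::arrange(df, .data$sample_id, .data$time_min)
}

#' Read a copper-chloride permeabilization table
#'
#' Columns: `sample_id, genotype, analyte, fraction, intensity_analyte,
#' intensity_marker`, with `fraction` one of `cytosol_B` (flowthrough after
#' selective plasma-membrane permeabilization) or `vacuole_C` (boiled whole
#' cells). The marker is a fiducial cytosolic amino acid (phenylalanine).
#'
#' @param path Path to the CSV file.
#' @return A tibble of validated records.
#' @export
read_cucl2_table <- function(path) {
  df <- read_caa_csv(path, c(
    sample_id = "c", genotype = "c", analyte = "c", fraction = "c",
    intensity_analyte = "d", intensity_marker = "d"
  ))
  validate_rows(df$fraction %in% c("cytosol_B", "vacuole_C"),
                "fraction must be cytosol_B or vacuole_C", path)
  validate_rows(df$intensity_analyte >= 0, "negative intensity_analyte", path)
  validate_rows(df$intensity_marker > 0, "intensity_marker must be > 0", path)
  dplyr::arrange(df, .data$sample_id, .data$analyte, .data$fraction)
}

#' Write a tabular record collection to CSV
#'
#' Uses a shortest-round-trip representation for doubles so that
#' `read_*` after `write_caa_table()` reproduces every numeric field exactly.
#'
#' @param df A tibble (intensities, standards, growth, renewal, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_caa_table <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' Write pipeline results to JSON
#'
#' Serializes any pipeline output (rate tables, fit objects, nested result
#' lists) to JSON with 17 significant digits so that numeric fields
#' round-trip bit-for-bit through [read_results()].
#'
#' @param results A list or tibble of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  json <- jsonlite::toJSON(results, digits = I(17), auto_unbox = TRUE,
                           na = "null", null = "null", pretty = TRUE)
  tryCatch(writeLines(json, path),
           error = function(e) abort(sprintf("cannot write '%s': %s",
                                             path, conditionMessage(e)),
                                     class = "caaflux_io_error"))
  invisible(path)
}

#' Read back a JSON results file
#'
#' @param path Path written by [write_results()].
#' @return The deserialized object (lists and vectors).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "caaflux_io_error")
  }
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# -- internal helpers ---------------------------------------------------------

# Read a CSV and check its header against a named col-type spec
# (c = character, d = double, i = integer).
read_caa_csv <- function(path, spec) {
  if (!is.character(path) || !file.exists(path)) {
    abort(sprintf("file not found: '%s'", path), class = "caaflux_io_error")
  }
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing <- setdiff(names(spec), header)
  if (length(missing) > 0) {
    abort(sprintf("'%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")),
          class = "caaflux_schema_error")
  }
  types <- do.call(readr::cols, as.list(setNames(
    lapply(spec, function(t) switch(t,
      c = readr::col_character(),
      d = readr::col_double(),
      i = readr::col_integer()
    )),
    names(spec)
  )))
  df <- readr::read_csv(path, col_types = types)
  bad_na <- which(rowSums(is.na(df[names(spec)])) > 0)
  if (length(bad_na) > 0) {
    abort(sprintf("missing or unparseable value(s) in row(s) %s of '%s'",
                  paste(bad_na, collapse = ", "), path),
          class = "caaflux_validation_error")
  }
  tibble::as_tibble(df[names(spec)])
}

validate_rows <- function(ok, what, path) {
  bad <- which(!ok)
  if (length(bad) > 0) {
    abort(sprintf("%s in row(s) %s of '%s'", what,
                  paste(bad, collapse = ", "), path),
          class = "caaflux_validation_error")
  }
  invisible(TRUE)
}
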