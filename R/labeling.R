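#' Calibrate isotopologue response factors from equimolar standards
#'
#' The light and heavy isotopologues of an amino acid do not necessarily
#' produce identical MS signal per mole. Equimolar light/heavy dilution
#' series are used to calibrate relative response factors `w_light`,
#' `w_heavy` (summing to one) such that the weighted intensity ratio maps to
#' a molar fraction. Per-level light/heavy intensity ratios are combined by
#' their arithmetic mean (or geometric mean, see [caa_config()]); the
#' coefficient of variation of per-level ratios is reported as a stability
#' diagnostic, since the calibration is only meaningful if the ratio is
#' stable across the intensity range of the assay.
#'
#' Two conventions are supported. Under `"inverse_response"` (default) the
#' weights satisfy `w_light / w_heavy = 1 / mean_ratio`, which makes the
#' equimolar standard itself map to fraction 0.5 exactly — the
#' self-consistency a calibration must satisfy. Under `"as_printed"` the
#' weights satisfy `w_light / w_heavy = mean_ratio`, i.e. the larger weight
#' goes to the stronger-responding isotopologue; this runs the correction
#' backwards (the equimolar standard maps to r^2/(1+r^2) rather than 0.5)
#' and is provided only for comparison. See the package vignette for the
#' rationale.
#'
#' @param standards A standards tibble as from [read_standards_table()].
#' @param convention `"inverse_response"` or `"as_printed"`.
#' @param aggregation `"mean"` or `"geometric"` combination of per-level
#'   ratios.
#' @param allow_single Allow calibration from a single standard level
#'   (default `FALSE`: at least two levels are required).
#' @return A tibble with one row per analyte: `analyte, w_light, w_heavy,
#'   mean_standard_ratio, ratio_cv, n_levels, convention`.
#' @export
#' @examples
#' std <- tibble::tibble(
#'   analyte = "lysine",
#'   concentration_mM = c(0.002, 0.03, 0.5),
#'   intensity_light = c(200, 3000, 50000),
#'   intensity_heavy = c(100, 1500, 25000)
#' )
#' calibrate_response_factors(std) # w_light = 1/3: light responds 2x stronger
calibrate_response_factors <- function(standards,
                                       convention = c("inverse_response", "as_printed"),
                                       aggregation = c("mean", "geometric"),
                                       allow_single = FALSE) {
  convention <- match.arg(convention)
  aggregation <- match.arg(aggregation)
  if (any(standards$intensity_light <= 0) || any(standards$intensity_heavy <= 0)) {
    abort("standard intensities must be strictly positive",
          class = "caaflux_calibration_error")
  }

  out <- standards |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(
      n_levels = dplyr::n(),
      mean_standard_ratio = if (aggregation == "mean") {
        mean(.data$intensity_light / .data$intensity_heavy)
      } else {
        exp(mean(log(.data$intensity_light / .data$intensity_heavy)))
      },
      ratio_cv = sd(.data$intensity_light / .data$intensity_heavy) /
        mean(.data$intensity_light / .data$intensity_heavy),
      .groups = "drop"
    )
  if (!allow_single && any(out$n_levels < 2)) {
    abort(sprintf(
      "analyte(s) %s have a single standard level; use allow_single = TRUE to override",
      paste(out$analyte[out$n_levels < 2], collapse = ", ")
    ), class = "caaflux_calibration_error")
  }

  r <- out$mean_standard_ratio
  # complements are formed by subtraction so the pair sums to 1 exactly
  if (convention == "inverse_response") {
    out$w_light <- 1 / (1 + r)
    out$w_heavy <- 1 - out$w_light
  } else {
    out$w_heavy <- 1 / (1 + r)
    out$w_light <- 1 - out$w_heavy
  }
  out$convention <- convention
  dplyr::select(out, "analyte", "w_light", "w_heavy",
                "mean_standard_ratio", "ratio_cv", "n_levels", "convention")
}

#' Light ("old") molar fraction from an intensity pair
#'
#' Core renewal quantity: `f = w_L * I_L / (w_L * I_L + w_H * I_H)`, the
#' response-factor-corrected molar fraction of the pre-switch light
#' isotopologue. `f` is scale-invariant in the intensities and lies in
#' [0, 1].
#'
#' @param intensity_light,intensity_heavy Non-negative intensities (at least
#'   one strictly positive). Vectorized.
#' @param w_light,w_heavy Calibrated response factors (positive, typically
#'   summing to 1).
#' @return Numeric vector of light fractions.
#' @export
#' @examples
#' light_fraction(300, 150, w_light = 1/3, w_heavy = 2/3) # 0.5
light_fraction <- function(intensity_light, intensity_heavy, w_light, w_heavy) {
  if (any(intensity_light < 0) || any(intensity_heavy < 0)) {
    abort("intensities must be non-negative", class = "caaflux_validation_error")
  }
  if (any(intensity_light + intensity_heavy <= 0)) {
    abort("light and heavy intensity are both zero: fraction undefined",
          class = "caaflux_validation_error")
  }
  if (any(w_light <= 0) || any(w_heavy <= 0)) {
    abort("response factors must be strictly positive",
          class = "caaflux_calibration_error")
  }
  wl <- w_light * intensity_light
  wh <- w_heavy * intensity_heavy
  wl / (wl + wh)
}

#' Renewal time courses from an intensity table
#'
#' Applies [light_fraction()] to every labeling row (fractions `soluble`,
#' `protein`, `total`) of an intensity table, using per-analyte calibrated
#' response factors, and converts times to hours. Renewal at time 0 is
#' expected to be near 1 (all material pre-switch); values below 0.9 at time
#' 0 trigger a warning, not an error.
#'
#' @param intensities Tibble from [read_intensity_table()].
#' @param factors Tibble from [calibrate_response_factors()].
#' @return Renewal tibble: `genotype, replicate, analyte, fraction, time_h, f`.
#' @export
compute_renewal <- function(intensities, factors) {
  lab <- dplyr::filter(intensities, .data$fraction %in% LABELING_FRACTIONS)
  missing <- setdiff(unique(lab$analyte), factors$analyte)
  if (length(missing) > 0) {
    abort(sprintf("no calibrated response factors for analyte(s): %s",
                  paste(missing, collapse = ", ")),
          class = "caaflux_calibration_error")
  }
  out <- lab |>
    dplyr::left_join(dplyr::select(factors, "analyte", "w_light", "w_heavy"),
                     by = "analyte") |>
    dplyr::mutate(
      time_h = .data$time_min / 60,
      f = light_fraction(.data$intensity_light, .data$intensity_heavy,
                         .data$w_light, .data$w_heavy)
    ) |>
    dplyr::select("genotype", "replicate", "analyte", "fraction",
                  "time_h", "f")
  low0 <- out$time_h == 0 & out$f < 0.9
  if (any(low0)) {
    warn(sprintf(
      "%d record(s) have renewal < 0.9 at time 0; check for heavy-isotope carryover",
      sum(low0)
    ))
  }
  out
}

#' Vacuolar fraction from a copper-chloride permeabilization assay
#'
#' CuCl2 selectively permeabilizes the plasma membrane, releasing cytosolic
#' solutes into a flowthrough (fraction B) while the vacuole stays largely
#' intact; boiling the remaining cells yields the complete soluble pool
#' (fraction C). With a fiducial cytosolic marker (phenylalanine), the
#' vacuolar share of an amino acid's soluble pool is
#' `f_vac = 1 - R_b / R_c`, where `R_b` and `R_c` are the analyte/marker
#' intensity ratios in fractions B and C. Because CuCl2 can break some
#' vacuoles, the estimate is a conservative lower bound.
#'
#' @param cucl2 Tibble from [read_cucl2_table()] (both fractions present per
#'   sample and analyte).
#' @return Tibble: `sample_id, genotype, analyte, r_b, r_c, f_vac_raw,
#'   f_vac, clipped`, where `f_vac` is `f_vac_raw` clipped to [0, 1] and
#'   `f_vac_raw` retains the unclipped value.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   sample_id = "s1", genotype = "WT", analyte = "lysine",
#'   fraction = c("cytosol_B", "vacuole_C"),
#'   intensity_analyte = c(20, 400), intensity_marker = c(100, 100)
#' )
#' cucl2_vacuolar_fraction(tbl) # f_vac = 1 - 0.2/4 = 0.95
cucl2_vacuolar_fraction <- function(cucl2) {
  wide <- cucl2 |>
    dplyr::mutate(ratio = .data$intensity_analyte / .data$intensity_marker) |>
    dplyr::select("sample_id", "genotype", "analyte", "fraction", "ratio") |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "ratio")
  if (!all(c("cytosol_B", "vacuole_C") %in% names(wide)) ||
      any(is.na(wide$cytosol_B)) || any(is.na(wide$vacuole_C))) {
    abort("each sample/analyte needs both a cytosol_B and a vacuole_C record",
          class = "caaflux_validation_error")
  }
  if (any(wide$vacuole_C <= 0)) {
    abort("vacuole_C analyte/marker ratio is zero: f_vac undefined",
          class = "caaflux_validation_error")
  }
  out <- wide |>
    dplyr::rename(r_b = "cytosol_B", r_c = "vacuole_C") |>
    dplyr::mutate(
      f_vac_raw = 1 - .data$r_b / .data$r_c,
      clipped = .data$f_vac_raw < 0 | .data$f_vac_raw > 1,
      f_vac = pmin(pmax(.data$f_vac_raw, 0), 1)
    )
  if (any(out$clipped)) {
    warn(sprintf("%d f_vac value(s) outside [0, 1] clipped (noise); raw values retained",
                 sum(out$clipped)))
  }
  out
}
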