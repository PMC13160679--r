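#' Run the full labeling analysis on in-memory tables
#'
#' Composes the pipeline stages in order: response-factor calibration from
#' the equimolar standards; conversion of every labeling intensity pair to
#' a renewal fraction; growth-rate fits from turbidity; pool-weight
#' partitioning, conservative rate estimates and the detailed three-pool
#' fit for every genotype x replicate x analyte. All estimates are
#' per-replicate so that replicate spread (SD, n) and any downstream
#' statistical test can be computed directly.
#'
#' @param intensities Tibble from [read_intensity_table()] (or the
#'   synthetic generator).
#' @param standards Tibble from [read_standards_table()].
#' @param growth Tibble from [read_growth_table()], or `NULL`: without
#'   turbidity data the conservative rates are skipped (with a warning) and
#'   the detailed fit runs with `mu` free.
#' @param config A [caa_config()].
#' @param scenario Detailed-fit scenario passed to [fit_detailed_model()];
#'   `"conservative_cap"` uses each culture's conservative `k_ve` as its cap.
#' @param mu_from_growth Fix `mu` in the detailed fit to the
#'   turbidity-derived estimate instead of fitting it (default `FALSE`).
#' @param fit_detailed Run the per-culture detailed fits (default `TRUE`;
#'   `FALSE` stops after the conservative stage, e.g. when a caller refits
#'   jointly).
#' @return A list of class `caa_analysis`: `factors`, `renewal`, `weights`
#'   (tibble of consensus pool weights), `growth_fits`, `conservative`
#'   (tibble), `detailed` (tibble of fit parameters), `fits` (list of
#'   `caa_fit` objects keyed `genotype/replicate/analyte`).
#' @export
#' @examples
#' sim <- simulate_experiment(synthetic_truth(
#'   genotypes = list(WT = model_params(0.03, 0.4, 2)),
#'   noise_cv = 0, seed = 1
#' ))
#' res <- analyze_experiment(sim$intensities, sim$standards, sim$growth)
#' res$detailed
analyze_experiment <- function(intensities, standards, growth = NULL,
                               config = caa_config(),
                               scenario = c("free", "no_export", "conservative_cap"),
                               mu_from_growth = FALSE, fit_detailed = TRUE) {
  scenario <- match.arg(scenario)
  factors <- calibrate_response_factors(
    standards,
    convention = config$calibration_convention,
    aggregation = config$ratio_aggregation
  )
  renewal <- compute_renewal(intensities, factors)

  sample_map <- intensities |>
    dplyr::distinct(.data$sample_id, .data$genotype, .data$replicate)

  growth_fits <- NULL
  mu_by_culture <- NULL
  if (!is.null(growth)) {
    growth_fits <- fit_growth_rates(growth,
                                    intercept = config$regression_intercept)
    mu_by_culture <- growth_fits |>
      dplyr::inner_join(sample_map, by = "sample_id") |>
      dplyr::select("genotype", "replicate", "mu")
  } else {
    warn("no growth table supplied: conservative rates skipped, mu fitted freely")
  }

  conservative <- NULL
  if (!is.null(mu_by_culture)) {
    conservative <- estimate_conservative_rates(renewal, mu_by_culture, config)
  }

  groups <- renewal |>
    dplyr::group_split(.data$genotype, .data$replicate, .data$analyte)
  fits <- list()
  detailed_rows <- list()
  weight_rows <- list()
  for (g in groups) {
    key <- sprintf("%s/%s/%s", g$genotype[1], g$replicate[1], g$analyte[1])
    # the partition degenerates when f_prot ~ f_sol (vacuole and protein
    # renewing at similar rates); the culture is then reported without
    # weights and without a detailed fit rather than failing the run
    w <- tryCatch(pool_weights(g, config), error = function(e) NULL)
    weight_rows[[key]] <- tibble::tibble(
      genotype = g$genotype[1], replicate = g$replicate[1],
      analyte = g$analyte[1],
      s_prot = if (is.null(w)) NA_real_ else w$s_prot,
      s_vac = if (is.null(w)) NA_real_ else w$s_vac,
      ratio_vac_prot = if (is.null(w)) NA_real_ else w$ratio_vac_prot
    )
    if (!fit_detailed) next
    if (is.null(w)) {
      warn(sprintf("pool weights unavailable for %s: detailed fit skipped", key))
      next
    }
    cap <- NULL
    if (scenario == "conservative_cap") {
      if (is.null(conservative)) {
        abort("scenario 'conservative_cap' needs a growth table",
              class = "caaflux_fit_error")
      }
      cap_row <- conservative |>
        dplyr::filter(.data$genotype == g$genotype[1],
                      .data$replicate == g$replicate[1],
                      .data$analyte == g$analyte[1])
      cap <- max(cap_row$k_ve[1], config$bounds_k_ve[1])
    }
    mu_fixed <- NULL
    if (mu_from_growth) {
      if (is.null(mu_by_culture)) {
        abort("mu_from_growth = TRUE needs a growth table",
              class = "caaflux_fit_error")
      }
      mu_fixed <- mu_by_culture |>
        dplyr::filter(.data$genotype == g$genotype[1],
                      .data$replicate == g$replicate[1]) |>
        dplyr::pull("mu")
    }
    fit <- fit_detailed_model(g, w, config, scenario = scenario, cap = cap,
                              mu_fixed = mu_fixed)
    fits[[key]] <- fit
    detailed_rows[[key]] <- tibble::tibble(
      genotype = g$genotype[1], replicate = g$replicate[1],
      analyte = g$analyte[1], scenario = fit$scenario,
      k_pd = fit$k_pd, mu = fit$mu, k_ve = fit$k_ve, K_ve = fit$K_ve,
      ssr = fit$ssr, converged = fit$converged
    )
  }

  structure(list(
    factors = factors,
    renewal = renewal,
    weights = dplyr::bind_rows(weight_rows),
    growth_fits = growth_fits,
    conservative = conservative,
    detailed = dplyr::bind_rows(detailed_rows),
    fits = fits,
    config = config
  ), class = "caa_analysis")
}

#' @export
print.caa_analysis <- function(x, ...) {
  cat("<caa_analysis>\n")
  cat(sprintf("  %d renewal point(s), %d culture fit(s)\n",
              nrow(x$renewal), nrow(x$detailed)))
  print(x$detailed)
  invisible(x)
}

#' Write all analysis outputs to a directory
#'
#' Emits `renewal.csv`, `pool_weights.csv`, `growth_fits.csv`,
#' `conservative_rates.json`, `detailed_fits.json`, a nested
#' `results.json` (genotype -> replicate -> analyte) and a
#' `provenance.json` recording the configuration and package version.
#'
#' @param analysis A `caa_analysis` object.
#' @param out_dir Output directory (created if needed; must not contain the
#'   input files).
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(analysis, out_dir) {
  stopifnot(inherits(analysis, "caa_analysis"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_caa_table(analysis$renewal, file.path(out_dir, "renewal.csv"))
  write_caa_table(analysis$weights, file.path(out_dir, "pool_weights.csv"))
  if (!is.null(analysis$growth_fits)) {
    write_caa_table(analysis$growth_fits, file.path(out_dir, "growth_fits.csv"))
  }
  if (!is.null(analysis$conservative)) {
    write_results(analysis$conservative,
                  file.path(out_dir, "conservative_rates.json"))
  }
  write_results(analysis$detailed, file.path(out_dir, "detailed_fits.json"))

  nested <- list()
  for (i in seq_len(nrow(analysis$detailed))) {
    row <- analysis$detailed[i, ]
    key <- sprintf("%s/%s/%s", row$genotype, row$replicate, row$analyte)
    fit <- analysis$fits[[key]]
    entry <- list(
      scenario = fit$scenario,
      k_pd = fit$k_pd, mu = fit$mu, k_ve = fit$k_ve, K_ve = fit$K_ve,
      ssr = fit$ssr, converged = fit$converged,
      residuals = fit$residuals
    )
    nested[[row$genotype]][[as.character(row$replicate)]][[row$analyte]] <- entry
  }
  write_results(nested, file.path(out_dir, "results.json"))

  prov <- list(
    package = "caaflux",
    version = as.character(utils::packageVersion("caaflux")),
    config = unclass(analysis$config)
  )
  write_results(prov, file.path(out_dir, "provenance.json"))
  invisible(out_dir)
}

#' Renewal overlay plot
#'
#' Plots per-fraction renewal time courses against the pure growth-dilution
#' reference `exp(-mu t)` — the decay expected with no vacuolar export.
#' Requires ggplot2 (optional dependency); purely diagnostic.
#'
#' @param renewal Renewal tibble.
#' @param mu Growth rate for the reference curve (h^-1), or `NULL` to omit.
#' @return A ggplot object.
#' @export
plot_renewal_curves <- function(renewal, mu = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_renewal_curves() needs ggplot2", class = "caaflux_io_error")
  }
  p <- ggplot2::ggplot(renewal, ggplot2::aes(x = .data$time_h, y = .data$f,
                                             colour = .data$fraction)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_grid(analyte ~ genotype) +
    ggplot2::labs(x = "time after medium switch (h)",
                  y = "renewal (light fraction)") +
    ggplot2::theme_minimal()
  if (!is.null(mu)) {
    tt <- seq(0, max(renewal$time_h), length.out = 50)
    ref <- tibble::tibble(time_h = tt, f = exp(-mu * tt))
    p <- p + ggplot2::geom_line(data = ref, ggplot2::aes(x = .data$time_h,
                                                         y = .data$f),
                                inherit.aes = FALSE, linetype = "dashed")
  }
  p
}
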