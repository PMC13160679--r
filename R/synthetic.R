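#' Ground truth for an in-silico labeling experiment
#'
#' Describes a complete simulated study: per-genotype kinetic parameters of
#' the three-pool model, per-analyte true light/heavy response ratios, the
#' intensity noise model, the replication structure and the sampling
#' schedule. Defaults emulate the standard study design: a wild-type strain
#' with substantial vacuolar export and a transporter-deletion strain whose
#' export rate is scaled down five-fold, three biological replicates,
#' samples at 0/20/60/120 min after the light-to-heavy medium switch, a
#' starting OD600 of 0.15, and multiplicative lognormal intensity noise
#' with 5% CV.
#'
#' @param genotypes Named list of [model_params()] objects, one per
#'   genotype.
#' @param response_ratio Named numeric vector (per analyte) of true
#'   equimolar light/heavy intensity ratios.
#' @param abundance_scale Overall intensity scale (arbitrary units).
#' @param noise_cv CV of the multiplicative lognormal noise on every
#'   intensity (0 for noise-free data).
#' @param od_noise_cv CV of the multiplicative noise on OD600 readings.
#' @param n_replicates Biological replicates per genotype.
#' @param time_points_min Sampling schedule, minutes.
#' @param od0 Starting OD600.
#' @param standard_concentrations Calibration dilution series, mM.
#' @param seed Integer seed (mandatory: generation is reproducible).
#' @return A list of class `caa_truth`.
#' @export
synthetic_truth <- function(genotypes = list(
                              "WT" = model_params(k_pd = 0.03, mu = 0.4, k_ve = 2.0),
                              "ypq1\u0394ypq2\u0394" = model_params(k_pd = 0.03, mu = 0.4, k_ve = 0.4)
                            ),
                            response_ratio = c(lysine = 1.25, arginine = 0.8),
                            abundance_scale = 1e6,
                            noise_cv = 0.05,
                            od_noise_cv = 0.01,
                            n_replicates = 3L,
                            time_points_min = c(0, 20, 60, 120),
                            od0 = 0.15,
                            standard_concentrations = c(0.0005, 0.002, 0.008,
                                                        0.03, 0.13, 0.5),
                            seed = 1L) {
  if (length(genotypes) == 0 || is.null(names(genotypes)) ||
      any(names(genotypes) == "")) {
    abort("`genotypes` must be a non-empty named list of model_params",
          class = "caaflux_validation_error")
  }
  for (g in genotypes) stopifnot(inherits(g, "caa_model_params"))
  if (is.null(names(response_ratio)) || any(response_ratio <= 0)) {
    abort("`response_ratio` must be a named positive vector (per analyte)",
          class = "caaflux_validation_error")
  }
  if (noise_cv < 0 || od_noise_cv < 0 || abundance_scale <= 0 || od0 <= 0) {
    abort("noise CVs must be >= 0 and scales > 0",
          class = "caaflux_validation_error")
  }
  if (is.null(seed) || !is.finite(seed)) {
    abort("a finite integer `seed` is mandatory",
          class = "caaflux_validation_error")
  }
  structure(list(
    genotypes = genotypes,
    response_ratio = response_ratio,
    abundance_scale = abundance_scale,
    noise_cv = noise_cv,
    od_noise_cv = od_noise_cv,
    n_replicates = as.integer(n_replicates),
    time_points_min = sort(unique(as.numeric(time_points_min))),
    od0 = od0,
    standard_concentrations = sort(standard_concentrations),
    seed = as.integer(seed)
  ), class = "caa_truth")
}

#' Simulate a complete dynamic labeling experiment
#'
#' For every genotype, replicate and analyte, computes the model-predicted
#' renewal fractions at the scheduled times, converts them into light/heavy
#' intensity pairs through per-analyte response ratios
#' (`I_L = rho_L * A * f`, `I_H = rho_H * A * (1 - f)`, with `rho_L/rho_H`
#' the true response ratio and multiplicative lognormal noise on every
#' intensity), and generates the matching OD600 growth curves and equimolar
#' calibration-standard dilution series. The same seed always yields
#' bit-identical tables.
#'
#' @param truth A [synthetic_truth()] object.
#' @return A list: `intensities`, `standards`, `growth` (tibbles in the CSV
#'   schemas of [read_intensity_table()] etc.) plus the `truth` used.
#' @export
#' @examples
#' sim <- simulate_experiment(synthetic_truth(noise_cv = 0, seed = 7))
#' head(sim$intensities)
simulate_experiment <- function(truth) {
  stopifnot(inherits(truth, "caa_truth"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(truth$seed)

  noise <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  analytes <- names(truth$response_ratio)
  t_min <- truth$time_points_min
  t_h <- t_min / 60

  rows <- list()
  growth_rows <- list()
  for (gt in names(truth$genotypes)) {
    p <- truth$genotypes[[gt]]
    obs <- model_renewal_observables(p, t_h)
    f_by_fraction <- list(soluble = obs$f_sol, protein = obs$f_prot,
                          total = obs$f_tot)
    for (rep_i in seq_len(truth$n_replicates)) {
      sid <- sprintf("%s_r%d", gt, rep_i)
      for (an in analytes) {
        rho_l <- truth$response_ratio[[an]]
        for (fr in names(f_by_fraction)) {
          f <- f_by_fraction[[fr]]
          il <- rho_l * truth$abundance_scale * f *
            noise(length(f), truth$noise_cv)
          ih <- 1 * truth$abundance_scale * (1 - f) *
            noise(length(f), truth$noise_cv)
          rows[[length(rows) + 1]] <- tibble::tibble(
            sample_id = sid, genotype = gt, replicate = rep_i,
            analyte = an, fraction = fr, time_min = t_min,
            intensity_light = il, intensity_heavy = ih
          )
        }
      }
      growth_rows[[length(growth_rows) + 1]] <- tibble::tibble(
        sample_id = sid, time_min = t_min,
        od600 = truth$od0 * exp(p$mu * t_h) *
          noise(length(t_h), truth$od_noise_cv)
      )
    }
  }

  std_rows <- list()
  for (an in analytes) {
    conc <- truth$standard_concentrations
    base <- truth$abundance_scale * conc / max(conc)
    std_rows[[length(std_rows) + 1]] <- tibble::tibble(
      analyte = an, concentration_mM = conc,
      intensity_light = truth$response_ratio[[an]] * base *
        noise(length(conc), truth$noise_cv),
      intensity_heavy = base * noise(length(conc), truth$noise_cv)
    )
  }

  list(
    intensities = dplyr::bind_rows(rows) |>
      dplyr::arrange(.data$genotype, .data$replicate, .data$analyte,
                     .data$fraction, .data$time_min),
    standards = dplyr::bind_rows(std_rows) |>
      dplyr::arrange(.data$analyte, .data$concentration_mM),
    growth = dplyr::bind_rows(growth_rows) |>
      dplyr::arrange(.data$sample_id, .data$time_min),
    truth = truth
  )
}

#' Simulate a copper-chloride permeabilization table
#'
#' Generates analyte and marker intensities for the cytosol-enriched (B)
#' and whole-soluble (C) fractions from a known true vacuolar share
#' `f_vac`, with the same multiplicative noise model as
#' [simulate_experiment()].
#'
#' @param truth A [synthetic_truth()] object.
#' @param f_vac True vacuolar fraction of each analyte's soluble pool.
#' @return A tibble in the [read_cucl2_table()] schema.
#' @export
simulate_cucl2 <- function(truth, f_vac = 0.9) {
  stopifnot(inherits(truth, "caa_truth"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(truth$seed + 104729L)

  noise <- function(n, cv) {
    if (cv <= 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  rows <- list()
  for (gt in names(truth$genotypes)) {
    for (an in names(truth$response_ratio)) {
      total <- truth$abundance_scale
      marker <- truth$abundance_scale / 2
      # fraction B holds the cytosolic share, fraction C the whole soluble pool
      ib <- (1 - f_vac) * total * noise(1, truth$noise_cv)
      ic <- total * noise(1, truth$noise_cv)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = sprintf("%s_cucl2", gt), genotype = gt, analyte = an,
        fraction = c("cytosol_B", "vacuole_C"),
        intensity_analyte = c(ib, ic),
        intensity_marker = marker * noise(2, truth$noise_cv)
      )
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$sample_id, .data$analyte, .data$fraction)
}

#' Simulate-then-fit parameter recovery study
#'
#' Repeats the full simulate-analyze round trip `n_trials` times with
#' derived seeds: each trial generates a complete experiment from `truth`,
#' runs calibration, renewal computation, growth fitting, pool-weight
#' partitioning, the conservative rate estimate and the free-scenario
#' detailed fit, and records fitted vs true parameters per genotype,
#' replicate and analyte. The summary reports, per genotype and parameter,
#' the median relative error and the spread of the estimates, and places
#' the conservative export estimate next to the truth to exhibit its
#' systematic underestimation.
#'
#' @param truth A [synthetic_truth()] object.
#' @param n_trials Number of independent simulated experiments.
#' @param config A [caa_config()].
#' @param pooled If `FALSE` (default) each replicate culture is fitted
#'   independently, as in the analysis pipeline; if `TRUE` the renewal
#'   points of all replicates of a genotype enter one joint fit with
#'   consensus pool weights, so the replicate count directly reduces the
#'   recovery error.
#' @param weights_source `"estimated"` (default): the fit uses pool weights
#'   partitioned from the simulated data, as the pipeline would on real
#'   data; `"truth"`: the generator's true pool weights are used, isolating
#'   the fitter from the pool-partitioning stage (the noise-free round trip
#'   is exact only under known weights, since estimated weights carry the
#'   nominal-cytosol approximation).
#' @return A list of class `caa_recovery`: `trials` (per-fit tibble) and
#'   `summary` (per genotype x parameter tibble), `n_failed`.
#' @export
recovery_experiment <- function(truth, n_trials = 20L,
                                config = caa_config(), pooled = FALSE,
                                weights_source = c("estimated", "truth")) {
  stopifnot(inherits(truth, "caa_truth"), n_trials >= 1)
  weights_source <- match.arg(weights_source)
  trial_rows <- list()
  n_failed <- 0L
  truth_tbl <- tibble::tibble(
    genotype = names(truth$genotypes),
    k_pd_true = vapply(truth$genotypes, `[[`, numeric(1), "k_pd"),
    mu_true = vapply(truth$genotypes, `[[`, numeric(1), "mu"),
    k_ve_true = vapply(truth$genotypes, `[[`, numeric(1), "k_ve")
  )
  for (trial in seq_len(n_trials)) {
    tr <- truth
    tr$seed <- (truth$seed + 7919L * trial) %% .Machine$integer.max
    sim <- simulate_experiment(tr)
    res <- tryCatch(
      analyze_experiment(sim$intensities, sim$standards, sim$growth,
                         config = config, fit_detailed = FALSE),
      error = function(e) NULL
    )
    fits <- if (!is.null(res)) {
      tryCatch(recovery_fits(res, truth, config, pooled, weights_source),
               error = function(e) NULL)
    }
    if (is.null(fits)) {
      n_failed <- n_failed + 1L
      next
    }
    fits$trial <- trial
    trial_rows[[length(trial_rows) + 1]] <-
      dplyr::left_join(fits, truth_tbl, by = "genotype")
  }
  if (length(trial_rows) == 0) {
    abort("all recovery trials failed", class = "caaflux_fit_error")
  }
  trials <- dplyr::bind_rows(trial_rows)

  summary <- trials |>
    tidyr::pivot_longer(cols = c("k_pd", "mu", "k_ve"),
                        names_to = "parameter", values_to = "estimate") |>
    dplyr::mutate(truth_val = dplyr::case_when(
      .data$parameter == "k_pd" ~ .data$k_pd_true,
      .data$parameter == "mu" ~ .data$mu_true,
      .data$parameter == "k_ve" ~ .data$k_ve_true
    )) |>
    dplyr::group_by(.data$genotype, .data$analyte, .data$parameter) |>
    dplyr::summarise(
      truth = .data$truth_val[1],
      median_rel_error = median(abs(.data$estimate - .data$truth_val) /
                                  .data$truth_val),
      median_estimate = median(.data$estimate),
      sd_estimate = sd(.data$estimate),
      n = dplyr::n(),
      .groups = "drop"
    )

  structure(list(trials = trials, summary = summary, n_failed = n_failed),
            class = "caa_recovery")
}

#' @export
print.caa_recovery <- function(x, ...) {
  cat(sprintf("<caa_recovery> %d fit(s), %d failed trial(s)\n",
              nrow(x$trials), x$n_failed))
  print(x$summary)
  invisible(x)
}

# Free-scenario fits for a recovery trial: per replicate or pooled across
# replicates, with pool weights either estimated from the data or taken
# from the generating truth. The conservative k_ve estimate rides along
# for the underestimation comparison.
recovery_fits <- function(res, truth, config, pooled, weights_source) {
  truth_weights <- function(gt) {
    p <- truth$genotypes[[gt]]
    list(s_prot = p$s2 / (p$s2 + p$s3), s_vac = p$s3 / (p$s2 + p$s3))
  }
  if (pooled) {
    groups <- res$renewal |>
      dplyr::group_split(.data$genotype, .data$analyte)
  } else {
    groups <- res$renewal |>
      dplyr::group_split(.data$genotype, .data$replicate, .data$analyte)
  }
  purrr::map(groups, function(g) {
    gt <- g$genotype[1]
    w <- if (weights_source == "truth") {
      truth_weights(gt)
    } else if (pooled) {
      w_tbl <- res$weights |>
        dplyr::filter(.data$genotype == gt, .data$analyte == g$analyte[1])
      list(s_prot = mean(w_tbl$s_prot), s_vac = mean(w_tbl$s_vac))
    } else {
      pool_weights(g, config)
    }
    fit <- fit_detailed_model(g, w, config, scenario = "free")
    cons <- res$conservative |>
      dplyr::filter(.data$genotype == gt, .data$analyte == g$analyte[1])
    if (!pooled) cons <- dplyr::filter(cons, .data$replicate == g$replicate[1])
    out <- tibble::tibble(
      genotype = gt, analyte = g$analyte[1],
      scenario = fit$scenario, k_pd = fit$k_pd, mu = fit$mu,
      k_ve = fit$k_ve, K_ve = fit$K_ve, ssr = fit$ssr,
      converged = fit$converged, k_ve_cons = mean(cons$k_ve)
    )
    if (!pooled) out$replicate <- g$replicate[1]
    out
  }) |>
    dplyr::bind_rows()
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}
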