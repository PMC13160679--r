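#' Fit an exponential growth rate from OD600 turbidity
#'
#' Under balanced exponential growth, `ln(OD(t)/OD(0)) = mu * t`. The growth
#' rate is the least-squares slope of the log-transformed ratio against time
#' in hours, through the origin by default (the model has no intercept; an
#' intercept is available as a diagnostic). R-squared is reported against the
#' same model (uncentered for the through-origin fit) on the log scale, the
#' standard check that growth really was exponential.
#'
#' @param growth Growth tibble (`sample_id, time_min, od600`) for a single
#'   culture, or any tibble with those columns and one unique `sample_id`.
#' @param intercept Include an intercept in the regression?
#' @return A one-row tibble: `sample_id, mu, r_squared, n_points`.
#' @export
#' @examples
#' g <- tibble::tibble(sample_id = "c1", time_min = c(0, 120),
#'                     od600 = c(0.15, 0.15 * exp(0.8)))
#' fit_growth_rate(g) # mu = 0.4 h^-1
fit_growth_rate <- function(growth, intercept = FALSE) {
  if (length(unique(growth$sample_id)) != 1) {
    abort("fit_growth_rate() expects a single culture; see fit_growth_rates()",
          class = "caaflux_validation_error")
  }
  if (any(growth$od600 <= 0)) {
    abort("od600 must be > 0", class = "caaflux_validation_error")
  }
  t_h <- growth$time_min / 60
  if (length(unique(t_h)) < 2) {
    abort("need at least two distinct time points per culture",
          class = "caaflux_validation_error")
  }
  if (!intercept && !any(t_h == 0)) {
    abort("through-origin growth fit requires a time-0 OD measurement",
          class = "caaflux_validation_error")
  }

  if (intercept) {
    fit <- stats::lm(log(od600) ~ t_h, data = data.frame(od600 = growth$od600, t_h = t_h))
    mu <- unname(stats::coef(fit)[2])
    r2 <- summary(fit)$r.squared
  } else {
    od0 <- mean(growth$od600[t_h == 0])
    y <- log(growth$od600 / od0)
    sl <- slope_through_origin(t_h, y)
    mu <- sl$slope
    r2 <- sl$r_squared
  }
  tibble::tibble(sample_id = growth$sample_id[1], mu = mu,
                 r_squared = r2, n_points = length(t_h))
}

#' Fit growth rates for every culture in a growth table
#'
#' @inheritParams fit_growth_rate
#' @return A tibble with one row per `sample_id`.
#' @export
fit_growth_rates <- function(growth, intercept = FALSE) {
  growth |>
    dplyr::group_split(.data$sample_id) |>
    purrr::map(fit_growth_rate, intercept = intercept) |>
    dplyr::bind_rows()
}

#' Fractional turnover rate from log-linear renewal decay
#'
#' Single-exponential renewal decay `f(t) = exp(-k t)` linearizes to
#' `-ln f(t) = k t`; the rate is the least-squares slope through the origin
#' (the boundary condition f(0) = 1 is part of the model). Applied to the
#' soluble-pool renewal this gives the bulk vacuolar import rate `k`; applied
#' to the total-pool renewal it gives the total cellular import rate `k_tot`.
#' Fractions at or below zero are floored at `epsilon` (with a warning)
#' before the logarithm.
#'
#' @param time_h Times in hours.
#' @param f Renewal fractions in (0, 1].
#' @param intercept Include an intercept (diagnostic)?
#' @param epsilon Floor for non-positive fractions.
#' @return A list: `rate` (h^-1), `r_squared`, `n`.
#' @export
#' @examples
#' t <- c(0, 1/3, 1, 2)
#' fit_fractional_rate(t, exp(-0.6 * t))$rate # 0.6
fit_fractional_rate <- function(time_h, f, intercept = FALSE, epsilon = 1e-6) {
  keep <- is.finite(time_h) & is.finite(f)
  time_h <- time_h[keep]; f <- f[keep]
  if (length(time_h) < 2) {
    abort("need at least two usable renewal points",
          class = "caaflux_validation_error")
  }
  if (any(f <= 0)) {
    warn(sprintf("%d renewal value(s) <= 0 floored at %g before log",
                 sum(f <= 0), epsilon))
    f <- pmax(f, epsilon)
  }
  y <- -log(f)
  if (intercept) {
    fit <- stats::lm(y ~ time_h)
    list(rate = unname(stats::coef(fit)[2]),
         r_squared = summary(fit)$r.squared, n = length(y))
  } else {
    sl <- slope_through_origin(time_h, y)
    list(rate = sl$slope, r_squared = sl$r_squared, n = length(y))
  }
}

#' Partition the amino acid pool between protein and vacuole
#'
#' All cellular cationic amino acids are taken to reside either in protein
#' or in the (vacuolar) soluble pool, so the total renewal is the
#' pool-weighted mixture `f_tot = S_vac * f_sol + S_prot * f_prot` with
#' `S_vac + S_prot = 1`. Inverting at each labeling time point gives
#' `S_prot(t) = (f_tot - f_sol) / (f_prot - f_sol)` and
#' `S_vac(t) = (f_prot - f_tot) / (f_prot - f_sol)`. Time 0 is always
#' excluded (all fractions are 1: 0/0). Per-time-point values outside
#' `[-0.05, 1.05]` are rejected as inconsistent; values inside but outside
#' [0, 1] are clipped with a warning. Consensus weights are the arithmetic
#' mean over usable time points.
#'
#' @param renewal Renewal tibble for a single genotype/replicate/analyte,
#'   containing fractions `total`, `soluble` and `protein` at shared times.
#' @param config A [caa_config()] (supplies the nominal cytosolic weight).
#' @return A list of class `caa_pool_weights`: `by_time` (tibble of
#'   per-time-point weights), consensus `s_prot` and `s_vac`,
#'   `ratio_vac_prot`, `s1_cyto`, plus the identifying columns.
#' @export
pool_weights <- function(renewal, config = caa_config()) {
  wide <- renewal |>
    dplyr::select("time_h", "fraction", "f") |>
    tidyr::pivot_wider(names_from = "fraction", values_from = "f") |>
    dplyr::arrange(.data$time_h)
  need <- c("total", "soluble", "protein")
  if (!all(need %in% names(wide))) {
    abort(sprintf("pool_weights() needs fractions %s", paste(need, collapse = ", ")),
          class = "caaflux_validation_error")
  }
  wide <- dplyr::filter(wide, .data$time_h > 0)

  denom <- wide$protein - wide$soluble
  degenerate <- denom == 0
  if (any(degenerate)) {
    warn(sprintf("f_prot = f_sol at time(s) %s h: point(s) skipped",
                 paste(wide$time_h[degenerate], collapse = ", ")))
  }
  s_prot_t <- ifelse(degenerate, NA_real_, (wide$total - wide$soluble) / denom)
  s_vac_t <- ifelse(degenerate, NA_real_, (wide$protein - wide$total) / denom)

  inconsistent <- !is.na(s_prot_t) & (s_prot_t < -0.05 | s_prot_t > 1.05)
  if (any(inconsistent)) {
    warn(sprintf("pool weight(s) outside [-0.05, 1.05] at time(s) %s h rejected",
                 paste(wide$time_h[inconsistent], collapse = ", ")))
    s_prot_t[inconsistent] <- NA_real_
    s_vac_t[inconsistent] <- NA_real_
  }
  clip <- !is.na(s_prot_t) & (s_prot_t < 0 | s_prot_t > 1)
  if (any(clip)) {
    warn(sprintf("pool weight(s) slightly outside [0, 1] at time(s) %s h clipped",
                 paste(wide$time_h[clip], collapse = ", ")))
    s_prot_t <- pmin(pmax(s_prot_t, 0), 1)
    s_vac_t <- 1 - s_prot_t
  }

  usable <- !is.na(s_prot_t)
  if (!any(usable)) {
    abort("no usable time points for pool weights",
          class = "caaflux_validation_error")
  }
  s_prot <- mean(s_prot_t[usable])
  s_vac <- mean(s_vac_t[usable])

  structure(list(
    genotype = first_or_na(renewal$genotype),
    replicate = first_or_na(renewal$replicate),
    analyte = first_or_na(renewal$analyte),
    by_time = tibble::tibble(time_h = wide$time_h, s_prot = s_prot_t,
                             s_vac = s_vac_t, usable = usable),
    s_prot = s_prot,
    s_vac = s_vac,
    ratio_vac_prot = s_vac / s_prot,
    s1_cyto = config$s1_cyto
  ), class = "caa_pool_weights")
}

#' @export
print.caa_pool_weights <- function(x, ...) {
  cat(sprintf("<caa_pool_weights> %s / rep %s / %s\n",
              x$genotype, x$replicate, x$analyte))
  cat(sprintf("  S_prot = %.4f, S_vac = %.4f (vacuole-to-protein ratio %.3f)\n",
              x$s_prot, x$s_vac, x$ratio_vac_prot))
  invisible(x)
}

#' Conservative vacuolar transport rates
#'
#' The conservative model treats every heavy amino acid entering the vacuole
#' as imported directly from the medium, so the soluble-pool renewal decays
#' as `exp(-k t)` with `k` the bulk vacuolar import rate. At steady state the
#' vacuolar import supports both export to the cytosol and growth of the
#' vacuolar pool, so the fractional export rate is `k_ve = k - mu`. Because
#' recycled (light) material also enters the vacuole in reality, `k`
#' underestimates total import and `k_ve` is a guaranteed lower bound on the
#' true export rate. Net import is pinned to growth: `k_vi = mu`. Rates are
#' converted from vacuolar-pool to protein-pool units via the pool-size
#' ratio: `K_ve = k_ve * S_vac / S_prot`, `K_vi = mu * S_vac / S_prot`;
#' total import converts as `K_tot = k_tot / S_prot` (dimensional form; see
#' [caa_config()] for the literal-product alternative).
#'
#' @param k Bulk vacuolar import rate (h^-1), slope of `-ln f_sol` vs t.
#' @param mu Growth rate (h^-1).
#' @param k_tot Total cellular import rate (h^-1), slope of `-ln f_tot` vs t.
#' @param weights A `caa_pool_weights` object (or list with `s_prot`,
#'   `s_vac`).
#' @param config A [caa_config()] (controls the `K_tot` conversion).
#' @return A one-row tibble of class: `k, mu, k_ve, k_ve_clipped, k_vi,
#'   k_tot, K_ve, K_vi, K_tot, s_prot, s_vac`.
#' @export
#' @examples
#' w <- list(s_prot = 0.6, s_vac = 0.4)
#' conservative_rates(k = 0.6, mu = 0.4, k_tot = 0.5, weights = w)
conservative_rates <- function(k, mu, k_tot, weights, config = caa_config()) {
  stopifnot(is.finite(k), is.finite(mu))
  s_prot <- weights$s_prot %||% NA_real_
  s_vac <- weights$s_vac %||% NA_real_
  if (is.finite(s_prot) && s_prot <= 0) {
    abort("conversion to protein-pool units requires s_prot > 0",
          class = "caaflux_validation_error")
  }
  k_ve_raw <- k - mu
  clipped <- k_ve_raw < 0
  k_ve <- max(k_ve_raw, 0)
  # rates in vacuolar-/total-pool units stand on their own; the protein-pool
  # conversions become NA when the pool partition is unavailable
  ratio <- s_vac / s_prot
  K_tot <- if (is.finite(k_tot)) {
    if (config$ktot_conversion == "quotient") k_tot / s_prot
    else k_tot * s_prot
  } else NA_real_
  tibble::tibble(
    k = k, mu = mu, k_ve = k_ve, k_ve_clipped = clipped, k_vi = mu,
    k_tot = k_tot,
    K_ve = k_ve * ratio, K_vi = mu * ratio, K_tot = K_tot,
    s_prot = s_prot, s_vac = s_vac
  )
}

#' Conservative rates for every culture in a renewal table
#'
#' Groups a renewal table by genotype, replicate and analyte; fits the bulk
#' vacuolar import rate from the soluble fraction and the total import rate
#' from the total fraction; combines them with the per-culture growth rate
#' and pool weights into [conservative_rates()].
#'
#' @param renewal Renewal tibble (all genotypes/replicates/analytes).
#' @param mu_by_culture Tibble `genotype, replicate, mu` (e.g. growth-rate
#'   fits joined to the sample map).
#' @param config A [caa_config()].
#' @return A tibble with one row per genotype/replicate/analyte, including
#'   the regression diagnostics `k_r_squared` and `k_tot_r_squared`.
#' @export
estimate_conservative_rates <- function(renewal, mu_by_culture,
                                        config = caa_config()) {
  groups <- renewal |>
    dplyr::group_split(.data$genotype, .data$replicate, .data$analyte)
  purrr::map(groups, function(g) {
    mu_row <- dplyr::semi_join(mu_by_culture, g[1, c("genotype", "replicate")],
                               by = c("genotype", "replicate"))
    if (nrow(mu_row) == 0) {
      abort(sprintf("no growth rate for %s replicate %s",
                    g$genotype[1], g$replicate[1]),
            class = "caaflux_validation_error")
    }
    mu <- mu_row$mu[1]
    sol <- dplyr::filter(g, .data$fraction == "soluble")
    tot <- dplyr::filter(g, .data$fraction == "total")
    fit_k <- fit_fractional_rate(sol$time_h, sol$f,
                                 intercept = config$regression_intercept,
                                 epsilon = config$epsilon_fraction_floor)
    fit_ktot <- if (nrow(tot) >= 2) {
      fit_fractional_rate(tot$time_h, tot$f,
                          intercept = config$regression_intercept,
                          epsilon = config$epsilon_fraction_floor)
    } else {
      list(rate = NA_real_, r_squared = NA_real_)
    }
    # the pool partition degenerates when vacuole and protein renew at
    # similar rates (f_prot ~ f_sol); rates survive, conversions become NA
    w <- tryCatch(pool_weights(g, config), error = function(e) {
      warn(sprintf("pool weights unavailable for %s/%s/%s: %s",
                   g$genotype[1], g$replicate[1], g$analyte[1],
                   conditionMessage(e)))
      list(s_prot = NA_real_, s_vac = NA_real_)
    })
    dplyr::bind_cols(
      tibble::tibble(genotype = g$genotype[1], replicate = g$replicate[1],
                     analyte = g$analyte[1]),
      conservative_rates(fit_k$rate, mu, fit_ktot$rate, w, config),
      tibble::tibble(k_r_squared = fit_k$r_squared,
                     k_tot_r_squared = fit_ktot$r_squared)
    )
  }) |>
    dplyr::bind_rows()
}

# -- internal -----------------------------------------------------------------

# Least-squares slope of y on x through the origin, with uncentered R^2
# (the conventional definition for a no-intercept model).
slope_through_origin <- function(x, y) {
  sxx <- sum(x^2)
  if (sxx == 0) {
    abort("degenerate regressor: all time points identical (or all zero)",
          class = "caaflux_validation_error")
  }
  slope <- sum(x * y) / sxx
  ss_res <- sum((y - slope * x)^2)
  ss_tot <- sum(y^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  list(slope = slope, r_squared = r2)
}

first_or_na <- function(x) if (length(x) > 0) x[[1]] else NA
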