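#' Parameters of the three-pool labeling model
#'
#' The detailed model represents the cationic amino acid content of a
#' growing yeast cell as three well-mixed pools: cytosol (weight `s1`),
#' protein-borne (`s2`) and vacuolar (`s3`), exchanging material at
#' constant fractional rates during balanced exponential growth. The free
#' kinetic parameters are the protein degradation rate `k_pd` (per protein
#' pool), the growth rate `mu`, and the fractional vacuolar export rate
#' `k_ve` (per vacuolar pool). Pool weights must be positive; by default
#' `s2` and `s3` are rescaled by `(1 - s1)` of their sum so the three
#' weights add to one (`renormalize = FALSE` preserves the supplied values
#' when they already include the cytosol).
#'
#' @param k_pd Protein degradation rate, h^-1.
#' @param mu Growth rate, h^-1.
#' @param k_ve Fractional vacuolar export rate, h^-1.
#' @param s1 Cytosolic pool weight (nominally small).
#' @param s2 Protein pool weight.
#' @param s3 Vacuolar pool weight.
#' @param renormalize Rescale `s2`, `s3` so that `s1 + s2 + s3 = 1`.
#' @return A list of class `caa_model_params`.
#' @export
#' @examples
#' model_params(k_pd = 0.03, mu = 0.4, k_ve = 2)
model_params <- function(k_pd, mu, k_ve, s1 = 0.01, s2 = 0.6, s3 = 0.39,
                         renormalize = TRUE) {
  vals <- c(k_pd = k_pd, mu = mu, k_ve = k_ve)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("rates k_pd, mu, k_ve must be finite and >= 0",
          class = "caaflux_model_error")
  }
  if (s1 <= 0 || s2 <= 0 || s3 <= 0) {
    abort("pool weights must be strictly positive",
          class = "caaflux_model_error")
  }
  if (renormalize) {
    scale <- (1 - s1) / (s2 + s3)
    s2 <- s2 * scale
    s3 <- s3 * scale
  }
  structure(list(k_pd = k_pd, mu = mu, k_ve = k_ve,
                 s1 = s1, s2 = s2, s3 = s3),
            class = "caa_model_params")
}

#' @export
print.caa_model_params <- function(x, ...) {
  cat(sprintf(
    "<caa_model_params> k_pd = %.4g, mu = %.4g, k_ve = %.4g h^-1; S = (%.3g, %.3g, %.3g)\n",
    x$k_pd, x$mu, x$k_ve, x$s1, x$s2, x$s3
  ))
  invisible(x)
}

#' Transition matrix of the labeling dynamics
#'
#' Builds the 3x3 generator `M` of the linear labeling ODE
#' `df/dt = M f`, where `f` is the vector of light (pre-switch) fractions in
#' (cytosol, protein, vacuole). Contributed turnovers `k_ij` (source pool i,
#' recipient pool j, in units of the recipient pool size) follow from mass
#' balance at steady state:
#' `k_e1 = mu / s1` (external influx into the cytosol supports growth of the
#' whole system), `k_21 = k_pd * s2 / s1`, `k_12 = mu + k_pd` (protein
#' synthesis balances degradation plus growth), `k_31 = k_ve * s3 / s1`,
#' `k_13 = mu + k_ve` (vacuolar import balances export plus growth). The
#' matrix is
#' \preformatted{
#'   [ -k_e1 - k_21 - k_31   k_21    k_31  ]
#'   [  k_12                -k_12    0     ]
#'   [  k_13                 0      -k_13  ]
#' }
#' Rows 2 and 3 sum to zero; row 1 sums to `-k_e1`, the dilution of the
#' cytosolic pool by fully-heavy external influx.
#'
#' @param params A [model_params()] object.
#' @return A list of class `caa_transition_matrix`: `m` (3x3 matrix,
#'   order cytosol/protein/vacuole), `turnovers` (named vector), `params`.
#' @export
build_transition_matrix <- function(params) {
  stopifnot(inherits(params, "caa_model_params"))
  if (params$s1 <= 0) {
    abort("s1 = 0 gives a singular parametrization",
          class = "caaflux_model_error")
  }
  k_e1 <- params$mu / params$s1
  k_21 <- params$k_pd * params$s2 / params$s1
  k_12 <- params$mu + params$k_pd
  k_31 <- params$k_ve * params$s3 / params$s1
  k_13 <- params$mu + params$k_ve
  m <- matrix(c(
    -k_e1 - k_21 - k_31, k_21, k_31,
    k_12, -k_12, 0,
    k_13, 0, -k_13
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("cytosol", "protein", "vacuole"),
                  c("cytosol", "protein", "vacuole")))
  structure(list(
    m = m,
    turnovers = c(k_e1 = k_e1, k_12 = k_12, k_21 = k_21,
                  k_13 = k_13, k_31 = k_31),
    params = params
  ), class = "caa_transition_matrix")
}

#' Propagate labeling through time by matrix exponentiation
#'
#' The labeling ODE `df/dt = M f` with the fully-light initial condition
#' `f(0) = (1, 1, 1)` has the closed-form solution `f(t) = exp(M t) 1`.
#' Each component lies in [0, 1] and is non-increasing in time; values are
#' clipped to [0, 1] only to absorb rounding at the 1e-15 level.
#'
#' @param tm A `caa_transition_matrix` (or a [model_params()] object, which
#'   is converted).
#' @param times_h Non-negative times, hours.
#' @return A numeric matrix, one row per time, columns `cytosol`, `protein`,
#'   `vacuole`.
#' @export
#' @examples
#' p <- model_params(0.03, 0.4, 2)
#' propagate_labeling(p, c(0, 1, 2))
propagate_labeling <- function(tm, times_h) {
  if (inherits(tm, "caa_model_params")) tm <- build_transition_matrix(tm)
  stopifnot(inherits(tm, "caa_transition_matrix"))
  if (any(times_h < 0)) {
    abort("times must be >= 0", class = "caaflux_model_error")
  }
  m <- tm$m
  one <- rep(1, 3)
  out <- t(vapply(times_h, function(t) {
    if (t == 0) return(one)
    as.numeric(Matrix::expm(m * t) %*% one)
  }, numeric(3)))
  out <- pmin(pmax(out, 0), 1)
  dimnames(out) <- list(NULL, c("cytosol", "protein", "vacuole"))
  out
}

#' Model-predicted renewal observables
#'
#' Maps the propagated compartment labeling onto the three measured
#' quantities: `f_sol` is the vacuolar component (the soluble pool is
#' vacuole-dominated), `f_prot` the protein component, and `f_tot` the
#' pool-weighted mixture `(s1 f_cyt + s2 f_prot + s3 f_sol) / (s1+s2+s3)`
#' (with the nominal cytosol included for self-consistency; at `s1 = 0.01`
#' it differs from the two-pool mixture by at most `s1`).
#'
#' @param params A [model_params()] object.
#' @param times_h Times, hours.
#' @return Tibble: `time_h, f_cyt, f_prot, f_sol, f_tot`.
#' @export
model_renewal_observables <- function(params, times_h) {
  f <- propagate_labeling(params, times_h)
  s <- c(params$s1, params$s2, params$s3)
  f_tot <- (f %*% s)[, 1] / sum(s)
  tibble::tibble(
    time_h = times_h,
    f_cyt = unname(f[, "cytosol"]),
    f_prot = unname(f[, "protein"]),
    f_sol = unname(f[, "vacuole"]),
    f_tot = unname(f_tot)
  )
}

#' Fit the three-pool model to renewal time courses
#'
#' Estimates `(k_pd, mu, k_ve)` by bounded nonlinear least squares,
#' minimizing the unweighted sum of squared residuals of the protein- and
#' soluble-pool renewal predictions against the observations. Pool weights
#' are taken from the data (consensus `S_prot`, `S_vac`) with the cytosolic
#' weight pinned to `config$s1_cyto`. Because the three-parameter landscape
#' can hold local minima at the `k_ve` bounds, starting values are laid out
#' on a grid over the box (log-spaced along `k_ve`), screened by objective
#' value, and the best `config$n_polish` starts are refined with the
#' Levenberg-Marquardt optimizer; the best refined solution wins. The
#' procedure is deterministic.
#'
#' Scenarios: `"free"` lets `k_ve` vary over its full bounds; `"no_export"`
#' pins `k_ve` at its lower bound (effectively no vacuolar export);
#' `"conservative_cap"` caps `k_ve` from above by the conservative
#' estimate `cap`. The feasible sets are nested, so the minimized SSR is
#' ordered no_export >= conservative_cap >= free.
#'
#' @param observed Renewal tibble with fractions `soluble` and `protein`
#'   (columns `fraction, time_h, f`); at least three distinct positive time
#'   points.
#' @param weights A `caa_pool_weights` object (or list with `s_prot`,
#'   `s_vac`).
#' @param config A [caa_config()].
#' @param scenario One of `"free"`, `"no_export"`, `"conservative_cap"`.
#' @param cap Upper bound for `k_ve` (h^-1); required when
#'   `scenario = "conservative_cap"`.
#' @param mu_fixed Optionally fix `mu` to a turbidity-derived value instead
#'   of fitting it.
#' @param extra_starts Optional list of named numeric vectors
#'   `c(k_pd=, mu=, k_ve=)` added to the polished starts (used to chain
#'   scenario fits).
#' @return A list of class `caa_fit`: fitted `params`, `k_pd`, `mu`, `k_ve`,
#'   `K_ve` (protein-pool units), `scenario`, `ssr`, `residuals` tibble,
#'   `converged`, `n_starts`, `best_start`.
#' @export
fit_detailed_model <- function(observed, weights, config = caa_config(),
                               scenario = c("free", "no_export", "conservative_cap"),
                               cap = NULL, mu_fixed = NULL,
                               extra_starts = list()) {
  scenario <- match.arg(scenario)
  obs <- observed |>
    dplyr::filter(.data$fraction %in% c("soluble", "protein")) |>
    dplyr::select("fraction", "time_h", "f")
  if (length(unique(obs$time_h[obs$time_h > 0])) < 3) {
    abort("need at least three distinct post-switch time points",
          class = "caaflux_fit_error")
  }
  s1 <- config$s1_cyto
  if (config$renormalize_pools) {
    s2 <- weights$s_prot * (1 - s1)
    s3 <- weights$s_vac * (1 - s1)
  } else {
    s2 <- weights$s_prot
    s3 <- weights$s_vac
  }

  lb <- c(k_pd = config$bounds_k_pd[1], mu = config$bounds_mu[1],
          k_ve = config$bounds_k_ve[1])
  ub <- c(k_pd = config$bounds_k_pd[2], mu = config$bounds_mu[2],
          k_ve = config$bounds_k_ve[2])
  if (scenario == "no_export") {
    ub["k_ve"] <- lb["k_ve"]
  } else if (scenario == "conservative_cap") {
    if (is.null(cap)) {
      abort("scenario 'conservative_cap' requires `cap`",
            class = "caaflux_fit_error")
    }
    if (cap < lb["k_ve"]) {
      abort(sprintf("cap %.4g below the k_ve lower bound %.4g", cap, lb["k_ve"]),
            class = "caaflux_fit_error")
    }
    ub["k_ve"] <- min(ub["k_ve"], cap)
  }
  if (!is.null(mu_fixed)) {
    mu_fixed <- min(max(mu_fixed, lb["mu"]), ub["mu"])
    lb["mu"] <- ub["mu"] <- mu_fixed
  }
  free <- which(ub > lb)
  fixed <- setNames(lb, names(lb))

  times <- sort(unique(obs$time_h))
  obs_prot <- obs$f[obs$fraction == "protein"][order(obs$time_h[obs$fraction == "protein"])]
  obs_sol <- obs$f[obs$fraction == "soluble"][order(obs$time_h[obs$fraction == "soluble"])]
  t_prot <- sort(obs$time_h[obs$fraction == "protein"])
  t_sol <- sort(obs$time_h[obs$fraction == "soluble"])

  resid_fun <- function(theta_free) {
    th <- fixed
    th[free] <- theta_free
    p <- model_params(th["k_pd"], th["mu"], th["k_ve"],
                      s1 = s1, s2 = s2, s3 = s3, renormalize = FALSE)
    pred <- model_renewal_observables(p, times)
    pred_prot <- pred$f_prot[match(t_prot, pred$time_h)]
    pred_sol <- pred$f_sol[match(t_sol, pred$time_h)]
    c(obs_prot - pred_prot, obs_sol - pred_sol)
  }

  starts <- multistart_grid_points(lb, ub, free, config$multistart_grid)
  for (es in extra_starts) {
    th <- pmin(pmax(es[names(lb)], lb), ub)
    starts <- rbind(starts, th[free])
  }
  ssr0 <- apply(starts, 1, function(s) sum(resid_fun(s)^2))
  n_polish <- min(max(config$n_polish, 1L), nrow(starts))
  # polish the globally best grid points, the best start at every k_ve grid
  # level (the landscape can hold a spurious minimum at the k_ve bounds, so
  # screening alone must not discard whole k_ve strata), and all chained
  # extra starts
  polish_idx <- order(ssr0)[seq_len(n_polish)]
  if ("k_ve" %in% colnames(starts)) {
    for (lev in unique(starts[, "k_ve"])) {
      at_lev <- which(starts[, "k_ve"] == lev)
      polish_idx <- union(polish_idx, at_lev[which.min(ssr0[at_lev])])
    }
  }
  if (length(extra_starts) > 0) {
    polish_idx <- union(polish_idx,
                        nrow(starts) - rev(seq_along(extra_starts)) + 1)
  }

  best <- NULL
  for (i in polish_idx) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], lower = lb[free], upper = ub[free],
        fn = resid_fun,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    if (is.null(best) || ssr < best$ssr) {
      best <- list(fit = fit, ssr = ssr, start = i)
    }
  }
  if (is.null(best)) {
    abort("no optimizer start converged", class = "caaflux_fit_error")
  }

  th <- fixed
  th[free] <- best$fit$par
  p_hat <- model_params(th["k_pd"], th["mu"], th["k_ve"],
                        s1 = s1, s2 = s2, s3 = s3, renormalize = FALSE)
  pred <- model_renewal_observables(p_hat, times)
  res_tbl <- dplyr::bind_rows(
    tibble::tibble(fraction = "protein", time_h = t_prot, observed = obs_prot,
                   predicted = pred$f_prot[match(t_prot, pred$time_h)]),
    tibble::tibble(fraction = "soluble", time_h = t_sol, observed = obs_sol,
                   predicted = pred$f_sol[match(t_sol, pred$time_h)])
  )
  res_tbl$residual <- res_tbl$observed - res_tbl$predicted

  structure(list(
    params = p_hat,
    k_pd = unname(th["k_pd"]), mu = unname(th["mu"]), k_ve = unname(th["k_ve"]),
    K_ve = unname(th["k_ve"]) * p_hat$s3 / p_hat$s2,
    scenario = scenario,
    ssr = best$ssr,
    residuals = res_tbl,
    converged = best$fit$info %in% 1:4,
    n_starts = nrow(starts),
    best_start = best$start
  ), class = "caa_fit")
}

#' @export
print.caa_fit <- function(x, ...) {
  cat(sprintf("<caa_fit> scenario '%s'%s\n", x$scenario,
              if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  k_pd = %.4g, mu = %.4g, k_ve = %.4g h^-1\n",
              x$k_pd, x$mu, x$k_ve))
  cat(sprintf("  K_ve = %.4g h^-1 (protein-pool units), SSR = %.3e\n",
              x$K_ve, x$ssr))
  invisible(x)
}

#' Vacuolar export rate in protein-pool units
#'
#' Converts the fitted fractional export rate (per vacuolar pool) to units
#' of the protein-borne pool: `K_ve = k_ve * s3 / s2`.
#'
#' @param fit A `caa_fit` object.
#' @return `K_ve` in h^-1.
#' @export
export_rate_protein_units <- function(fit) {
  stopifnot(inherits(fit, "caa_fit"))
  if (!fit$converged) {
    abort("fit did not converge; K_ve not reported",
          class = "caaflux_fit_error")
  }
  if (fit$params$s2 <= 0) {
    abort("s2 = 0: conversion undefined", class = "caaflux_fit_error")
  }
  fit$k_ve * fit$params$s3 / fit$params$s2
}

#' Fit all three export scenarios on one dataset
#'
#' Runs the `no_export`, `conservative_cap` and `free` fits on the same
#' observations, chaining each restricted optimum in as an extra start of
#' the less restricted fit. Since the feasible sets are nested and each fit
#' starts (among others) from the previous optimum, the returned SSRs
#' satisfy `ssr(no_export) >= ssr(conservative_cap) >= ssr(free)`.
#'
#' @inheritParams fit_detailed_model
#' @param cap Conservative `k_ve` estimate used as the cap (if missing, the
#'   `conservative_cap` scenario is skipped).
#' @return Named list of `caa_fit` objects.
#' @export
fit_scenarios <- function(observed, weights, config = caa_config(),
                          cap = NULL, mu_fixed = NULL) {
  fits <- list()
  fits$no_export <- fit_detailed_model(observed, weights, config,
                                       scenario = "no_export",
                                       mu_fixed = mu_fixed)
  chain <- list(c(k_pd = fits$no_export$k_pd, mu = fits$no_export$mu,
                  k_ve = fits$no_export$k_ve))
  if (!is.null(cap)) {
    cap_eff <- max(cap, config$bounds_k_ve[1])
    fits$conservative_cap <- fit_detailed_model(
      observed, weights, config, scenario = "conservative_cap",
      cap = cap_eff, mu_fixed = mu_fixed, extra_starts = chain
    )
    chain <- c(chain, list(c(k_pd = fits$conservative_cap$k_pd,
                             mu = fits$conservative_cap$mu,
                             k_ve = fits$conservative_cap$k_ve)))
  }
  fits$free <- fit_detailed_model(observed, weights, config,
                                  scenario = "free", mu_fixed = mu_fixed,
                                  extra_starts = chain)
  fits
}

# -- internal -----------------------------------------------------------------

# Grid of starting values over the free axes of the box [lb, ub]:
# linear along k_pd and mu, log-spaced along k_ve (it spans decades).
multistart_grid_points <- function(lb, ub, free, n) {
  axes <- lapply(names(lb)[free], function(nm) {
    if (nm == "k_ve" && lb[nm] > 0) {
      exp(seq(log(lb[nm]), log(ub[nm]), length.out = n))
    } else {
      seq(lb[nm], ub[nm], length.out = n)
    }
  })
  g <- as.matrix(expand.grid(axes))
  colnames(g) <- names(lb)[free]
  g
}
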