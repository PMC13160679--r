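test_that("growth rate is the log-linear slope of OD600", {
  g <- tibble::tibble(sample_id = "c1", time_min = c(0, 120),
                      od600 = c(0.15, 0.15 * exp(0.8)))
  fit <- fit_growth_rate(g)
  expect_equal(fit$mu, 0.4, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  flat <- tibble::tibble(sample_id = "c1", time_min = c(0, 60, 120),
                         od600 = rep(0.2, 3))
  expect_equal(fit_growth_rate(flat)$mu, 0)

  expect_error(fit_growth_rate(g[1, ]), class = "caaflux_validation_error")
  g$od600[2] <- 0
  expect_error(fit_growth_rate(g), class = "caaflux_validation_error")
})

test_that("noisy synthetic growth curves recover mu within 3%", {
  truth <- synthetic_truth(
    genotypes = list(WT = model_params(0.03, 0.35, 2.0)),
    response_ratio = c(lysine = 1.25),
    noise_cv = 0, od_noise_cv = 0.01, seed = 21
  )
  sim <- simulate_experiment(truth)
  fits <- fit_growth_rates(sim$growth)
  # with 1% OD noise on 4 readings (including the time-0 reference) the
  # slope standard error is ~2%, so single replicates scatter accordingly;
  # the replicate mean is the calibrated quantity
  expect_lt(abs(mean(fits$mu) - 0.35) / 0.35, 0.03)
  expect_true(all(abs(fits$mu - 0.35) / 0.35 < 0.10))
  expect_true(all(fits$r_squared > 0.99))
})

test_that("fractional rates recover exact exponential decay to 1e-12", {
  t <- c(0, 1 / 3, 1, 2)
  expect_equal(fit_fractional_rate(t, exp(-0.6 * t))$rate, 0.6,
               tolerance = 1e-12)
  expect_equal(fit_fractional_rate(t, rep(1, 4))$rate, 0)
  # pure growth dilution: renewal at exactly mu, so conservative export is 0
  k <- fit_fractional_rate(t, exp(-0.4 * t))$rate
  expect_equal(k, 0.4, tolerance = 1e-12)
  expect_equal(max(k - 0.4, 0), 0)

  expect_error(fit_fractional_rate(1, 0.5), class = "caaflux_validation_error")
  expect_warning(fit_fractional_rate(t, c(1, 0.5, 0.1, 0)), "floored")
})

test_that("pool weights invert the mixture identity and sum to one", {
  ren <- tibble::tibble(
    genotype = "WT", replicate = 1L, analyte = "lysine",
    fraction = rep(c("total", "soluble", "protein"), each = 1),
    time_h = 1, f = c(0.7, 0.4, 0.9)
  )
  w <- pool_weights(ren)
  expect_equal(w$s_prot, 0.6)
  expect_equal(w$s_vac, 0.4)
  expect_equal(w$ratio_vac_prot, 2 / 3)

  # all protein-borne: f_tot = f_prot
  ren$f <- c(0.9, 0.4, 0.9)
  w <- pool_weights(ren)
  expect_equal(w$s_prot, 1)
  expect_equal(w$s_vac, 0)

  # algebraic identity over random valid triplets
  set.seed(13)
  for (i in 1:30) {
    fs <- sort(runif(3))           # f_sol < f_tot < f_prot
    ren$f <- c(fs[2], fs[1], fs[3])
    w <- pool_weights(ren)
    expect_equal(w$by_time$s_prot + w$by_time$s_vac, 1, tolerance = 1e-15)
  }
})

test_that("degenerate and inconsistent pool-weight points are handled", {
  ren <- tibble::tibble(
    genotype = "WT", replicate = 1L, analyte = "lysine",
    fraction = rep(c("total", "soluble", "protein"), times = 2),
    time_h = rep(c(1, 2), each = 3),
    f = c(0.7, 0.4, 0.9, 0.5, 0.45, 0.45)
  )
  # second point has f_prot = f_sol -> skipped, first still usable
  expect_warning(w <- pool_weights(ren), "skipped")
  expect_equal(w$s_prot, 0.6)

  # a wildly inconsistent point (s outside [-0.05, 1.05]) is rejected
  ren$f <- c(0.7, 0.4, 0.9, 0.9, 0.4, 0.45)
  expect_warning(w <- pool_weights(ren), "rejected")
  expect_equal(w$s_prot, 0.6)

  # nothing usable -> error
  ren2 <- ren[4:6, ]
  expect_warning(expect_error(pool_weights(ren2),
                              class = "caaflux_validation_error"))
})

test_that("time zero never enters the pool-weight consensus", {
  ren <- tibble::tibble(
    genotype = "WT", replicate = 1L, analyte = "lysine",
    fraction = rep(c("total", "soluble", "protein"), times = 2),
    time_h = rep(c(0, 1), each = 3),
    f = c(1, 1, 1, 0.7, 0.4, 0.9)
  )
  w <- pool_weights(ren)
  expect_equal(nrow(w$by_time), 1L)
  expect_equal(w$s_prot, 0.6)
})

test_that("conservative rates implement k_ve = k - mu with unit conversions", {
  w <- list(s_prot = 0.6, s_vac = 0.4)
  r <- conservative_rates(k = 0.6, mu = 0.4, k_tot = 0.3, weights = w)
  expect_equal(r$k_ve, 0.2)
  expect_false(r$k_ve_clipped)
  expect_equal(r$k_vi, 0.4)
  expect_equal(r$K_ve, 0.2 * 0.4 / 0.6)     # 0.1333...
  expect_equal(r$K_vi, 0.4 * 0.4 / 0.6)     # 0.2666...
  expect_equal(r$K_tot, 0.3 / 0.6)          # quotient conversion

  # boundary: no export
  expect_equal(conservative_rates(0.4, 0.4, 0.3, w)$k_ve, 0)
  # noise below the floor clips with a flag
  r2 <- conservative_rates(0.35, 0.4, 0.3, w)
  expect_equal(r2$k_ve, 0)
  expect_true(r2$k_ve_clipped)

  # literal-product alternative stays available
  cfg <- caa_config(ktot_conversion = "literal_product")
  expect_equal(conservative_rates(0.6, 0.4, 0.3, w, cfg)$K_tot, 0.3 * 0.6)

  expect_error(conservative_rates(0.6, 0.4, 0.3, list(s_prot = 0, s_vac = 1)),
               class = "caaflux_validation_error")
})

test_that("batch conservative estimation reproduces the per-culture pieces", {
  sim <- simulate_experiment(wt_truth(noise_cv = 0, seed = 17))
  rf <- calibrate_response_factors(sim$standards)
  ren <- compute_renewal(sim$intensities, rf)
  mu_tbl <- tibble::tibble(genotype = "WT", replicate = 1:3, mu = 0.4)
  rates <- estimate_conservative_rates(ren, mu_tbl)
  expect_equal(nrow(rates), 3L)
  # replicates of a noise-free simulation are identical
  expect_equal(rates$k_ve, rep(rates$k_ve[1], 3))
  # conservative estimate bounded by the truth (true k_ve = 2)
  expect_true(all(rates$k_ve <= 2 + 1e-9))
  expect_true(all(rates$k_ve >= 0))
  # growth dilution floor: k >= mu always (heavy influx at least at growth rate)
  expect_true(all(rates$k >= rates$mu - 1e-9))
})
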