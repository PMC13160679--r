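make_standards <- function(ratio, analyte = "lysine",
                           conc = c(0.0005, 0.002, 0.008, 0.03, 0.13, 0.5)) {
  base <- 1e6 * conc / max(conc)
  tibble::tibble(analyte = analyte, concentration_mM = conc,
                 intensity_light = ratio * base, intensity_heavy = base)
}

test_that("symmetric response gives equal weights under both conventions", {
  std <- make_standards(ratio = 1)
  for (conv in c("inverse_response", "as_printed")) {
    rf <- calibrate_response_factors(std, convention = conv)
    expect_equal(rf$w_light, 0.5)
    expect_equal(rf$w_heavy, 0.5)
  }
})

test_that("2:1 response calibrates to w_light = 1/3 and recovers f = 0.5", {
  rf <- calibrate_response_factors(make_standards(ratio = 2),
                                   convention = "inverse_response")
  expect_equal(rf$w_light, 1 / 3)
  expect_equal(rf$w_heavy, 2 / 3)
  expect_equal(rf$mean_standard_ratio, 2)
  # applying the factors back to the equimolar standard yields 0.5
  expect_equal(light_fraction(2, 1, rf$w_light, rf$w_heavy), 0.5)

  # the printed (as_printed) form runs the correction backwards
  rf2 <- calibrate_response_factors(make_standards(ratio = 2),
                                    convention = "as_printed")
  expect_equal(rf2$w_light, 2 / 3)
  expect_equal(light_fraction(2, 1, rf2$w_light, rf2$w_heavy), 4 / 5)
})

test_that("calibration is self-consistent across random response ratios", {
  set.seed(7)
  for (i in 1:25) {
    ratio <- exp(runif(1, log(0.2), log(5)))
    rf <- calibrate_response_factors(make_standards(ratio))
    expect_equal(rf$w_light + rf$w_heavy, 1, tolerance = 0)
    f_std <- light_fraction(ratio, 1, rf$w_light, rf$w_heavy)
    expect_equal(f_std, 0.5, tolerance = 1e-12)
  }
})

test_that("the canonical six-point dilution series is accepted", {
  std <- make_standards(ratio = 1.25)
  rf <- calibrate_response_factors(std)
  expect_equal(rf$n_levels, 6L)
  expect_lt(rf$ratio_cv, 1e-12)  # exact ratios -> no level-to-level spread
})

test_that("degenerate standards are rejected", {
  std <- make_standards(ratio = 2)
  std$intensity_heavy[2] <- 0
  expect_error(calibrate_response_factors(std),
               class = "caaflux_calibration_error")
  one <- make_standards(ratio = 2)[1, ]
  expect_error(calibrate_response_factors(one),
               class = "caaflux_calibration_error")
  expect_equal(
    calibrate_response_factors(one, allow_single = TRUE)$mean_standard_ratio, 2
  )
})

test_that("light_fraction handles boundary signals and stays in [0, 1]", {
  expect_equal(light_fraction(0, 100, 0.5, 0.5), 0)
  expect_equal(light_fraction(100, 0, 0.5, 0.5), 1)
  expect_equal(light_fraction(300, 150, 1 / 3, 2 / 3), 0.5)
  expect_error(light_fraction(0, 0, 0.5, 0.5),
               class = "caaflux_validation_error")
})

test_that("light_fraction is scale-invariant and monotone", {
  set.seed(11)
  for (i in 1:20) {
    il <- runif(1, 1, 1e6); ih <- runif(1, 1, 1e6)
    wl <- runif(1, 0.1, 0.9); wh <- 1 - wl
    f <- light_fraction(il, ih, wl, wh)
    for (c in c(1e-3, 7, 1e4)) {
      expect_equal(light_fraction(c * il, c * ih, wl, wh), f)
    }
    expect_gt(light_fraction(il * 1.1, ih, wl, wh), f)
    expect_lt(light_fraction(il, ih * 1.1, wl, wh), f)
  }
})

test_that("renewal computation converts minutes to hours and flags low f(0)", {
  sim <- simulate_experiment(wt_truth(noise_cv = 0, seed = 3))
  rf <- calibrate_response_factors(sim$standards)
  ren <- compute_renewal(sim$intensities, rf)
  expect_setequal(unique(ren$time_h), c(0, 20, 60, 120) / 60)
  expect_true(all(ren$f >= 0 & ren$f <= 1))
  expect_true(all(ren$f[ren$time_h == 0] == 1))

  # an uncalibrated analyte is an error
  bad <- dplyr::mutate(sim$intensities, analyte = "ornithine")
  expect_error(compute_renewal(bad, rf), "ornithine",
               class = "caaflux_calibration_error")

  # heavy carryover at time zero warns
  odd <- sim$intensities
  odd$intensity_heavy[odd$time_min == 0] <-
    odd$intensity_light[odd$time_min == 0]
  expect_warning(compute_renewal(odd, rf), "time 0")
})

test_that("CuCl2 vacuolar fractions follow 1 - Rb/Rc with conservative clipping", {
  tbl <- function(ib, ic, mb = 100, mc = 100) {
    tibble::tibble(
      sample_id = "s1", genotype = "WT", analyte = "lysine",
      fraction = c("cytosol_B", "vacuole_C"),
      intensity_analyte = c(ib, ic), intensity_marker = c(mb, mc)
    )
  }
  expect_equal(cucl2_vacuolar_fraction(tbl(0, 400))$f_vac, 1)
  expect_equal(cucl2_vacuolar_fraction(tbl(400, 400))$f_vac, 0)
  expect_equal(cucl2_vacuolar_fraction(tbl(20, 400))$f_vac, 0.95)

  expect_error(cucl2_vacuolar_fraction(tbl(20, 0)),
               class = "caaflux_validation_error")

  # noise can push Rb above Rc; the raw value is kept, the report clipped
  expect_warning(res <- cucl2_vacuolar_fraction(tbl(450, 400)), "clipped")
  expect_equal(res$f_vac, 0)
  expect_lt(res$f_vac_raw, 0)
})

test_that("simulated CuCl2 tables recover the true vacuolar share", {
  truth <- wt_truth(noise_cv = 0, seed = 9)
  cu <- simulate_cucl2(truth, f_vac = 0.9)
  res <- cucl2_vacuolar_fraction(cu)
  expect_equal(res$f_vac, rep(0.9, nrow(res)), tolerance = 1e-12)
})
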