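# Shared fixture builders. Everything is generated in code; nothing is read
# from disk except files the tests themselves write to tempdir().

# Single-genotype, single-analyte truth: the cheapest complete experiment.
wt_truth <- function(k_ve = 2.0, noise_cv = 0, seed = 1L, ...) {
  synthetic_truth(
    genotypes = list(WT = model_params(k_pd = 0.03, mu = 0.4, k_ve = k_ve)),
    response_ratio = c(lysine = 1.25),
    noise_cv = noise_cv,
    od_noise_cv = noise_cv,
    seed = seed,
    ...
  )
}

# Renewal observations (soluble + protein) straight from the model, plus the
# exact pool weights used to generate them -- the noise-free fit fixture.
model_observations <- function(params, times_h = c(0, 20, 60, 120) / 60) {
  obs <- model_renewal_observables(params, times_h)
  list(
    observed = dplyr::bind_rows(
      tibble::tibble(fraction = "soluble", time_h = obs$time_h, f = obs$f_sol),
      tibble::tibble(fraction = "protein", time_h = obs$time_h, f = obs$f_prot)
    ),
    weights = list(s_prot = params$s2 / (params$s2 + params$s3),
                   s_vac = params$s3 / (params$s2 + params$s3))
  )
}

# Random model parameters inside the standard fitting box.
draw_params <- function() {
  model_params(
    k_pd = runif(1, 0.01, 0.05),
    mu = runif(1, 0.3, 0.45),
    k_ve = exp(runif(1, log(0.01), log(10)))
  )
}

# A fast config for fit-heavy tests: coarser start grid, but every start
# polished (screening alone is unreliable on a 3^3 grid).
fast_config <- function(...) {
  caa_config(multistart_grid = 3L, n_polish = 27L, ...)
}
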