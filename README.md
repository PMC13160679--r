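# caaflux

Estimation of vacuolar cationic amino acid (CAA: lysine, arginine)
transport rates in budding yeast from dynamic stable-isotope labeling
experiments.

When an exponentially growing culture is switched from light to heavy
isotopologues of lysine and arginine, the pre-switch ("light") fraction
*f* of each cellular CAA pool decays at a rate set by that pool's renewal.
`caaflux` takes the integrated light/heavy MS peak intensities measured in
three subcellular fractions (soluble ≈ vacuolar, protein-incorporated, and
total) at 0/20/60/120 min after the switch, together with equimolar
calibration standards and OD600 growth curves, and computes:

- **calibrated renewal fractions** `f = wL·IL / (wL·IL + wH·IH)`, with
  response factors `wL`, `wH` calibrated so the equimolar standard maps to
  exactly 0.5;
- **growth rates** from `ln OD(t)/OD(0) = μt`;
- **pool weights** `S_prot(t) = (f_tot − f_sol)/(f_prot − f_sol)`,
  `S_vac = 1 − S_prot` — the vacuole-to-protein CAA pool ratio;
- **conservative (lower-bound) export rates** from the single-exponential
  renewal model `−ln f_sol(t) = k·t` and the steady-state balance
  `k_ve = k − μ`, with net import `k_vi = μ` and conversions
  `K_ve = k_ve·S_vac/S_prot`, `K_tot = k_tot/S_prot`;
- **detailed export rates** by fitting a three-pool compartmental model
  (cytosol, protein, vacuole; `f(t) = e^{Mt}·1` with mass-balance-derived
  transition matrix `M`) to the protein and soluble renewal curves by
  bounded multistart least squares over `(k_pd, μ, k_ve)`, under three
  nested scenarios (no export / conservatively capped export / free);
- **vacuolar fractions** from CuCl₂ permeabilization assays,
  `f_vac = 1 − R_b/R_c`;
- **complete synthetic experiments** from known ground truth
  (`simulate_experiment()`), and simulate-then-fit **recovery studies**
  (`recovery_experiment()`), so every stage is testable without any
  external download.

All estimates are per biological replicate; outputs are tidy tables ready
for downstream statistics.

## A worked example

```r
library(caaflux)

# a complete in-silico study: WT (k_ve = 2 h^-1) vs a transporter-deletion
# strain (k_ve = 0.4 h^-1), 3 replicates, 5% intensity noise
sim <- simulate_experiment(synthetic_truth(noise_cv = 0.05, seed = 42))
res <- analyze_experiment(sim$intensities, sim$standards, sim$growth)
res$detailed
#> # A tibble: 12 × 10
#>   genotype replicate analyte scenario   k_pd    mu  k_ve  K_ve     ssr converged
#>   <chr>        <int> <chr>   <chr>     <dbl> <dbl> <dbl> <dbl>   <dbl> <lgl>
#> 1 WT               1 argini… free     0.0243 0.422  2.36  1.68 8.29e-4 TRUE
#> 2 WT               1 lysine  free     0.0373 0.412  3.14  2.54 3.20e-4 TRUE
#> 3 WT               2 argini… free     0.01   0.409  1.82  1.18 1.92e-4 TRUE
#> 4 WT               2 lysine  free     0.01   0.399  1.58  1.15 6.26e-4 TRUE
#> # … 8 more rows
```

Each row is one culture and analyte: the fitted protein-degradation rate
`k_pd`, growth rate `mu` and fractional vacuolar export rate `k_ve`
(h⁻¹, per vacuolar pool), the export rate `K_ve` re-expressed per
protein-borne pool, and the fit's sum of squared residuals. The WT rows
recover export near the true 2 h⁻¹; the deletion rows sit five-fold lower.
The companion `res$conservative` table holds the guaranteed lower bounds
(`k_ve = k − μ`; e.g. WT replicate 1 arginine: `k = 0.807`, `μ = 0.401`,
so `k_ve = 0.406` and `K_ve = 0.289`), which the detailed estimates always
exceed — on this dataset the WT mean detailed `K_ve` is 5.9-fold above the
conservative mean.

A command-line wrapper over the same functions is installed with the
package:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts", "caaflux.R", package = "caaflux"))')" \
  analyze --intensities intensities.csv --standards standards.csv \
  --growth growth.csv --out-dir results/
```

Subcommands: `calibrate`, `renewal`, `analyze`, `fit-detailed`,
`simulate`, `recover`.

## Package layout

- `R/tables_io.R` — CSV/JSON schemas, validation, results serialization
- `R/labeling.R` — response-factor calibration, renewal fractions, CuCl₂
- `R/rates.R` — growth rates, log-linear renewal rates, pool weights,
  conservative transport rates
- `R/compartmental.R` — three-pool model, matrix-exponential propagation,
  bounded multistart fitting, scenarios
- `R/synthetic.R` — ground-truth experiment generator, recovery harness
- `R/pipeline.R`, `R/cli.R` — end-to-end orchestration and the CLI
- `vignettes/caa-transport-modeling.Rmd` — the model, its assumptions,
  numerical choices and known identifiability limits
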