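# frickesim

Stochastic track-chemistry simulation of the Fricke (ferrous sulfate)
dosimeter, from the 1-ps radiolytic species distribution of a proton track
to the asymptotic ferric yield at ~100 s, including the viscosity
(gel-matrix) dependence of the yield.

The pipeline has four stages:

1. **Chemistry** (`build_fricke_system`): species registry and reaction
   network of acidic aerated water with Fe²⁺, with sulfuric acid speciation,
   ionic-strength (Debye–Brønsted) corrections at 0.4 M acid, and a
   Noyes partition of every rate constant into diffusion-limited and
   activation-limited parts. `apply_viscosity(system, f)` divides every
   diffusion coefficient by `f` and repartitions the rate constants with
   fixed reaction radii.
2. **Track generation** (`sample_spur_ensemble`,
   `sample_cylindrical_track`): synthetic 1-ps distributions — Gaussian
   spurs on a line for low LET, a Gaussian-radial cylinder for high LET —
   with per-species yields and widths calibrated against the accepted
   escape yields of 0.4 M acidic water
   (`calibrate_spur_parameters`).
3. **Stochastic stage** (`run_irt`): independent-reaction-times (IRT)
   simulation of the intra-track chemistry from 1 ps to the hand-off time
   (1 µs at unit viscosity, scaled with `f`), with analytic first-passage
   kernels for fully and partially diffusion-controlled pairs and
   exponential scavenging by the background solutes (acid, Fe²⁺, O₂).
   The inner loop is compiled (Rcpp).
4. **Homogeneous stage** (`evolve_bulk`): pseudo-first-order kinetics of
   the escaped radicals in the bulk solution to 200 s, with a closed-form
   asymptote (`bulk_asymptote`) used as an internal oracle, and a
   decomposition of the ferric yield into its OH, HO₂ and H₂O₂ channels.

`run_scenario` / `scenario_config` tie the stages together per Monte Carlo
history; `reproduce_figure` bundles the headline condition grids
(LET dependence, viscosity profiles and sweep, acid comparison);
`summarize_scenarios` compares computed 100-s yields against the tabulated
reference values.

## Quick start

```r
library(frickesim)

## analytic stoichiometric yield from the accepted escape yields
stoichiometric_yield(reference_escape_yields())   # 15.66 molecules/100 eV

## calibrate the 1-ps generator (about 5 minutes on one core)
set.seed(1)
fit <- calibrate_spur_parameters()

## standard aerated dosimeter at low LET
cfg <- scenario_config(LET = 0.3, n_histories = 50, seed = 2, params = fit)
res <- run_scenario(cfg)
res$summary$G_Fe3     # ferric yield at 100 s, molecules/100 eV
summarize_scenarios(res)
```

## Command line

A thin CLI ships in `inst/cli`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "frickesim", package = "frickesim"))')
Rscript "$CLI" calibrate --seed 1 --out spur_params.yaml
Rscript "$CLI" run --config scenario.yaml --params spur_params.yaml --out results/
Rscript "$CLI" reproduce viscosity_sweep --params spur_params.yaml --out results/
Rscript "$CLI" summarize --tol 0.2 results/*_summary.csv
```

Exit codes: 0 success, 2 validation/usage error, 3 tolerance failure.

`scripts/acceptance.R` recomputes the headline yield targets from scratch
(calibration plus seven production scenarios) and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

## Units and conventions

- Yields are G-values in molecules/100 eV throughout.
- Concentrations in mol/L, rate constants in 1/(M·s), diffusion
  coefficients in m²/s, distances in the track generator in nm.
- For identical reactants the tabulated rate constant `k` follows the
  convention −d[A]/dt = 2k[A]²; the pairwise IRT kernel uses the matching
  2k partition (see the methods vignette).

## Tests

The test suite (testthat, edition 3) contains fast unit/property tests and
a long-running acceptance suite (`test-acceptance.R`) that recalibrates and
reruns the production scenarios; some acceptance assertions encode known
model-fidelity limits of the simple two-width spur model and fail honestly
(documented in the methods vignette, "Known limitations").

```r
testthat::test_dir("tests/testthat", package = "frickesim",
                   load_package = "installed")
```
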