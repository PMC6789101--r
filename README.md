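# ecoeff

Carbon- and water-use efficiency analysis for factorial ecosystem model
ensembles.

Terrestrial ecosystem models couple the carbon and water cycles through
photosynthesis and evapotranspiration. Two ratios summarize that coupling:

- **WUE** (water-use efficiency) = GPP / ET, in gC/kgH₂O — carbon gained per
  unit water lost;
- **CUE** (carbon-use efficiency) = NPP / GPP, dimensionless — the fraction
  of assimilated carbon retained as net production (1 − Ra/GPP).

Model intercomparison archives run each model under a nested factorial
design: RG1 (all forcings held at reference), SG1 (+ time-varying climate),
SG2 (+ land use), SG3 (+ atmospheric CO₂), BG1 (+ nitrogen deposition;
carbon–nitrogen models only). Differencing adjacent scenarios isolates one
driver at a time:

    climate effect = SG1 − RG1
    CO₂ effect     = SG3 − SG2
    N-dep effect   = BG1 − SG3
    combined       = BG1 (or SG3 for C-only models), net of the first year

`ecoeff` provides the full pipeline for this analysis: CF-style NetCDF I/O
with unit normalization, cosine-latitude area-weighted aggregation, trend
detection with the trend-free pre-whitened Mann–Kendall test and Sen's
slope, the percentage-change metric `100 · slope · n / mean`, per-driver
percent contributions, per-cell dominant-driver maps, comparison against a
reference WUE product, and a growing-season LAI diagnostic of the
nitrogen-deposition response. Because the real model archives are far too
large for a test suite, the package ships a synthetic ensemble generator
that fabricates multi-model factorial archives with *known, injected* driver
effects and AR(1) interannual noise, so every stage can be verified against
ground truth.

For whom: anyone analyzing factorial ensemble output (model intercomparison
archives, perturbed-physics ensembles) who needs driver attribution with
honest trend inference on serially correlated annual series.

## Worked example

Generate a three-model synthetic study ensemble (two carbon–nitrogen
models, one carbon-only; 110 years on a 10×20 grid; AR(1) noise shared
across scenarios) and analyze it:

```r
library(ecoeff)

grid      <- make_grid(nlat = 10, nlon = 20, land_fraction = 0.3, seed = 1)
specs     <- default_specs(seed = 1, noise_sd = 0.03)
ensembles <- lapply(specs, generate_ensemble, grid = grid)

# global annual WUE of the all-drivers scenario, and its trend
wue <- efficiency_series(ensembles[[1]], "BG1", "wue")
trend_test(wue, method = "tfpw-mk")
#> <trend_result> tfpw-mk
#>   n = 109, S = 5164, varS = 145842.000, Z = 13.5195, p = 1.2e-41
#>   tau = 0.8773, Sen's slope = 0.00268504 / yr, significant at 0.05: yes
```

The slope says global WUE rises by ≈0.0027 gC/kgH₂O per year; over the 110
simulated years that is a ≈13.7% increase relative to the mean — dominated,
for this model, by the injected CO₂ fertilization effect. The per-model,
per-driver summary makes that explicit:

```r
ensemble_summary(ensembles, "wue")
#>         model      driver sen_slope  p.value significant pct_change pct_contribution
#>     cnmod-co2     climate -0.001070 8.96e-53        TRUE      -5.48            -2.74
#>     cnmod-co2         co2  0.003170 3.23e-52        TRUE      16.20             8.14
#>     cnmod-co2        ndep  0.000600 9.08e-51        TRUE       3.07             1.55
#>     cnmod-co2    combined  0.002690 1.20e-41        TRUE      13.70               NA
#>     ...
#>     cmod-clim     climate -0.003420 6.46e-50        TRUE     -20.30           -10.20
```

Each row is the trend of one driver's effect series (scenario difference):
`pct_change` is the Sen's slope times the period length relative to the
all-drivers mean, and `pct_contribution` is the mean effect as a percentage
of the all-drivers scenario mean. The carbon-only model (`cmod-clim`) has no
nitrogen row, and a model lacking ET would simply have no WUE rows at all.

Per-cell dominant drivers:

```r
dominant_driver_map(ensembles[[1]], "wue")
#> <dominant_driver_map> wue, cnmod-co2, 1982-2008
#> co2
#>  60
```

All 60 land cells of this model are CO₂-dominated, matching what was
injected. `autoplot()` renders the map; `write_dominant_map()` writes it as
a categorical NetCDF grid.

## Command line

A thin dispatcher over the same functions lives at `inst/cli/ecoeff.R`:

```sh
Rscript inst/cli/ecoeff.R generate     --config cfg.yml --out archive/
Rscript inst/cli/ecoeff.R efficiency   --in archive/ --out eff/
Rscript inst/cli/ecoeff.R attribute    --in archive/ --driver co2 --out att/
Rscript inst/cli/ecoeff.R trend        --series eff/cnmod-co2_wue.csv --method tfpw-mk
Rscript inst/cli/ecoeff.R dominant-map --in archive/ --var wue --out dom.nc
Rscript inst/cli/ecoeff.R compare      --model archive/ --reference archive/reference_wue.nc
Rscript inst/cli/ecoeff.R lai-ndep     --in archive/ --out lai.csv
```

Archives are laid out as `<model>/<scenario>/<variable>.nc` with a
`ground_truth.json` ledger of the injected effects; reruns with the same
seed are bit-identical.

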