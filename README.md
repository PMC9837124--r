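# peatfire

Hydrology-informed fire forecasting for tropical peatlands, as a tested,
reusable R pipeline.

Fires in Indonesian peatlands are controlled less by same-week weather than by
the state of the peat itself: the water table depth (WTD) and near-surface
moisture that integrate months of rainfall, evapotranspiration and artificial
drainage. Fire-danger indices built from weather alone miss that subsurface
memory. `peatfire` implements the full chain needed to study — and test — the
claim that simulated hydrology improves fire-count forecasts:

1. **Column hydrology** — a daily water balance for stand-alone layered peat
   and mineral soil columns: van Genuchten retention θ(ψ) = θ_r +
   (θ_s−θ_r)[1+(αψ)^n]^(−1+1/n) with Mualem conductivity, a tipping-bucket
   vertical cascade, FAO-56-style reference evapotranspiration with a
   root-zone stress ramp, and lateral Darcy exchange
   q = K̄ (WTDx − WTD)/L · b/D with a boundary water table WTDx representing
   the adjacent watershed or drainage canal. Outputs: daily WTD and
   near-surface (litter + top 0.05 m) soil moisture, with a flux ledger that
   closes to machine precision.
2. **Fortnight features** — 14-day aggregates (5 weather means/sums + 28-day
   antecedent precipitation; plus mean WTD and near-surface moisture for the
   hydrology variant).
3. **Fire models** — two parallel neural-network regressors for fortnightly
   fire counts, ANN(WTHR) with 6 inputs and ANN(WTHR+HYDROL) with 8, both
   6/8–32–16–1 relu networks trained with Adam (lr 0.001, MSE loss, early
   stopping) under leave-one-year-out cross-validation.
4. **Evaluation** — pooled fortnightly R²/MAE, time-differenced skill, and a
   Youden-J estimator of the WTD threshold separating fire from no-fire
   fortnights.
5. **Synthetic data** — a seeded generator (bimodal dry seasons, drought
   years, peat/mineral columns, land-use-dependent drainage, Poisson fire
   counts with a known 0.4 m WTD threshold) so the whole pipeline runs and is
   validated offline.

See `vignettes/peatfire-methods.Rmd` for the model equations, parameter
defaults, and design rationale.

## Worked example

Simulate one pristine-forest peat column for the 2008–2015 production years
(spin-up to equilibrium first):

```r
library(peatfire)
tr   <- synthetic_truth(seed = 1)            # generator = study conditions
cell <- gen_grid(tr, 50)[[1]]                # a pristine-forest peat cell
col  <- cell$column
col$wtdx <- assign_boundary_wtdx(cell$landuse, cell$classification, run_config())
st   <- spin_up(col, gen_weather(tr, 1)[1:366, ], run_config())
simulate_column(col, st, gen_weather(tr, 1))
#> <column_run> 2922 days; pristine_forest (wtdx 0.25 m)
#>   WTD  mean 0.174 m, range [0.000, 0.296] m below surface
#>   theta_ns mean 0.555 m3/m3; ET 9474 mm; lateral +8507 mm; runoff 344 mm
```

The water table of the undrained forest column stays within ~0.3 m of the
surface, precipitation exceeds evapotranspiration (9.5 m over 8 years) and
the surplus leaves as lateral discharge — the rain-fed peat dome regime.

Run the full 50-cell benchmark and compare the two fire models:

```r
pipe <- peatfire_pipeline(synthetic_truth(seed = 1), n_cells = 50, train = TRUE)
pipe$fit_hydrol
#> <fire_loocv> 8 leave-one-year-out folds, 8 features, 10300 records
#>   out-of-sample R2 (record level): 0.398, MAE: 0.661
pipe$fit_wthr
#> <fire_loocv> 8 leave-one-year-out folds, 6 features, 10300 records
#>   out-of-sample R2 (record level): 0.011, MAE: 1.024
round(pooled_skill(pipe), 3)
#>    r2_wthr  r2_hydrol   mae_wthr mae_hydrol
#>      0.441      0.471      6.054      5.964
pipe$report
#> <evaluation_report>
#>   pooled fortnightly series (all cells):
#>     R2 0.471 | time-differenced R2 0.073 | MAE 5.96 counts/fortnight
#>   fire WTD threshold: 0.40 m (J = 0.71)
```

Per fortnight record the weather-only model has essentially no out-of-sample
skill (R² 0.01) while the hydrology-informed model explains most of the
explainable (Poisson-noisy) variance (R² 0.40); on fortnightly counts pooled
over all cells both track the shared seasonality but the hydrology variant
stays ahead. The Youden-J scan of fortnight-mean WTD against fire occurrence
recovers the generator's 0.4 m threshold.

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/peatfire.R pipeline --n-cells 50 --seed 1 --out-dir out/
Rscript inst/cli/peatfire.R synth    --n-cells 50 --seed 1 --out-dir out/
```

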