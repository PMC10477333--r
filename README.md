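# soccf — counterfactual attribution of cropland management effects on soil organic carbon

`soccf` quantifies how individual climate-smart cropland practices — winter
cover crops, conservation tillage, hay/pasture in rotation with annual crops,
manure amendments, and land set-aside — have changed national soil organic
carbon (SOC) stocks in the top 30 cm of mineral soils. It is built for
survey-based national assessments: per-location SOC trajectories are
simulated over a weighted area survey of cropland locations, one practice is
removed at a time, and the difference in annual stock changes is scaled to
national totals with design-based uncertainty.

The real inputs behind such assessments (national survey microdata,
field-level management surveys) are confidential, so the package ships a
first-class synthetic-data module that generates every input the pipeline
needs — survey frame with expansion and replicate weights, daily weather,
true management histories with configurable national adoption trends, donor
surveys, and calibration sites with known model bias — making the entire
analysis reproducible and testable end to end.

## The method

**Soil carbon model.** A surrogate multi-pool model in the classic
active/slow/passive tradition: each pool decays at rate
`k_i · m_T · m_W · m_till` (temperature modifier `m_T = Q10^((T−T_ref)/10)`
capped at 2, moisture modifier `m_W = w/(w + w_half)`, tillage multiplier on
the active and slow pools with FT ≥ RT ≥ NT), decayed carbon splits into
respiration and clay-dependent transfers, and crop-driven inputs enter the
active pool. Mass balance `Δtotal = inputs − respired` holds to machine
precision at every daily step. Runs initialise from the analytic steady state
under native vegetation (verified against 6000-year brute-force spin-ups),
pass through a staged base history (low-input agriculture, then a 1950–1978
productivity ramp), and report Dec-31 stocks and annual stock changes ΔSOC
for the survey era.

**Calibration.** Sobol total-order sensitivity screening (Saltelli sampling,
Jansen estimator; parameters with total index > 2.5% are selected) feeds a
sampling-importance-resampling (SIR) calibration whose maximum a posteriori
estimate parameterises the simulator. Structural model uncertainty is
captured empirically: a REML linear mixed-effect model maps simulated onto
"measured" SOC from calibration sites, with site and region random
intercepts.

**Management imputation.** Six imputation sets are built per assessment:
tillage is hot-decked for the 2001–2005 anchor block within
region × crop-group × texture strata, then propagated backward and forward
through 5-year blocks by an inhomogeneous Markov chain whose transition
matrices change tillage as little as possible — the diagonal of the coupling
carries `min(p_i, q_i)`, the LP optimum, with the residual mass placed by the
northwest-corner rule — so block marginals track harmonized trend series
while individual sequences rarely switch. Nitrogen inputs use predictive
mean matching (predict, then assign the observed value of the
nearest-prediction donor). Cover crops are hot-decked at the anchor and
ramped linearly back to exactly zero adoption in 1990.

**Counterfactuals and estimation.** Scenarios eliminate one practice at a
time across 1979–2015 (cover crops off; all NT/RT → FT; hay/pasture replaced
by the location's other annual crops; manure N moved to synthetic N with
total N conserved); set-aside is attributed directly from the baseline run.
Practice effects `ΔSOC_baseline − ΔSOC_counterfactual` are scaled to Mt C/yr
with survey weights. A 1000-iteration Monte Carlo propagates three
uncertainty sources — imputation choice, bias-model parameters plus a
prediction-error draw, and delete-a-group jackknife replicate weights — into
means, standard deviations, and percentile confidence intervals per scenario
and year. Mean 1995–2015 effects are interpolated onto a 5 km grid by
inverse distance weighting (20 km search radius, ≥ 5 supporting locations
per cell, else null).

## Worked example

```r
library(soccf)
cfg <- default_config(list(n_locations = 200,
                           imputation = list(M = 3),
                           monte_carlo = list(n_iter = 300)))
res <- run_pipeline(cfg)
res$summary
```

```
national_summary: 1995 - 2015
  total stock change: 16.9 Mt C/yr (1995) to 3.6 Mt C/yr (2015)
```

The synthetic world's croplands sequester carbon throughout the series, with
the sink shrinking over time as set-aside and hay/pasture areas decline. Per
practice, in 2015:

```r
subset(res$summary$national, year == 2015,
       c(scenario, total_mt_c, area_mha, rate_t_c_ha_yr, co2e_mt))
```

```
             scenario total_mt_c area_mha rate_t_c_ha_yr co2e_mt
 cover_crop_herbicide      0.388    1.886         0.2056   1.422
   cover_crop_tillage      0.385    1.886         0.2041   1.411
 conservation_tillage      2.158   29.705         0.0726   7.912
          hay_pasture     -0.182    0.903        -0.2011  -0.666
               manure      0.968    5.613         0.1725   3.550
            set_aside      0.807    6.150         0.1313   2.961
                total      3.568  125.400         0.0285  13.082
     other_management     -0.572       NA             NA  -2.097
```

Each row gives the practice's national effect (Mt C/yr, positive =
sequestration attributable to the practice), the area exposed to the
practice that year (Mha), the per-area rate (t C ha⁻¹ yr⁻¹ = effect/area),
and the CO₂-equivalent (× 44/12). Conservation tillage is the largest
contributor late in the series (adoption grew after 2000); cover crops sit
on a small area, with herbicide termination storing slightly more carbon
than tillage termination; `other_management` is the explicit residual
between the total and the attributed practices (practices interact, so
effects are not forced to add up).

Uncertainty comes from the Monte Carlo table — at a few hundred synthetic
locations the survey-scaling and model-error components are large, so
confidence intervals are wide:

```r
subset(res$summary$mc, year == 1996 & scenario == "total")
```

```
 scenario year mean sd ci_low ci_high n_iter
    total 1996 23.5 77   -128     172    300
```

Gridded 21-year mean effect maps are in `res$maps` and can be exported as
ESRI ASCII rasters with `write_effect_grid()`.

A thin command-line wrapper with subcommands
(`generate | calibrate | impute | simulate | counterfactual | estimate | map | all`)
is installed at `inst/cli/soccf.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "soccf.R", package = "soccf"))')" \
  all --seed 1 --out out/ --iterations 300
```

## Package layout

- `R/synthetic_survey.R` — survey frame, weather, truth histories, donors,
  calibration sites
- `R/soc_model.R`, `R/simulate.R`, `src/pools.cpp` — the surrogate pool
  model and per-location trajectory simulation
- `R/calibration.R` — Sobol screening, SIR, bias model
- `R/imputation.R` — tillage harmonization/Markov imputation, PMM nitrogen,
  cover-crop hot-deck
- `R/counterfactual.R` — scenario edits and effect attribution
- `R/estimation.R` — weighted totals, jackknife, Monte Carlo, national series
- `R/mapping.R` — IDW interpolation and raster export
- `R/pipeline.R` — configuration and end-to-end orchestration
- `vignettes/soc-counterfactuals.Rmd` — the methods vignette (model,
  assumptions, parameter choices, limitations)
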