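---
title: "Counterfactual attribution of cropland management effects on SOC: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual attribution of cropland management effects on SOC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soccf)
```

This vignette documents the science inside `soccf`: the models and
statistical procedures, the assumptions they rest on, the parameters a user
might want to change, and the limits of what the synthetic-world tests can
demonstrate about real data.

## The question the pipeline answers

National greenhouse-gas accounting wants to know not just how much soil
organic carbon (SOC) cropland soils gained in a given year, but how much of
that gain is attributable to specific "climate-smart" practices. The
attribution logic is counterfactual: simulate the historical management as
observed (the baseline), then re-simulate with one practice removed
everywhere, and call the difference in annual stock changes the practice's
effect. Because stock changes of practices interact (a cover-cropped,
no-till field is not the sum of its parts), the per-practice effects are not
forced to add to the total; the residual is reported explicitly as
`other_management`.

Effects are differences of *annual stock changes* (t C ha⁻¹ yr⁻¹), not of
stock levels. Stock-level differences accumulate over time and would conflate
this year's practice with decades of legacy; the flux framing matches how
annual national inventories are reported. Counterfactual edits are applied
from the first history year (1979) even though effects are only reported
from 1995, so that the assessment window carries no artificial transient
from an abrupt management switch.

Set-aside (land retired from production into grass cover) is the one
practice attributed without a counterfactual run: it is the only practice at
its location-years, so its effect is read directly from the baseline stock
change in enrolled years.

## The surrogate soil carbon model

The simulator is a three-pool (active/slow/passive) first-order
decomposition model in the classic tradition of multi-pool soil organic
matter models, run on a daily step to represent the 0–30 cm layer. It is an
explicitly documented surrogate: a transparent stand-in with the qualitative
behaviour the analysis needs (pool turnover separation, climate and tillage
sensitivity, exact mass balance), packaged behind a small interface
(`simulate_location()`, `solve_equilibrium()`, `step_pools()`) so that a
full process-model binding could replace it without touching the rest of the
pipeline.

Per day, pool $i$ decays by $C_i\,k_i\,m_T\,m_W\,m_{till}\,\Delta t$, with

* $m_T = Q_{10}^{(T - T_{ref})/10}$, capped at 2.0 (`q10 = 2`,
  `t_ref = 25` °C);
* $m_W = w/(w + w_{half})$ on a relative-water index $w \in [0,1]$
  (`w_half = 0.3`); $w$ is an exponentially smoothed precipitation index,
  $w = s/(s + \bar p)$ with a ~10-day memory — a deliberate scalar proxy, not
  a water-balance model;
* $m_{till}$ applies to the active and slow pools only:
  NT = 1.00, RT = 1.15, FT = 1.30.

Decayed carbon splits into respiration (55% for every pool) and transfers:
active→passive $0.004 + 0.03\,\mathrm{clay}$, slow→passive
$0.003 + 0.009\,\mathrm{clay}$, remainder to the adjacent pool. Inputs enter
the active pool. The update is constructed so that
$\Delta \text{total} = \text{inputs} - \text{respired}$ holds exactly; the
test suite verifies this to $10^{-9}$ relative over random steps and an
isolated pool against the closed form $C_0 e^{-kt}$.

Base decay rates are `k_active = 7.3`, `k_slow = 0.2`,
`k_passive = 0.0045` yr⁻¹. With the default climate this yields equilibrium
stocks of roughly 60–110 t C ha⁻¹ in 0–30 cm and practice-contrast rates of
0–1 t C ha⁻¹ yr⁻¹, the plausible range for temperate cropland.

**Initialisation.** Production runs initialise from the *analytic* steady
state of the linear pool system under mean forcing and native-vegetation
input (3 t C ha⁻¹ yr⁻¹), rather than an explicit multi-millennial spin-up;
the equivalence is a tested invariant (analytic vs 6000-year brute-force
spin-up, < 0.5% relative over 100 random parameter draws). One numerical
caveat: with a fixed spin-up horizon, agreement can only be expected where
the passive pool's *effective* turnover (base rate × modifiers) is well
inside the horizon; the test draws mean modifiers in that physically typical
regime. The base history then runs low-input agriculture
(`low_input_scale = 0.5` of a 2.2 t C ha⁻¹ yr⁻¹ reference input, full
tillage) from `base_start = 1910` to 1949, a linear productivity ramp to
modern inputs over 1950–1978, and the survey era 1979–2015 under daily
weather with management-driven inputs. Pre-1979 phases use the location's
mean modifiers; this is an initialisation device, and the reported years are
simulated with full daily forcing.

**Management couplings.** Crop carbon inputs (t C ha⁻¹ yr⁻¹: corn 2.8,
soybean 2.0, wheat 2.2, hay 3.0, pasture 3.2, grass 3.0, …) are spread over
the growing season (annual crops days 121–273; perennials 91–304). Cover
crops add `cover_crop_c = 0.8` t C ha⁻¹ each winter (days 60–89).
Terminating a cover crop with tillage applies one extra 30-day full-till
decomposition window in the termination year; herbicide termination does
not — hence tillage-terminated cover crops always sequester less, the sign
ordering the acceptance suite checks. Manure adds carbon as
`manure_n × C:N / 1000` with `manure_cn = 15`. Set-aside years are simulated
as continuous grass cover under no-till regardless of the recorded fields.
When a daily vegetation-index series is supplied, annual-crop inputs from
2000 on are scaled by the growing-season mean of the gap-filled index
relative to `evi_ref = 0.5`; `sg_gapfill()` fills the ~8-day observation
gaps by Savitzky–Golay-style local polynomial least squares on the nearest
observed samples (exact on polynomials up to the fit order, including at
gaps and edges — the reason it fits observed samples directly rather than
filtering a pre-interpolated series).

## Calibration and structural uncertainty

The calibration chain is screening → SIR → MAP. `sobol_total_indices()`
implements Saltelli-sampled total-order indices with the Jansen estimator;
parameters with total index above 2.5% (configurable) are selected.
`sir_calibrate()` draws prior particles, weights them by a Gaussian
likelihood around the calibration measurements (the likelihood form is a
package choice; log-sum-exp normalisation guards against underflow), and
resamples; the MAP is operationalised as the highest-weight particle among
those resampled. The optional pipeline stage (`calibration$run_screening`)
runs this chain against the equilibrium response and adopts the MAP.

Structural model uncertainty uses the empirical route: `fit_bias_model()`
fits, by REML, `measured ~ simulated` with site and region random intercepts
on calibration-site data. If the region component is not identifiable the
fit falls back to a site-only random effect with a warning; noise-free data
fall back to an exact fixed-effects fit. The prediction standard deviation
is $\sqrt{\sigma^2_{site} + \sigma^2_{region} + \sigma^2_{resid}}$.

## Monte Carlo uncertainty propagation

Three sources are propagated with 1000 iterations by default; simulations
are run once per imputation set and cached — iterations resample cached
stocks, never re-run the simulator. Per iteration:

1. one of the M = 6 imputation sets, uniformly;
2. a bias-model fixed-effect vector from $N(\beta, \mathrm{Cov}(\beta))$,
   applied to annual stocks *before* differencing into stock changes (the
   order is a documented, switchable choice — the intercept cancels in
   differencing, the slope scales stock changes), plus a residual
   prediction-error draw;
3. one delete-a-group jackknife replicate-weight vector, uniformly.

The prediction-error structure deserves its own paragraph, because the
choice is genuinely open. The bias model's site-level component represents a
persistent site offset: it cancels exactly when stocks are differenced into
stock changes, so it contributes nothing and is not simulated. The residual
component is drawn per location-year at the stock level and *independently
per model run*, because in calibration data the residual captures
treatment- (i.e. management-) specific model error. Consequently it
propagates into both the total series and the practice effects. At a real
survey's scale (~170k locations with ~730 ha weights) this structure
produces national standard deviations of a few Mt C yr⁻¹ and practice CIs
on the order of ±100% — the magnitudes national assessments report. At the
package's default desk scale (500 locations carrying ~250,000 ha each) the
same per-location error is multiplied by enormous weights, so CIs are much
wider relative to the mean. This is a scale effect of down-sampling the
survey, not a property of the method, and it is why the worked examples show
wide intervals.

Percentile (2.5/97.5) intervals are the primary CI; the normal
approximation ("a 95% interval is about ±2 s.d.") is available via the
reported standard deviations. With all three sources degenerate (M = 1,
zero covariance and variances, full-sample weights) the Monte Carlo
collapses exactly: s.d. 0 and mean equal to the deterministic estimate — a
tested identity.

## Management imputation

**Blocks.** Practices are imputed in 5-year blocks. The anchor hot-deck
block is 2001–2005, so block starts run 1981, 1986, …, 2011, and 1979–1980
fold into the first block.

**Tillage.** Trend series from two overlapping sources are harmonized by
per-class OLS over the overlap blocks (pre-overlap values mapped through the
fit, clamped to [0,1], renormalized; missing blocks linearly interpolated).
The anchor block is hot-decked within region × crop-group × texture strata
(empty strata fall back to region-level donors, with a warning). Adjacent
blocks are then sampled through `max_stay_transition()` matrices: the joint
mass puts $\min(p_i, q_i)$ on the diagonal — exactly the optimum of the
linear program maximizing stay mass subject to both marginals — and
distributes the residual by the northwest-corner rule over the fixed order
NT < RT < FT. The deterministic residual rule is a design choice: the LP's
diagonal is unique but its off-diagonal mass is not, and a deterministic
rule makes the tests exact. Row-stochasticity and $pT = q$ hold to
$10^{-12}$; sequences change tillage rarely while block marginals track the
trend series.

**Nitrogen.** Predict-then-match: a predictor (default: linear regression on
region, crop group, texture class and clay fraction; any
`predictor_fn(donors, newdata)` can replace it — the scientific content is
the predict-then-match contract, not the predictor family) scores donors and
recipients; each recipient receives the *observed* (fertilizer, manure) pair
of the donor with the nearest prediction, ties to the lowest donor id.
Matching one donor record for both N fields preserves their joint structure
— in particular the zero-inflation of manure. Imputed values therefore never
leave the donor support. Regional year multipliers are applied afterwards.

**Cover crops.** Anchor hot-deck, then a backward linear ramp: a location
cover-cropped at the anchor adopts in year $y \in [1991, 2000]$ with
probability $(y-1990)/10$ via a single persistent uniform per location, so
expected adoption rises linearly from exactly zero in 1990 to the anchor
level in 2000 (1995 sits at half the 2000 level). Post-2005 blocks add or
remove adopters to match census-style block targets. Termination practice is
unobservable in the underlying surveys, so it is a scenario axis: the
pipeline runs both variants and reports cover-crop effects under each.

Irrigation is copied from the survey frame, not imputed. Six sets are built
with independent substream seeds; the N-input matching is deterministic
given the donors, so between-set variation enters through the tillage and
cover-crop draws.

## The synthetic world

The generator's defaults define the study conditions and are not tuned
per-test:

* **Frame:** 500 locations (configurable) on a planar 800 × 500 km domain
  with four clustered regional strata; log-normal expansion weights rescaled
  to 125.4 Mha (the assessment-era national cropland area); G = 30
  delete-a-group jackknife replicate-weight vectors with variance multiplier
  $(G-1)/G$. The replicate construction is a standard stand-in: the real
  survey's replicate-weight scheme is proprietary and its G is unpublished.
  Planar kilometre coordinates keep IDW distances trivial; no geographic
  projection is implied.
* **Weather:** regional seasonal sinusoid plus AR(1) daily noise
  (ρ = 0.7) for temperature; a two-state occurrence chain with exponential
  wet-day intensities for precipitation, calibrated to regional normals;
  365-day years.
* **Adoption trends** (weighted national area fractions, matched in
  expectation through persistent per-location uniforms): cover crops zero
  before 1990, linear to 1.2% in 2000 and 1.6% (~2 Mha) by 2015;
  conservation tillage 5% (1979) → 15% (2000) → 24% (~30 Mha) by 2013, with
  a rising NT share; hay/pasture declining from 4.5% to 1.8% (4.7 → 2.3 Mha
  over 1995–2015), generated as rotation systems (one hay year per 3-year
  cycle while a location is in the system) because hay *in rotation with
  annual crops* is the practice being attributed; manure flat at 3.6%
  (~4.5 Mha); set-aside ramping up 1986–1993 to 10% and declining to 5% by
  2015. Monotone trends plus persistent uniforms give realistic multi-year
  spells instead of year-to-year churn.
* **Donors and calibration sites:** donors are sampled from the truth over
  the anchor years with 10% multiplicative observation noise on N rates and
  guaranteed stratum coverage; calibration sites have ≥ 2 treatments per
  site and encode a known linear bias (default intercept 5 t C ha⁻¹, slope
  0.9) with site-level (5 t C ha⁻¹) and residual (5 t C ha⁻¹) components,
  so the bias model's parameter recovery is checkable.

What the synthetic world does *not* emulate: spatially correlated weather
and soils, crop-specific phenology and yield feedbacks, measurement error in
the survey's crop histories, non-random adoption (adoption is independent of
soil and climate by construction), and real geography. Passing tests
demonstrate the statistical machinery — unbiased scaling, correct variance
propagation, marginal-faithful imputation, correct counterfactual
bookkeeping — under known conditions; they do not validate the surrogate
model's biogeochemistry against field data.

## Numerical choices and degenerate inputs

* Daily Euler steps: the discrete fixed point coincides with the continuous
  steady state for this linear system, and a step that would drive a pool
  negative raises an explicit instability error rather than clipping.
* `max_stay_transition` validates marginal sums to $10^{-6}$ and assigns
  rows with $p_i = 0$ the end marginal $q$.
* PMM ties break to the lowest donor id; hot-deck strata fall back
  region-level, then to the full donor pool.
* Zero practice area leaves the per-area rate `NA` with an `undefined` flag,
  never zero.
* IDW cells with fewer than `min_points = 5` locations within
  `radius_km = 20` are null; a point within 1 m of a centroid
  short-circuits; the exponent (default 2) and the cell-centroid convention
  are configurable because the source convention is unstated.
* All randomness flows from one master seed through named substreams
  (`substream_seed`), so any stage reproduces in isolation and identical
  configurations are bit-identical.

## Problem sizes

The package's reference configuration — and the one its end-to-end checks
use — is 500 locations, M = 6 imputation sets, 37 history years, and 1000
Monte Carlo iterations; a full pipeline run takes on the order of a minute
on a single core, with the simulation work done by the compiled daily pool
loop and cached across Monte Carlo iterations. The unit-test world is
smaller (120 locations, M = 2) purely as a matter of test hygiene.

## Known limitations

* The pool model is a surrogate: no nitrogen cycling (fertilizer N affects
  nothing but the manure-to-synthetic bookkeeping), no N₂O or CH₄, no
  explicit water balance, no depths below 30 cm.
* The tillage-termination penalty (one 30-day full-till window) is mild; in
  richer process models termination method can flip the sign of the
  cover-crop effect, here it only orders it.
* Legacy dynamics can turn the late-series hay/pasture effect negative at
  low remaining area: locations that left hay rotation carry elevated
  stocks whose faster decomposition outweighs the dwindling current-hay
  gains. The effect's *decline* is the robust feature.
* Desk-scale confidence intervals are dominated by the prediction-error
  scaling discussed above; comparisons of CI widths with survey-scale
  assessments are not meaningful.
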