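# iceways

Freshwater lakes and rivers of the North freeze later and thaw earlier than
they used to. For terrestrial animals that travel across frozen water bodies —
most prominently migratory caribou, whose routes cross some of the largest
lakes and reservoirs of the subarctic — the window during which ice supports
locomotion is part of the migration corridor itself. `iceways` is an R
toolbox for quantifying that link at fine scale, written for movement
ecologists and spatial biostatisticians. It covers four stages:

1. **Ice phenology** from 8-day classified rasters. For each period the
   ice/water index over a water mask is

   *I = (n_ICE − n_WATER) / (n_ICE + n_WATER)*,

   with land and cloud cells excluded from both counts, so *I* = −1 for open
   water and *I* = +1 for a completely frozen surface. Breakup and freeze-up
   dates are the x-intercepts of the index series (linear interpolation
   between bracketing periods), the ice-availability window is the span
   between one winter's freeze and the next breakup, and linear trends of the
   dates across years are tested by OLS.

2. **Trajectory segmentation.** GPS fixes are turned into steps (length,
   duration, rate in m/h, heading, turning angle), clipped to water-body
   surfaces and their 5-km buffers, cleaned of stopovers (clumped runs of
   fixes on land), and classified into ice crossings, water crossings,
   detours, or vicinity-only movement, with per-segment movement metrics and
   buffer-composition summaries.

3. **Step-selection inference.** Each observed step is matched to 10 random
   control steps drawn from the individual's empirical step-length (top 5 %
   trimmed) and turning-angle distributions. A conditional-logistic model

   *L(β) = Σ_s [ x_obs,s′β − log Σ_j exp(x_j,s′β) ]*

   with water and ice step-composition covariates is maximized by
   Newton–Raphson (an implementation cross-checked against
   `survival::clogit`), models are compared by AICc over strata, and fit is
   validated by rank-based k-fold cross-validation (mean Spearman r̄s between
   within-stratum prediction ranks 1–11 and observed-step counts).

4. **Climate scenarios.** Breakup is advanced and freeze-up delayed in 1-day
   increments (up to 30 days); ice crossings dated outside the shrunken ice
   window are flagged impossible, and those on lakes/reservoirs (rivers and
   island endpoints excluded) are replaced by shortest land detours over an
   8-connected grid, yielding projected travel-distance changes with paired
   t-tests.

A first-class synthetic-data module (`generate_landscape`,
`generate_ice_series`, `simulate_trajectories`, `simulate_ssf_strata`)
generates landscapes, seasonal ice-raster series with classification noise
and cloud gaps, and behaviour-driven multi-individual trajectories with
known ground truth, so the whole pipeline is testable without telemetry or
satellite data.

## Worked example

```r
library(iceways)

ls    <- generate_landscape(landscape_config(), seed = 1)
truth <- phenology_truth(breakup_doy = 148, freeze_doy = 323,
                         noise = 0.02, cloud = 0.05)
ser   <- generate_ice_series(ls, truth, years = 2010:2012, seed = 1)
ph    <- phenology_series(ice_index_series(ser, water_mask(ls)))
print(as.data.frame(ph), digits = 4)
#>   year breakup_doy freeze_doy window_days flags
#> 1 2010       148.2      323.6          NA
#> 2 2011       148.3      323.5       189.7
#> 3 2012       148.4      323.4       189.9

st  <- simulate_ssf_strata(1000, seed = 1)   # truth: water -0.733, ice 0.475
fit <- fit_clogit(st)
print(fit)
#> Step-selection fit: 1000 strata, k = 2, LL = -2390.54, AICc = 4785.10
#>                  beta        se          z           p
#> prop_water -0.8807274 0.2765746 -3.1844124 0.001450482
#> prop_ice    0.1587849 0.2501176  0.6348409 0.525532172
```

The phenology table recovers the generating dates (day 148 ≈ late May
breakup, day 323 ≈ mid-November freeze, a 190-day ice window) to a fraction
of a day despite 2 % classification noise and 5 % cloud gaps. The fitted
selection coefficients show significant avoidance of open water and a
positive (here non-significant at n = 1000 strata) coefficient for ice; both
estimates agree with the generating truth within two standard errors.

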