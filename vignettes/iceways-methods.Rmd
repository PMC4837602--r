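---
title: "Methods: ice phenology, trajectory segmentation, step selection, and phenology-shift scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ice phenology, trajectory segmentation, step selection, and phenology-shift scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iceways)
```

`iceways` links the phenology of freshwater ice to the fine-scale movement
decisions of migrating ungulates. This vignette documents the models and
procedures the package implements, the parameters that matter and their
defaults, the design choices made where several defensible options existed,
and the limits of what the synthetic-data tests can show.

## Ice phenology

### The ice/water index

Classified 8-day rasters (cell codes `LAND = 0`, `ICE = 1`, `WATER = 2`,
`CLOUD = 3`, 500-m cells by default) are summarized over a water mask by

$$ I \;=\; \frac{n_\mathrm{ICE} - n_\mathrm{WATER}}{n_\mathrm{ICE} + n_\mathrm{WATER}}, $$

so $I = +1$ on a completely frozen surface and $I = -1$ on open water. Land
and cloud cells are *null*: excluded from numerator and denominator alike.
A period whose masked cells are all null yields an undefined (flagged)
record rather than an error, and such records are skipped when dating.

Two sign conventions circulate for indices of this family. `iceways` keeps
ice positive, as the formula above is written: breakup is therefore a
positive-to-negative crossing and freeze-up a negative-to-positive crossing.
All downstream code and documentation follow this orientation consistently.

### Dating breakup and freeze-up

Within a year, breakup is searched among records up to mid-year (day-of-year
183, the natural split for northern-hemisphere seasonality) and freeze-up
from mid-year on. A crossing is located by **linear interpolation** between
the two bracketing 8-day records; snapping to period labels would discard up
to four days of information for no robustness gain. Because shoulder-season
records flicker under classification noise, a crossing only qualifies if the
new sign **persists for at least two subsequent records**, and among
qualifying crossings the *last* one is taken; a year with no qualifying
crossing is flagged missing rather than guessed. Dates are reported as
fractional day-of-year; calendar formatting is left to the caller.

The ice-availability window of a winter is `(days in year y−1 − freeze(y−1))
+ breakup(y)`, labelled by its breakup year and flagged missing when either
endpoint is. Trends of dates across years use ordinary least squares with
the F-test of zero slope on n−2 df; a constant response is reported as F = 0
rather than as the 0/0 artifact a naive computation produces.

With the 8-day cadence, a noise-free series determines each crossing to
within half a period; the tests require recovery within 4 days in the clean
case and within 8 days under 5 % classification noise plus cloud gaps.

## The synthetic-data generator

The generator exists to give every downstream stage inputs with known
ground truth; it is a test harness, not a behavioural claim about caribou.

* **Landscapes** are LAND grids with rectangular water bodies (lake, river,
  reservoir types; optional rectangular islands) aligned to cell boundaries,
  so footprints are exact and polygon/raster consistency holds by
  construction. Coordinates are projected metres throughout — all metrics
  (m/h, km) are Euclidean, and no geographic math is used anywhere.
* **Ice series** classify each water cell ICE with a probability following a
  logistic curve of day-of-year around the year's true breakup/freeze dates
  (default steepness 3 days), then flip it with the noise rate and mask it
  CLOUD with the gap probability. Periods run from day-of-year 33 (start of
  February) in 8-day windows, the cadence of the classified product the
  pipeline consumes; the period timestamp is the first day of the window.
* **Trajectories** follow a biased correlated random walk: 24 equally spaced
  candidate headings; a gamma base step length (default shape 2, scale 270
  m/h, i.e. ≈540 m/h mean hourly displacement, matching ordinary migratory
  travel rates) scaled by the fix interval; heading weights
  $\exp(\beta_\mathrm{ice}\,\mathrm{ice} + \beta_\mathrm{water}\,\mathrm{water}
  + \kappa \cos(\theta - \theta_\mathrm{goal}))$ with the substrate probed at
  the candidate step's midpoint *and* endpoint (a candidate touching open
  water at either probe counts as water, so a strongly negative
  $\beta_\mathrm{water}$ keeps whole steps dry — probing the midpoint alone
  lets walkers strand in open water). Realized length is multiplied by the
  on-ice speed factor (default 3, reflecting the roughly threefold
  ice-versus-terrain contrast in observed movement rates). Stopover bouts
  (clustered, jittered fixes) start at a per-step rate while on land. Fix
  intervals are drawn per individual from the mixed 1, 2, 7, 11, 13 h
  schedule. Default selection coefficients are water −0.733 and ice 0.475 —
  the values the step-selection analysis is expected to recover.
* **Ground-truth strata** (`simulate_ssf_strata`) are drawn exactly from the
  conditional-logit data-generating process: candidate covariates come from
  an availability mixture (a point mass of land-only steps plus
  beta-distributed water-surface fractions split between ice and open water
  by a stratum-level "season"), and the observed step is selected with
  probability proportional to $\exp(x'\beta)$. Estimator-recovery tests use
  these strata because the random walk is not itself a conditional-logit
  process.

What the generator does **not** emulate: GPS measurement error, real
shoreline geometry (bodies are rectangles), ice-thickness heterogeneity,
weather, predators, energetics, or demographic turnover. Passing tests
therefore demonstrate that the estimators recover what they are designed to
recover under their own assumptions, not that those assumptions hold in any
particular field system.

## Trajectory segmentation

Steps are straight lines between successive fixes of one individual:
Euclidean length, duration in hours, rate in m/h, heading, and from the
second step on a signed turning angle in (−180°, 180°]. Duplicate
timestamps are an error naming the individual and time.

Movement near large water bodies is isolated by keeping maximal runs of
consecutive fixes on a body's surface or within a 5-km buffer. The boundary
is **closed** (a fix at exactly 5 000 m is kept); runs touching two bodies
are split at the change of nearest-body assignment; runs of fewer than
three locations are dropped because a turning angle needs three.

Stopovers — runs of at least `min_fixes` consecutive fixes on land whose
pairwise maximum displacement is at most `radius_m` — are collapsed to
their final fix. The criterion in the source analyses is qualitative
("clumped locations"), so the thresholds are this package's defaults:
radius 1 000 m, `min_fixes` 4, both exposed in the API. Removal iterates to
a fixed point, which makes it idempotent by construction; clumps on ice or
open water are never removed, since lingering on ice is substantive
behaviour rather than a stopover.

A segment is a **crossing** when any step's chord, sampled at half-cell
spacing, lies on the body's surface for at least 10 % of its length — the
threshold stops shoreline-grazing steps from being called crossings. The
crossing substrate (ice vs water) is the majority class of the on-surface
sample points on the date-matched raster (the raster whose 8-day window
contains the step's start time; ties resolve to ice, and cloud cells fall
back to the nearest clear period for that cell). A non-crossing segment is
a **detour** when its net displacement reaches the body's smaller
bounding-box side (it passed the body rather than lingering); anything else
is vicinity-only and excluded from crossing/detour counts.

Movement metrics are arithmetic means over a segment's steps; turning
angles are summarized as means of absolute angles on the 0–180° scale (the
convention of the summaries this mirrors), not circular means. Substrate
contrasts are estimated by a method-of-moments analogue of a
random-intercept model: within each individual-by-interval group holding
both substrates, the group-mean difference is computed, and the contrast is
the mean of those differences with its between-group SE and a t reference
on groups−1 df. Full REML machinery with Satterthwaite df is deliberately
out of scope; the grouped-difference estimator is unbiased under the same
random-intercept structure, holds its nominal type-I error in simulation,
and degrades gracefully (a pooled Welch comparison, with a warning) when
fewer than two groups are informative.

Buffer composition reports the proportions of ICE and WATER cells among all
cells whose centres fall within 1-km or 2.5-km discs — land stays in the
denominator, so the proportions deliberately do not sum to one.

## Step selection

Availability distributions are empirical, keyed by individual × fix
interval: step lengths with the top 5 % removed (`floor(n × trim)` largest
values — guarding against overly long random steps), and *signed* turning
angles (the signed choice preserves any lateral bias in the empirical
distribution; absolute angles would have to invent a symmetry). Each
observed step with a defined previous heading gets 10 controls sharing its
origin; a control's heading applies a sampled angle to the previous
*observed* heading — the standard matched-availability design — and its
length is sampled independently. Controls may land anywhere, including
outside the buffer. Observed steps without a previous heading are skipped
and counted, never silently dropped.

Step covariates are the fractions of chord sample points (half-cell
spacing) classified WATER and ICE; cloud points fall back to the nearest
clear period for their cell and otherwise leave the denominator. Points
beyond the grid count as land.

The conditional log-likelihood
$\sum_s [x_{\mathrm{obs},s}'\beta - \log \sum_{j \in s} \exp(x_{j,s}'\beta)]$
is maximized by Newton–Raphson from $\beta = 0$ with step-halving on any
likelihood decrease, stopping when the gradient max-norm falls below 1e−8
(50-iteration cap). No regularization is used — the likelihood is concave —
and the implementation is cross-checked against `survival::clogit` and
against a brute-force grid search in the tests. Degenerate inputs have
defined behaviour: a covariate with no within-stratum variation anywhere is
a named error; complete separation yields a non-convergence flag (diverging
estimate) instead of a silent number; strata whose observed step has no
covariate contrast with its controls are retained (they contribute zero
gradient) and counted. Standard errors come from the inverse observed
information.

AICc uses $-2LL + 2k + 2k(k+1)/(n-k-1)$ with **n = number of strata** — the
independent units of a conditional likelihood. Model comparison adds
covariate × body-type interactions (lake as reference) as the richer
model.

Validation follows the rank protocol: 10 random 80/20 splits of strata; in
each test stratum the 11 steps are ranked by fitted score (rank 11
highest, ties broken by seeded random order — the protocol leaves
tie-breaking open, and a seeded draw keeps runs reproducible); observed-step
ranks are tallied and correlated with 1–11 by the tie-corrected (midrank)
Spearman formula. One caution the tests make explicit: the per-draw null
distribution of this correlation has an intrinsic standard deviation near
$1/\sqrt{10} \approx 0.32$ regardless of test-set size, because the
correlation is computed over only 11 rank bins; null means over 10 draws
scatter roughly ±0.15 around zero, which is why the null check uses a ±0.2
band while strong simulated selection clears 0.5.

## Phenology-shift scenarios

A spring ice crossing dated $d$ days is impossible under a breakup advance
of $\delta$ iff $d > \mathrm{breakup} - \delta$; a fall crossing under a
freeze delay iff $d < \mathrm{freeze} + \delta$. The crossing *date* is the
timestamp of the first fix on the water-body surface (the procedure's
sources are silent; the first surface contact is the moment ice is actually
committed to). Shifts run 0–30 days in 1-day increments, so the
lost-crossing proportion is non-decreasing in the shift by construction —
a property the tests verify on arbitrary inputs. Literature projections for
the 2041–2070 horizon default to a 10–15-day spring advance and
7.8–13.8-day fall delays; seasonal maxima combine into an overall
lost-crossing proportion.

Impossible ice crossings within the analysis window — the first 15 days
after freeze-up or before breakup, closed at both ends — are replaced by
shortest land detours between the crossing's first and last fixes.
Crossings of river-type bodies and crossings whose endpoints lie on islands
are not replaced (an alternate land route is generally unavailable), and a
crossing with no land-connected route is kept at its original distance and
counted separately. Paths are computed on the 8-connected landscape grid
(straight moves cost one cell, diagonals $\sqrt{2}$) with water-surface
cells excluded, via Dijkstra on a weighted lattice. A grid metric was
chosen over polygon-visibility geodesics because it is simple, handles
arbitrary obstacle shapes, and is verifiable against an independent
shortest-path oracle; its known bias is an overestimate of Euclidean
geodesic length of at most ≈8 % (the 8-connectivity bound), which is
conservative for the projected extra distances reported. Totals compare
observed window distance with the projected one; detour-to-crossing ratios
and a paired t-test on the raw distances (logs would change the question
from "how much farther" to "how many fold") complete the summary.

## Problem sizes and tolerances in the test suite

The suite runs entirely on synthetic data at sizes chosen to keep each
property sharply testable: 1 000–1 500 strata for estimator recovery
(coefficients within 3 SE of truth, across 20 seeds), 5 000+ simulated
steps for speed-ratio checks (within 20 % of the factor-3 truth), 1 000–
2 000 replicates for type-I-error checks (rates within ±0.02 of 0.05), 100
random ≤50×50 grids for exact shortest-path agreement with the oracle, and
single-year raster series for phenology recovery (4-day clean / 8-day noisy
tolerances, i.e. half and one 8-day period). Fixed seeds make every
stochastic check reproducible.

## Known limitations

* Rectangular water bodies make polygon arithmetic exact but cannot probe
  concave-shore pathologies (e.g. bays that trap grid paths).
* The mixed-model surrogate estimates contrasts and their uncertainty but
  not variance components; studies needing those should export
  `segments.csv` and fit `lme4`/`lmerTest` models directly.
* Cloud handling is nearest-in-time fallback per cell; no spatial
  interpolation is attempted.
* The scenario engine treats phenology shifts as exogenous inputs; it does
  not model the climate that produces them, nor behavioural adaptation
  (e.g. retimed migration) to them.
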