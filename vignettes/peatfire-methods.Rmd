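---
title: "Methods: column hydrology, fortnightly fire models, and the synthetic benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: column hydrology, fortnightly fire models, and the synthetic benchmark}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`peatfire` couples a process-style water balance for stand-alone tropical soil
columns to a pair of fortnightly neural-network fire-count regressors, so that
the value of simulated hydrology for fire forecasting can be studied and
tested end to end without any external data. This vignette documents the
model equations, the tunable parameters and their defaults, the numerical
choices, and what the synthetic benchmark does and does not establish.

## The soil column water balance

Each grid cell is one vertical soil column (default 15 layers, 2 m total,
surface litter layer of 0.02 m) that never exchanges water with neighbouring
cells — only vertically with the atmosphere and laterally with a fixed
boundary water table. The daily balance is

P − ET − Q_lateral − Q_runoff = ΔS,

and the implementation moves explicit amounts of water between stores, so the
ledger closes to machine precision; the test suite enforces 1e−6 m on random
states and forcing.

**Retention and conductivity.** Each layer carries a van Genuchten retention
curve θ(ψ) = θ_r + (θ_s − θ_r)[1 + (αψ)^n]^(−m), m = 1 − 1/n, with the Mualem
conductivity closure K(θ) = K_sat √S_e [1 − (1 − S_e^{1/m})^m]². Any monotone
retention family satisfying the same limits would serve; van Genuchten was
chosen because pedo-transfer literature for peat and tropical mineral soils is
readily available for it. Parameters either come from retention samples via
`fit_retention()` (box-constrained Levenberg–Marquardt, multi-start over
plausible (α, n) pairs because the α–n likelihood surface is strongly
correlated) or from pedo-transfer defaults driven by bulk density and organic
matter. Saturated conductivity uses log-linear pedo-transfer forms — peat:
10^(2 − 13·BD) m/d, mineral: 10^(1.2 − 1.2·BD + 2·OM) m/d, clamped to
[0.001, 50] m/d — giving ~9 m/d for loose fibric peat (BD 0.08) down to
~0.1 m/d for dense sapric peat (BD 0.2). Both forms are configurable; the
point tests only pin the documented defaults.

**Vertical flow.** A tipping-bucket scheme with 24 sub-steps per day: rain
wets the litter, overflow ponds and infiltrates the top layer at up to
K_sat·dt; water above field capacity (suction 0.34 m ≈ 3.3 kPa) cascades
downward rate-limited by K(θ), and is blocked by saturated layers below, so
saturation grows from the column bottom and a water table forms. A full
Richards solution is deliberately out of scope; the sub-step refinement test
(24 vs 48 sub-steps changing end-of-run water table by < 5 mm) bounds the
splitting error.

**Evapotranspiration.** Potential ET is an FAO-56-style daily reference value
(grass reference, albedo 0.23, clear-sky longwave, soil heat flux 0) scaled
by a land-cover coefficient (pristine forest 1.00 down to smallholder 0.85).
Negative radiative balance clamps to zero before scaling, keeping PET exactly
linear in the coefficient. Actual ET is PET times a linear stress ramp on
root-zone (top 0.3 m + litter) water between wilting (ψ = 153 m ≈ 1.5 MPa)
and field capacity. The litter evaporates first; root uptake is distributed
across root-zone layers in proportion to each layer's available water, the
standard availability-weighted scheme — this matters for the peat/mineral
near-surface contrast, because a peat column with a shallow water table keeps
transpiring from depth rather than stripping its surface layers.

**Lateral exchange.** Darcy exchange with a prescribed boundary water table
WTDx (the water level of the adjacent watershed or drainage canal, m below
the column surface):

q = K̄_sat · (WTDx − WTD)/L · (b / D),

where K̄_sat is the thickness-weighted saturated conductivity of the
transmitting zone, L the effective lateral distance (default 100 m), b the
transmitting saturated thickness (below the deeper of the two heads... below
`min(WTD, WTDx)`), and D the column depth. The b/D factor reads the flux
density "applied over the saturated thickness" as the fraction of the column
cross-section that transmits; it gives drainage time scales of weeks to
months for peat at L = 100 m, consistent with seasonal drawdown. Positive q
is discharge (boundary deeper than the column water table); water is removed
from the top of the saturated zone downward, and recharge fills layers from
the bottom up. With WTD = WTDx the flux is exactly zero.

**Water table diagnosis.** WTD is the top of the contiguous saturated stack
reaching the column bottom (a layer counts as saturated at θ ≥ 0.999·θ_s),
linearly interpolated into the first unsaturated layer above the stack to
avoid layer-thickness quantisation. Ponded surface water puts the water table
at the surface. With no bottom saturation WTD is capped at the column depth —
a convention for a case the physics leaves undefined. Internally WTD is a
positive depth below the surface; exports carry both signs (`wtd`,
`wtd_signed`) because figure conventions in this field plot depths negative.

**Near-surface moisture** is the thickness-weighted mean of the litter
(0.02 m) and the top two soil layers. The default grids use 0.03 m for *each*
of the two layers (0.08 m total) — the natural reading of "top two layers
(thickness = 0.03 m)"; the layer thicknesses are configurable where a
different reading is wanted.

**Boundary-condition defaults.** Non-peatland cells outside mangroves drain
to WTDx = 6 m, deep enough to allow free drainage of the whole profile.
Peatland defaults encode progressively more intensive artificial drainage:
pristine forest 0.25 m, degraded forest 0.30 m, industrial plantation
0.55 m, smallholder farmland 0.65 m. These were chosen once so that the
simulated mean water-table ordering reproduces the field-observed ordering
(forest shallower than plantation shallower than smallholder); the ordering —
not the specific values — is what the structural test asserts. Mangroves are
tidal and get a surface boundary (0 m); their water balance is otherwise out
of scope.

**Spin-up.** Production runs are preceded by repeating the first forcing year
until the annual-mean water table drifts less than 1 mm between cycles, with
a hard cap of 56 cycles. In practice convergence takes a handful of cycles;
the two-start convergence test (initially dry vs initially saturated columns
ending within 1 mm mean WTD) shows the initial state is forgotten.

## Fortnight features

The prediction time step is the non-overlapping 14-day block, anchored at
1 January of each year; the 1–2 remainder days at year end are dropped (the
anchoring convention is otherwise immaterial and is fixed for
reproducibility). Features per (cell, fortnight): means of air temperature,
radiation, wind and relative humidity; total precipitation; and precipitation
summed over the 28 days strictly before the block (pre-drying). Records whose
antecedent window is not covered — the first two blocks of a series — are
dropped rather than padded. The weather-only design matrix (6 columns) is by
construction the first 6 columns of the weather+hydrology matrix (8 columns:
plus fortnight-mean WTD and near-surface moisture).

## The fire-count networks

Both variants use the same four-layer architecture: input (6 or 8 nodes), two
hidden layers of 32 and 16 relu neurons, and one linear output; loss is mean
squared error optimised by Adam at learning rate 0.001. Training is
leave-one-year-out: one fold per calendar year, fitted on the other years
only; feature z-scoring constants are likewise computed on the training years
only. Every record gets exactly one out-of-sample prediction, from the fold
that held out its year. Negative raw outputs are clipped to zero (counts are
nonnegative; the hidden layers are relu, the output is linear).

Choices the architecture description leaves open, fixed here as defaults:
mini-batch size 256; at most 500 epochs; early stopping on an internal
validation split with patience 20, restoring the best weights; the internal
split takes every 10th row within each training year — deterministic and
stratified by year, so a fold's weights depend only on its training rows and
the seed (the fold-hygiene test deletes the held-out rows and requires
bit-identical weights). Weights initialise fan-in-scaled uniform from a
seeded generator; fits are bit-reproducible given the seed. The network is
implemented in compiled code inside the package because no multi-hidden-layer
regression network with this training protocol exists in the R stack the
package targets.

One pooled model is trained over all cells (cells contribute rows), rather
than one network per cell: at 50 cells × 8 years there are ~200 records per
cell, too few to fit 5,000-weight networks per cell, and the pooled model
keeps the benchmark inside a desk-scale budget. A per-cell protocol is a
documented deviation that the interface permits (subset the records by cell)
but is not the default.

## Evaluation

Predicted and observed counts are pooled (summed) per fortnight over peatland
cells, non-peatland cells, and all cells; skill is R² and MAE on the pooled
series, per validation year and overall, plus R² of the first-differenced
series n_{t+1} − n_t, which is sensitive to peak-timing errors. Residual
distributions (mean annual residual per cell) are summarised by quantiles
split by peatland class.

The fire-occurrence water-table threshold is estimated by scanning candidate
depths 0.00–1.00 m in 0.01 m steps and maximizing Youden's J
(sensitivity + specificity − 1) for the rule "fire fortnight ⇔ WTD ≥ depth",
ties broken toward the shallower depth, and flagged uninformative when max J
< 0.05. A "fire event" is a fortnight with any fire (count > 0) — the
simplest formalisation, configurable via the indicator the caller passes.
The estimator is invariant to strictly monotone transforms applied
consistently to data and candidates (property-tested).

Hydrology benchmarking against observation-like moisture uses per-cell
Pearson correlations of daily series and subset medians; with observation
noise variance equal to signal variance the expected correlation is
1/√2 ≈ 0.707 (attenuation), which the synthetic observation generator
reproduces.

## The synthetic benchmark

`synthetic_truth()` fixes a seeded generative world emulating the study
setting — a Sumatran peatland province on a 0.05° grid:

* **Rainfall**: per-day Bernoulli wet/dry with seasonal wet probability
  (0.65 wet season; 0.45 in the short dry window, days 15–59, mid-January to
  late February; 0.25 in the long window, days 166–300, mid-June to late
  October) and gamma wet-day amounts calibrated so the expected annual total
  is 2500 mm. Drought years (defaults 2009 and 2015) scale amounts by 0.6.
  This is the simplest family matching the qualitative regime; the real
  study region's forcing is reanalysis data, not a generative model.
* **Soils**: 60% peat cells (bulk density 0.08–0.15 Mg/m³ increasing with
  depth, organic matter ~0.85–0.92) and 40% mineral cells (BD ~1.25–1.40,
  OM ≤ 0.05), with per-cell jitter; 15 layers to 2 m with the two 0.03 m
  layers at the top. Peat land uses mix 30/20/30/20% pristine forest,
  degraded forest, industrial plantation, smallholder.
* **Fires**: fortnightly Poisson counts with rate
  λ = λ_max · sigmoid((WTD − d\*)/s) · dryness(θ_ns), d\* = 0.4 m, s = 0.04 m,
  λ_max = 2 counts/fortnight/cell, and a dryness modifier ramping from 1
  (θ_ns ≤ 0.2) to 0.5 (θ_ns ≥ 0.7). The narrow sigmoid makes the response
  threshold-like: a saturated column has λ < 10⁻⁴·λ_max. With a modest
  λ_max the fortnight event probability is roughly proportional to λ, and
  then the Youden-J maximiser sits where the sigmoid equals its average over
  the WTD distribution — i.e. essentially at d\* for a distribution that
  straddles the threshold, which the land-use mix guarantees. That analysis,
  not trial and error, fixed s and λ_max.
* **Observed moisture**: true series plus clamped gaussian noise.

Generator parameters ride along with the data, so recovery tests are
self-validating: the threshold-recovery check regenerates everything from 10
seeds and requires the mean Youden estimate within ±0.05 m of d\*.

**What passing does and does not show.** The benchmark establishes internal
correctness — conservation, convergence, fold hygiene, metric definitions,
parameter recovery, and the *structural* reproduction of the study
phenomenology (peat wetter than mineral near the surface through dry seasons;
drainage-ordered water tables; hydrology features strictly improving pooled
out-of-sample skill in ≥9/10 replicates). It cannot certify accuracy on real
forcing and real fire data: the generator has no spatial rainfall
correlation, no coastal tidal effects, no human ignition dynamics, and its
fire process is by construction driven by the simulated hydrology, which is
favourable to the hydrology-informed variant in sign (though not in any
particular margin). Real-data headline numbers are therefore not targets of
the test suite.

## Problem sizes and budgets

The default benchmark is 50 cells × 8 years (≈10,300 fortnight records,
~146,000 cell-days of simulated hydrology per replicate), 10 replicate seeds
for the stochastic checks, chosen to keep the full suite in the minutes
range on one CPU while leaving Poisson counting error well below the margins
being tested. The compiled column stepper simulates a cell-year in about
20 ms; training one fold takes well under a second.

## Known limitations

* The tipping-bucket scheme has no upward capillary flux; near-surface
  rewetting from a shallow water table is mediated only by reduced drainage
  and the ET stress ramp.
* The litter layer is a single bucket wetted by rain and dried by
  evaporation; it does not equilibrate with the top soil layer.
* Mangrove hydrology (tidal forcing) is reduced to a surface boundary head.
* WTDx is static per cell; seasonally managed canal levels are not
  represented.
* The fire generator's dryness modifier uses absolute moisture, so it damps
  peat fire rates relative to mineral ones; it is a modifier, not a
  calibrated flammability model.
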