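---
title: "Methods: gridding, trends, ranking, and risk composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridding, trends, ranking, and risk composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorisk)
```

## The problem

Local microplastic emissions in the Southern Ocean come mainly from ships and
terrestrial facilities. Where those emissions are most likely to matter
depends on where biota are concentrated (krill and the phytoplankton they
graze) and where the environment is already under stress (warming surface
water, declining pH). `sorisk` turns six heterogeneous observation streams
into comparable gridded layers, grades each on a common 1–5 concern scale,
and composes the grades into baseline, interaction, and combined risk maps.
The combined map locates *hotspots*: cells where potential emissions overlap
both biota and existing abiotic stress.

None of the upstream source datasets ship with the package (several are
proprietary); instead, a synthetic-data module generates inputs with the same
statistical structure and a known ground truth, so that every stage of the
pipeline is verifiable at desk scale.

## The common grid

All layers live on one longitude–latitude grid, by default 9° × 3° south of
45°S (40 columns × 15 rows): the resolution at which krill net samples can be
pooled meaningfully, which therefore sets the resolution of every map.
Cells are half-open intervals `[lo, hi)` on both axes with the longitude
origin at −180° and +180° wrapping, so the cells partition the domain: a
randomized sweep in the test suite confirms no coordinate falls in zero or
two cells. Cell areas use the spherical-zone formula
\(A = R^2\,\Delta\lambda\,(\sin\varphi_{hi}-\sin\varphi_{lo})\) on an
authalic sphere (R = 6371.0072 km, configurable); the suite checks the areas
sum to the closed-form zone area of the whole domain to 1e-9. The grid
deliberately extends to the pole and carries no land mask — missingness
belongs to the layers, not the geometry.

## Zero-assimilating geometric mean

Krill densities from net hauls are right-skewed and zero-inflated, so cells
are summarised by a geometric rather than arithmetic mean. The ordinary
geometric mean collapses to zero with a single empty haul, so zeros are
assimilated by weighting the geometric mean of the positive observations
with the positive fraction:

$$G \;=\; \frac{n_{pos}}{n}\,\exp\!\Big(\frac{1}{n_{pos}}\sum_{x_i>0}\log x_i\Big).$$

This is the nonnegative-data special case of the signed extension of the
geometric mean; it reduces to the ordinary geometric mean without zeros, to
zero when all observations are zero, and never exceeds the geometric mean of
the positive subset. The formula is isolated in one exported function
(`geometric_mean_with_zeros()`) so it can be swapped if a different
zero-handling convention is preferred, and the test suite checks it against
an independent product-of-roots implementation.

Samples are pooled across all years within a cell (a single interannual
geometric mean per cell) and month-filtered to January–March, the months the
krill data represent; the chlorophyll raster is regridded the same way, by
the geometric mean of the fine cells whose centres fall inside each coarse
cell. Centre-in-cell membership was chosen over areal weighting: at a 1/12°
to 9° resolution ratio the difference is negligible and the convention is
unambiguous.

## Per-cell trends: the five-step method

Sea surface temperature and pH enter as per-cell time series and leave as a
linear gradient with a 95% confidence interval and a significance flag:

1. **Monthly means** — daily values are averaged within calendar months
   (`to_monthly()`); already-monthly products skip this step.
2. **Climatology** — per-calendar-month means over a fixed reference window,
   1993–2014 by default (`compute_climatology()`).
3. **Anomalies** — climatology differenced from the monthly means.
4. **Seasonal adjustment** — an additive X11-style decomposition
   (`x11_decompose()`): initial trend by a centred 2×12 moving average;
   initial seasonal factors by a 3×3 moving average within each calendar
   month, re-centred by removing their own 2×12 moving average; refined
   trend by a 13-term Henderson filter of the deseasonalised series; refined
   seasonal by a 3×5 within-month moving average, re-centred; irregular as
   the exact residual. This is the classical X11 core rather than a full
   X-11-ARIMA system: it captures the seasonal/trend split with fully
   specified filters, and the function is pluggable if a complete X11
   implementation is preferred.
5. **Linear fit** — ordinary least squares of the decomposed trend component
   against time in decimal years (`linear_trend()`), with the standard
   two-sided t-interval and t-test on the slope; cells with p > 0.05 are
   flagged insignificant. Fitting the seasonally adjusted series
   (trend + irregular) instead is available via `fit_on =
   "seasonally_adjusted"`.

Two numerical choices deserve explanation.

*Endpoints.* Every moving average uses truncated windows renormalised to sum
one at the series ends, so all three components are defined over the full
span and reconstruct the input exactly everywhere. The price is distortion
near the ends: working through the filter cascade, the trend component is
affected within 42 months of each end and the seasonal within about 84. The
trend regression therefore drops a 48-month run-in at each end
(`trim_months`, configurable). On noiseless linear-plus-seasonal input this
makes the recovered gradient exact to machine precision, which the
acceptance suite verifies at 1e-10.

*Serial correlation.* OLS on a smoothed trend component has optimistic
nominal significance, since the Henderson filter correlates neighbouring
residuals. This is retained deliberately — the method is defined as
decompose-then-fit — and documented rather than corrected; the type-I-error
guarantee in the acceptance suite is stated for the fitting step applied to
independent noise, where the t-test is exact.

Gaps of up to two consecutive missing months are linearly interpolated
before filtering; longer gaps or fewer than 36 non-missing months make a
cell's series unusable, and `trend_map()` records such cells as failures
while continuing with the rest of the map.

## Human-activity proxies

Both human layers are expressed in person-days per year, the common currency
that makes ships and facilities comparable. Ship records (vessel, type,
year, cell, days) are multiplied by a per-type typical-persons-aboard table,
summed within the five vessel types (fishing, tourist, cargo/supply,
research, other) per cell and year, and averaged across years; the total
layer is the sum of the five type layers. The persons-aboard values are
configuration, not constants: the defaults shipped in `default_config()` are
plausible mid-range crew/passenger counts and every test sets them
explicitly.

Facilities convert as 365·p person-days per year when operated year-round
and 182.5·p when seasonal (six months at peak population p). The facility
*density* layer (people per 10,000 km²) spreads each facility's population
over distance: a cell containing facilities takes their summed population
divided by the cell area; every other cell receives
\(p/(\pi d^2)\) from each facility, where d is the great-circle distance to
the cell centroid — the population spread uniformly over the disc whose
radius is that distance, an inverse-square smoothing representing uniform,
undirected dispersion. An alternative reading that additionally multiplies
by the cell-to-disc area ratio (an inverse fourth power) is implemented
behind `method = "areal_product"` for comparison; the inverse-square form is
the default because it matches the model's stated behaviour. Whether
seasonality should discount the density proxy is genuinely open; the default
uses peak population directly (the population housed at the facility), with
`seasonal_weighting = TRUE` switching to the 182.5/365 annualisation.

One consequence of the two-regime density rule is worth knowing: additivity
over a partition of the facility set holds exactly only on cells containing
no facilities. A cell containing facilities of one subset ignores the other
subset's remote smoothing when the union is evaluated. The tests pin down
additivity on facility-free cells.

## Discrete 1–5 ranks

Each continuous layer is graded on a discrete scale from 1 (least concern)
to 5 (greatest). Skewed layers are first transformed — log for krill,
chlorophyll, ship traffic, and facility density; square root for positive
SST trends; pH decline magnitudes are ranked untransformed — then zeros and
outliers are omitted and four thresholds are placed at the interior points
of a five-way equipartition of the retained range, so each rank spans an
equal transformed interval. "Evenly spaced between the minimum and maximum"
could also be read as four points including the endpoints, but that would
leave ranks 1 and 5 attainable only at the exact extremes, so the
equipartition reading is used. Values exactly on a threshold take the
higher rank, consistent with the grid's half-open bins.

The outlier rule is the 1st/99th percentile of the transformed nonzero
values (configurable); omitted outliers are assigned rank 1 or 5, and zeros
always rank 1. For trend layers, cells with insignificant gradients — or
gradients in the unconcerning direction (cooling; pH increase) — are
assumed low risk and take rank 1; only significant gradients in the
direction of concern are graded on the fitted scale. If the eligible
gradients are all identical the degenerate cells take rank 5, being the
layer maximum.

## Composition

Rank layers combine by per-cell arithmetic means (`mean_rank()`), keeping
scores continuous in [1, 5]. Missingness is handled by the available-mean
rule: a cell missing in some inputs uses the mean of those present, so where
krill samples are lacking the biota score is defined entirely by the
chlorophyll. The six maps are

* **A** biota = mean(krill, chlorophyll);
* **C** abiotic = mean(SST trend rank, pH trend rank);
* **E** human activity = mean(ship, facility), masked to south of 60°S where
  ship data end — the mask propagates to everything downstream of E;
* **B** = mean(E, A), **D** = mean(E, C), **F** = mean(B, D).

On complete cells the nesting gives exactly F = E/2 + A/4 + C/4, which the
acceptance suite checks to 1e-12. Scores are not re-discretised for
composition; binning is left to export options. `hotspot_cells()` lists
cells at or above a score threshold in descending order.

## What the synthetic generator emulates

* **Facilities** (`gen_facilities()`): placement in a coastal latitude band
  with one engineered dense cluster (default near the Antarctic Peninsula at
  58°W, 64°S — the analogue of the real facility concentration there);
  log-normal peak populations (median 20, σ_log 1.2, integer-truncated,
  occasionally producing the rare very large station) in a
  year-round/seasonal mix.
* **Ship traffic** (`gen_ship_traffic()`): expected ship-days decay
  exponentially from facilities (scale 400 km) scaled by facility
  population, over a small uniform background; Poisson counts per type,
  cell, and year, restricted to south of 60°S.
* **Krill** (`gen_krill_samples()`): a coastal-enhanced true mean field with
  the engineered maximum in the cluster cell; samples zero-inflated
  (default 20%) log-normal around the cell truth, dated January–March.
* **Chlorophyll** (`gen_chl_raster()`): a smooth nearshore-high gradient
  with multiplicative log-normal noise at satellite resolution.
* **Environmental series** (`gen_env_series()`): base + linear trend +
  12-month sinusoid + AR(1) noise, daily (SST-like) or monthly (pH-like).
  Defaults: φ = 0.5, innovation σ = 0.05 °C for SST-like and 0.005 for
  pH-like series, SST trend magnitudes 0.003–0.012 °C yr⁻¹ of either sign,
  pH trends negative at 0.0005–0.003 yr⁻¹. The noise level is deliberately
  modest — small enough that gradient recovery is sharply testable on a
  40-year series, while still exercising the decomposition and inference
  machinery. Real Southern Ocean monthly SST anomalies are several times
  noisier, and recovery there is correspondingly less precise; the tests
  quantify the method under the stated regime, not under satellite-product
  noise.

All generators are pure functions of their parameters and a seed, restore
the caller's RNG state, and emit the same table/raster shapes the readers
consume.

The end-to-end fixture (`gen_input_bundle()`) co-locates the facility
cluster, the traffic maximum, and the krill maximum in one cell, so the
combined map has a known answer: that cell and its immediate neighbours
(`hotspot_region()` — the distance-smoothed activity fields spread the peak
into adjacent cells) should attain the map-F maximum. For this fixture the
abiotic series are generated with zero gradients and no noise
(`neutral_abiotic = TRUE`): the planted construct involves activity and
biota only, and a spatially random abiotic draw would otherwise act as an
arbitrary tiebreaker among high-activity, high-biota cells and decide the
maximum on grounds unrelated to what is planted. With the neutral abiotic
field every cell's trend is exactly zero and insignificant, the abiotic rank
layer is uniform, and the whole trend stack still runs.

## Problem sizes

The shipped defaults are desk-scale by design: the 40 × 15 grid with 112
facilities, 2000 krill samples, a 1/4° chlorophyll raster, and 20-year
monthly environmental series runs end to end in a few seconds on one CPU.
The heavier simulation-based checks in the test suite use 1000 replicate
type-I-error series, 500 coverage replicates, a full-grid noisy
gradient-recovery run over a 40-year span, and 50 seeded end-to-end runs.
The generator scales to finer chlorophyll resolution (1/12°) and daily SST
series unchanged.

## Known limitations

* The ranking outlier rule and the exact X11 variant are conventions chosen
  here (documented above, isolated behind configuration) — other choices
  change individual ranks, mostly near scale boundaries.
* Significance of the per-cell gradients inherits the optimism of fitting a
  smoothed component; treat the flags as the method defines them, not as
  calibrated field-wise inference (no multiplicity correction is applied,
  matching the per-cell definition).
* The synthetic ocean has no circulation, sea ice, bloom phenology, or
  transport of emissions; the maps locate potential sources, not sinks.
* Interannual averaging pools krill samples across years within cells; with
  strongly unbalanced sampling across decades, a cell's "interannual mean"
  is weighted toward its better-sampled years.
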