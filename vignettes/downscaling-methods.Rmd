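---
title: "Methods: debiasing, downscaling and bioclimatic derivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: debiasing, downscaling and bioclimatic derivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleodown)
```

`paleodown` implements the statistical machinery needed to turn coarse,
biased climate-model output — transient paleo simulations archived as
decadal means, or modern scenario runs archived as monthly values — into
fine-grid, observation-anchored monthly climate fields and the
bioclimatic summaries ecological models consume. This vignette explains
the methods, their assumptions, the tunable parameters, and the design
choices made where the methodology leaves genuine freedom. Every
empirical statement here is one the package's test suite computes.

## Change-factor debiasing

The core premise is that a climate model's *change* between two of its
own states is more trustworthy than its absolute values. For a variable
with no physical bounds (temperature, net longwave radiation) the model
anomaly against the model's own reference period is bilinearly
interpolated to the fine observational grid and added to the observed
climatology (`downscale_additive()`). Any time-constant model bias
cancels exactly: if the model shows no change, the output *is* the
observed climatology. For zero-bounded variables (vapour pressure, wind
speed) the same logic runs multiplicatively (`downscale_factor()`), which
preserves the zero bound.

Two design points worth noting:

* **Reference period.** For a paleo run the reference is the last 110
  years of the run; for scenario runs, the 1950–2005 historical
  climatology. Both are caller-configurable — they are conventions, not
  constants of nature.
* **Ratios at dry/calm cells.** A zero reference with a zero target
  yields factor 1 (no information); a zero reference with a nonzero
  target is capped (default 10). Precipitation never reaches this code
  path in the full pipeline because it is routed through quantile
  mapping, which handles exactly this pathology; the cap protects the
  vapour/wind edge cases only.
* **Coarse ocean cells.** Coarse cells with no model value still enter
  the bilinear stencil of nearby fine land cells. They are filled by
  nearest-valid-cell extension (`extend_nearest()`) before
  interpolation; this is a documented package choice, made because
  leaving them missing would punch holes in coastal output.

### Shortwave radiation

Much of the shortwave change across glacial cycles is orbital, not
model physics, and raw surface shortwave must respect
$0 \le S \le B$ where $B$ is the top-of-atmosphere insolation for the
epoch's orbit. Both constraints are honoured by working with the
normalized flux $\hat S = S/B$ and expressing change as a power law
$\hat S_{alt} = \hat S_0^{\,\gamma}$, with
$\gamma = \log \hat S_{alt} / \log \hat S_0$ computed on the coarse grid
(`shortwave_gamma()`), interpolated, and applied to the observed
$\hat S_0$ (`apply_gamma()`). Because $\hat S \in (0,1)$, $\gamma$ is
positive and the output automatically stays inside the orbit's allowed
range. Numerical guards: $\hat S$ is clamped to
$[10^{-6}, 1-10^{-6}]$ before logs, and cells with $B < 1$ W m⁻² are
treated as polar night ($S = 0$, $\gamma$ undefined). Upward shortwave
is normalized by the same downward $B$, so downscaled albedo is not
separately constrained.

## Quantile mapping for precipitation

Dry model cells show huge fractional changes; multiplying those onto a
wet observed cell is unphysical. Quantile mapping sidesteps the problem
by using the historical relationship between model variability and
observed variability. Observed and modelled baseline series at a coarse
cell (one calendar month at a time) are sorted independently; the
rank-paired points $(q_j, p_j)$ define a monotone map from model space
to observation space (`fit_empirical_qmap()`), evaluated with linear
interpolation inside the sample and linear extension of the end
segments outside it.

With decadal archives the baseline has only 11 points (the 1901–2011
convention), too few for a stable empirical map, so a least-squares
line $p = aq + b$ through the sorted pairs replaces it
(`fit_paleo_linear_qmap()`). When $b < 0$ the line crosses zero at
positive $q$; for $q_{alt} < q_1$ the map switches to the
origin-passing chord $p = q\,(a q_1 + b)/q_1$, continuous at $q_1$ and
positive for all positive $q$. Maps are fitted per cell and per
calendar month — pooling cells would mix climatologically distinct
distributions, and per-month fitting removes seasonal non-stationarity.
The mapped coarse precipitation is converted to change factors against
the coarse climatology and downscaled multiplicatively
(`qmap_to_fine()`); cells with zero coarse climatology get factor 1.

## Seasonal-to-monthly harmonization

Seasonal-only archives must be interpolated to months, but naive linear
interpolation of seasonal values damps the annual cycle and — worse —
produces months that do not average back to the seasons they came from.
The package instead solves a constrained smoothness problem: among all
12-vectors whose three-month means reproduce the four seasonal values
exactly (winter = Jan + Feb + Dec of the same cyclic climatological
year), choose the one minimizing the sum of squared cyclic second
differences. Lagrange multipliers reduce this to one linear
16×16 system (12 months + 4 multipliers), solved directly
(`s2m_additive()`). The flat solution (each month equal to its season)
is always feasible, so the optimum's roughness can never exceed it, and
re-aggregation reproduces the seasonal input to machine precision — the
tests assert residuals below 1e−10 and verify optimality against an
independent null-space quadratic-program solver.

For zero-bounded variables the monthly unknowns are change factors
$f_j$ weighted by the observed monthly climatology $P_j$, the seasonal
constraints become $\sum_j f_j P_j = F_s \sum_j P_j$ over each season's
months, and smoothness is imposed on $\log f$ so factors stay positive.
The stationarity conditions now form a 16-equation system, four of them
nonlinear (`s2m_factor()`). It is solved with a MINPACK
Levenberg–Marquardt root finder on the residual vector, initialized
from the flat solution $f_j = F_{s(j)}$ — which satisfies the
constraints exactly and is deterministic — with up to three rescaled
restarts (factors 0.9, 1.1, 0.75 on the log start) before reporting
failure with the offending cell. Constraint residuals are required
below 1e−8 relative; the tests cross-check the solution against an
augmented-Lagrangian minimizer to 1e−6. Months with zero climatology
weight drop out of their season's constraint and are set by smoothness
alone; each season must retain positive total weight.

Shortwave exponents are harmonized by applying the additive solver to
$\log \gamma$ and exponentiating (`s2m_gamma()`), which preserves
positivity and the seasonal means of $\log \gamma$.

## Secondary (bioclimatic) variables

### Growing degree days

Daily degree days are $\max(T - T_0, 0)$, but only monthly means are
available. Assuming daily temperature is normal with mean $\bar T$ and
standard deviation $\sigma$, the expectation has the closed form

$$\mathrm{GDD} = \frac{\sigma}{\sqrt{2\pi}}
  e^{-\frac{1}{2}\left(\frac{\bar T - T_0}{\sigma}\right)^2}
  + \frac{\bar T - T_0}{2}\,
  \mathrm{erfc}\!\left(\frac{T_0 - \bar T}{\sigma\sqrt 2}\right)$$

(`gdd_day_expectation()`). The naive estimator
$\max(\bar T - T_0, 0)$ is its $\sigma \to 0$ limit and, because the
hinge is convex, always an underestimate; the difference matters
precisely in the shoulder seasons, which is where growing-season
metrics are decided. Daily mean temperature is taken as
$(T_{max} + T_{min})/2$. The tests validate the closed form against a
$10^6$-draw Monte-Carlo oracle across $(\bar T - T_0)/\sigma \in
[-3, 3]$ and confirm on synthetic station series that it beats the
naive estimator in cool months.

The daily standard deviation is estimated from the interannual monthly
standard deviation through
$\sigma_{daily}^2 = a\, n\, \sigma_{monthly}^2 + \sigma_{annual}^2$
(`sigma_daily()`), where $a = 0.178$ is an empirical memory constant
(white noise would give $a = 1$; day-to-day autocorrelation makes the
effective value much smaller) and $\sigma_{annual}$ is the spread the
annual cycle itself contributes within a month. Modelling the daily
cycle as piecewise linear through the monthly means at month centres,
with half-month slopes $a_\pm$, the within-month variance about the
month's own mean works out analytically to

$$\sigma_{annual} = n_j\sqrt{\frac{5a_+^2 + 6a_+a_- + 5a_-^2}{192}}$$

(`sigma_annual()`); the tests verify this against a brute-force daily
construction (agreement within discretization error, under 2%). The
daily standard deviation is taken from modern data and held constant
across time — decadal paleo archives carry no daily information, so
this is an assumption, not an estimate.

### Evapotranspiration

Reference (potential) evapotranspiration uses the FAO-56
Penman–Monteith combination equation (`pet_penman_monteith()`) with the
radiation budget supplied directly from the downscaled fields: net
radiation is downward minus upward shortwave plus net longwave, so
albedo enters through the downscaled upward shortwave rather than a
prescribed constant — important over paleo ice and snow. Soil heat flux
is zero at monthly scale; surface pressure comes from elevation via the
standard barometric formula (`surface_pressure()`); negative computed
values are clipped to zero. Albedo implied by the radiation inputs is
bounded to [0.05, 0.95], with a warning when the upper clip engages.

Actual evapotranspiration uses a single-bucket soil water balance
(`aet_bucket()`, capacity 150 mm) with a snowpack: precipitation falls
as snow below 0 °C monthly mean and as rain above +3 °C, mixing
linearly between; melt is degree-day style at 2.5 mm °C⁻¹ day⁻¹. These
phase/melt constants are explicit package defaults, configurable per
call. Liquid supply meets demand first; unmet demand draws soil water
along the exponential extraction curve
$\Delta = soil\,(1 - e^{-deficit/capacity})$, which guarantees
AET ≤ PET and AET = 0 when no liquid water exists (ice-bound cells
evaporate nothing). The monthly balance
$P = AET + runoff + \Delta soil + \Delta snow$ closes to numerical
precision over arbitrary forcings — a property test, not a hope. Series
runs start at half capacity with 24 spin-up months discarded, removing
initial-condition sensitivity.

Derived indices: evapotranspiration ratio ETR = AET/PET (missing where
PET = 0) and water deficit index WDI = PET − precipitation
(`derive_etr_wdi()`).

### Top-of-atmosphere insolation

`toa_insolation()` computes monthly-mean TOA flux from latitude, month
and orbital elements (eccentricity, obliquity, longitude of perihelion)
using standard day-length/zenith geometry with Kepler-timed earth–sun
distance, averaged over sub-month quadrature points. The calendar is a
365.25-day year with the vernal equinox anchored at 20 March and
February carrying 28.25 days — decadal climatologies have no leap
structure, so months carry their long-run mean lengths. Present-day
elements are packaged; past elements are user input from an orbital
solution.

## Coastal extrapolation

Cells that were land under lower sea level but are ocean today have no
observational anchor. They are filled from present-land donors using an
east–west elliptical distance
$a = \sqrt{(1-w)d^2 + w(R|\Delta\phi|)^2}$ with $w = 0.75$ — climate
varies less along latitude circles than across them — where $d$ is the
great-circle distance on a 6371-km sphere. The search threshold starts
at $1.5\varepsilon$ ($\varepsilon$ = latitudinal grid spacing as a
distance) and grows by $\varepsilon$ until donors appear; donors are
averaged with weights $1/a$ (`fill_submerged()`). Filled values are
convex combinations of donors, present-land cells are never modified,
and cells already filled are not allowed to donate — extrapolating from
extrapolations would compound error. Paleoshoreline masks exist at 1 ka
steps; each decade maps to the temporally closest epoch, with exact
half-interval ages assigned to the older epoch as a fixed tie rule
(`shoreline_for_decade()`); decade midpoints never actually land on a
half-interval, so the rule only matters for direct calls.

## Summaries and output conventions

Window statistics follow a strict order: compute per member (one decade
or one year), then average members — not the other way around, which
would destroy the variability statistics. Paleo windows are 200 years
at 500-year centres (20 decadal members; the 0 ka window truncates at
the run's end), future windows are 20-year spans at 10-year steps after
a 1950–2005 historical climatology, deliberately overlapping by 10
years. Annual statistics are sums for water/energy totals (PRCP, GDD,
AET, PET, WDI) and averages for temperatures and ETR; variability is
the intra-annual standard deviation for temperature-scale variables and
the coefficient of variation for the rest (missing where the mean is
zero). "Quarterly" extremes use the fixed calendar seasons (DJF, MAM,
JJA, SON) — not running 3-month windows, a documented choice —
aggregated by sum or mean to match the variable's annual statistic.
Raster names follow the `<period>-<stat>-<VAR>` grammar with only the
meaningful combinations populated (minimum temperature has `qt-lwr` but
no `qt-hgr`; maximum temperature the reverse).

Archives pack values into 16-bit integers
(`unpacked = add_offset + packed × scale_factor`, sentinel −32768,
`pack_field()`/`choose_packing()`), written as classic-format NetCDF by
a purpose-built reader/writer (`nc_write()`/`nc_read()`) that any
standard NetCDF library can read. Summary rasters are written as TIFF
with a plain-text world file and a JSON value-scaling sidecar
(`write_raster_tiff()`), under the `model/time/name.tif` (paleo) or
`scenario/model/time/name.tif` (future) directory grammar.

## The fixture generator

`make_fixture()` builds the synthetic study system every test runs on:
a 10×7-cell coarse model grid at 2.5° nested in a 0.5° fine grid;
smooth two-harmonic annual cycles with spatial gradients for the eight
primary variables; a coarse model reference with deliberate constant
biases (+2 °C, ×1.25 precipitation) that change-factor debiasing must
cancel; an 11-decade precipitation baseline with 10% relative decadal
variability; a planted epoch (+3 °C anomaly, ×1.4 precipitation
factor, shortwave exponent 1.2) with 20 member decades of small
decadal noise; an ocean bay with an exposed paleo shelf; daily station
series with a known 4 °C daily standard deviation; and the truth values
needed to score recovery. Everything is deterministic under the
scenario seed.

What the generator does *not* emulate: realistic spatial covariance
beyond smooth random fields, model physics (no energy balance links
between variables), precipitation intermittency and extremes, or abrupt
intra-annual shifts. Passing tests therefore demonstrate that the
*machinery* is correct — bias cancellation, constraint satisfaction,
conservation, planted-signal recovery — not that any particular earth
system model is right about the past or future.

## Problem sizes and runtime

The test suite and acceptance checks run at desk scale by design: the
10×7 / 50×35 fixture grids, 100-instance solver sweeps, $10^6$-draw
Monte-Carlo comparisons, 240-month bucket forcings and a 20-member
end-to-end pipeline run complete in well under a minute together. The
same code paths scale to production grids (the reference North American
domain is 250×140 at 0.5°) because every kernel is either vectorized
over cells or a small fixed-size solve per cell.

## Known limitations

* Bilinear downscaling cannot reproduce gradients finer than the coarse
  grid; no topographic (lapse-rate) correction is applied.
* Monthly precipitation from seasonal archives cannot recover abrupt
  monsoon-type onsets — the smoothness prior actively resists them.
* The daily temperature distribution is assumed normal and its spread
  time-invariant; both fail in principle for strongly skewed or
  changing climates.
* Downscaling debiases each variable marginally; cross-variable
  correlation is inherited from the model, not corrected. The
  `crosscorr_monthly_anomalies()` utility exists to audit exactly this.
* Coastal extrapolation is a spatial average; submerged-cell climates
  carry higher, unquantified uncertainty.
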