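# paleodown

Ecological and biogeographic models increasingly span the whole arc
from the last deglaciation to the end of this century — but the climate
simulations they need come from earth system models whose output is
coarse, systematically biased, and archived inconsistently (decadal
means of seasonal values for long paleo runs, monthly values per year
for scenario runs). Feeding such output to a species-distribution or
diversity model without a *common* debiasing and downscaling treatment
confounds every past-vs-future comparison with model bias.

`paleodown` implements that treatment as a tested, reusable R package:

* **Change-factor debiasing + bilinear downscaling** against a fine
  observational climatology — additive for unbounded variables
  (`downscale_additive()`), multiplicative for zero-bounded ones
  (`downscale_factor()`), and a power-law transform
  $\hat S_{alt} = \hat S_0^{\,\gamma}$ for shortwave radiation
  normalized by top-of-atmosphere insolation
  (`shortwave_gamma()` / `apply_gamma()`), which keeps downscaled
  fluxes inside the range the epoch's orbit allows.
* **Quantile mapping** for precipitation: the classical sorted
  empirical map $p_j = f(q_j)$ for monthly archives
  (`fit_empirical_qmap()`), and a linear variant $p = aq + b$ fitted to
  the 11 sorted decadal pairs of a 1901–2011 baseline, with an
  origin-passing branch for $b < 0$, $q < q_1$ that guarantees
  $p > 0$ whenever $q > 0$ (`fit_paleo_linear_qmap()`).
* **Seasonal-to-monthly harmonization**: the smoothest annual cycle
  whose three-month means reproduce the seasonal values exactly —
  minimize $\sum_j (T_{j-1} - 2T_j + T_{j+1})^2$ subject to
  $T_1 + T_2 + T_{12} = 3S_1$ etc., a 16×16 Lagrange system
  (`s2m_additive()`); a log-space nonlinear analogue for zero-bounded
  variables (`s2m_factor()`).
* **Bioclimatic derivation**: growing degree days from monthly
  statistics via the truncated-normal expectation
  $\sigma\varphi(z) + (\bar T - T_0)\Phi(z)$ (`gdd_month()`), FAO-56
  Penman–Monteith reference evapotranspiration driven by the downscaled
  radiation budget (`pet_penman_monteith()`), a 150-mm single-bucket
  soil water balance with snow (`aet_bucket()`), and ETR / WDI moisture
  indices.
* **Coastal extrapolation** onto shelf cells exposed by lower sea
  level, by inverse-distance averaging inside a growing east–west
  ellipse (`fill_submerged()`).
* **Centennial/decadal summaries** (per-member-then-average, the
  `<period>-<stat>-<VAR>` raster grammar) and **packed-integer NetCDF /
  TIFF output** conventions.
* A **synthetic-fixture generator** (`make_fixture()`) that plants
  recoverable signals, so the entire pipeline is testable without
  multi-GB archives.

See `vignettes/downscaling-methods.Rmd` for the full methodological
account.

## Worked example

The reference production domain, and seasonal-to-monthly
harmonization of a single cell:

```r
library(paleodown)

make_grid(-173, -48, 10, 80, 0.5)
#> <pd_grid> 250x140 cells at 0.5 deg; lon [-173, -48], lat [10, 80]; 35000 land cells

S <- c(-8.4, 4.1, 17.9, 6.2)          # DJF, MAM, JJA, SON means
T <- s2m_additive(S)
round(T, 2)
#> -9.82 -8.26 -2.99  4.09 11.20 16.72 19.13 17.85 13.20  6.40 -0.99 -7.12
round(seasonal_from_monthly(T), 2)    # months average back exactly
#> -8.40  4.10 17.90  6.20
```

The winter months dip below the winter *mean* (−9.8 °C in January
against a −8.4 °C DJF mean): the solver restores the annual-cycle
amplitude that flat or linear interpolation would damp. Near the
growing-season margin the naive degree-day estimator reads zero while
the truncated-normal expectation does not:

```r
gdd_day_expectation(3, 4.5, 5)   # mean 3 degC, daily sd 4.5, base 5
#> 0.970                          # naive max(3 - 5, 0) = 0
```

End to end on a synthetic archive with planted signals (+3 °C epoch
anomaly, ×1.4 precipitation factor, 20 member decades):

```r
fx  <- make_fixture(fixture_scenario(seed = 42))
out <- run_pipeline(fx, "out-tree", mode = "paleo", model = "CCSM3-FIX")
#> recovered tmax anomaly: 3.00 (planted 3.0)
#> recovered prcp factor:  1.40 (planted 1.4)
length(out$files)
#> 52
```

The run writes 44 summary rasters (`an-sum-PRCP.tif`, `mo-lwr-TMIN.tif`,
… under `out-tree/CCSM3-FIX/0.5ka/`) and 8 packed NetCDF archives, one
per primary variable. A thin command-line wrapper with verbs
`make-fixtures`, `downscale`, `s2m`, `derive`, `fill-coast`,
`summarize` and `run` is installed at `inst/cli/paleodown`.

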