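# Saturation vapour pressure (kPa) at temperature T (degC), Magnus form
# used by the FAO-56 reference evapotranspiration standard.
esat_kpa <- function(T) {
  0.6108 * exp(17.27 * T / (T + 237.3))
}

#' Penman-Monteith reference evapotranspiration from monthly variables
#'
#' Reference-surface (grass) Penman-Monteith evapotranspiration in the
#' FAO-56 formulation, with the radiation budget supplied directly from
#' the downscaled fields instead of estimated from sunshine or
#' temperature: net radiation is downward minus upward shortwave plus net
#' downward longwave, so surface albedo enters through the downscaled
#' upward shortwave rather than a prescribed constant. Soil heat flux is
#' taken as zero at the monthly scale. Negative computed values are
#' clipped to zero (reference ET is non-negative by definition).
#'
#' @param Tmax,Tmin Monthly mean daily extreme temperatures, degC.
#' @param vap Vapour pressure, hPa.
#' @param wind Wind speed at reference height, m s-1.
#' @param sw_down,sw_up Downward/upward surface shortwave, W m-2.
#' @param lw_net Net downward longwave at the surface, W m-2 (usually
#'   negative).
#' @param pressure Surface air pressure, kPa.
#' @param n Days in the month.
#' @return Potential evapotranspiration, mm per month (>= 0). Upward
#'   shortwave exceeding `0.95 * sw_down` is clipped with a warning
#'   (albedo bounded to `[0.05, 0.95]`).
#' @export
pet_penman_monteith <- function(Tmax, Tmin, vap, wind, sw_down, sw_up,
                                lw_net, pressure, n = 30) {
  hi <- is.finite(sw_up) & is.finite(sw_down) & sw_up > 0.95 * sw_down
  lo <- is.finite(sw_up) & is.finite(sw_down) & sw_up < 0.05 * sw_down
  if (any(hi)) {
    warning("upward shortwave exceeds 0.95 * downward at ", sum(hi),
            " cell(s); albedo clipped")
    sw_up[hi] <- 0.95 * sw_down[hi]
  }
  sw_up[lo] <- 0.05 * sw_down[lo]
  T <- (Tmax + Tmin) / 2
  delta <- 4098 * esat_kpa(T) / (T + 237.3)^2
  gamma_psy <- 0.000665 * pressure
  es <- (esat_kpa(Tmax) + esat_kpa(Tmin)) / 2
  ea <- vap / 10  # hPa -> kPa
  deficit <- pmax(es - ea, 0)
  rn <- (sw_down - sw_up + lw_net) * 0.0864  # W m-2 -> MJ m-2 day-1
  et0 <- (0.408 * delta * rn +
            gamma_psy * 900 / (T + 273) * wind * deficit) /
    (delta + gamma_psy * (1 + 0.34 * wind))
  pmax(et0, 0) * n
}

#' Single-bucket soil water balance, one monthly step
#'
#' Tracks soil water (capacity 150 mm by default) and a snowpack.
#' Precipitation falls as snow below `snow_T_low` degC monthly mean, as
#' rain above `snow_T_high`, mixing linearly in between. Melt is
#' degree-day style, `melt_coef * max(T, 0) * n`, limited by the pack.
#' Liquid supply (rain + melt) meets demand first; unmet demand draws soil
#' water down along the standard exponential extraction curve
#' `soil * (1 - exp(-deficit / capacity))`; surplus refills the soil and
#' then runs off. With no liquid water the actual evapotranspiration is
#' zero, so ice-bound cells evaporate nothing.
#'
#' @param precip Monthly precipitation, mm (vectorized over cells).
#' @param pet Potential evapotranspiration for the month, mm.
#' @param T Monthly mean temperature, degC.
#' @param state List with `soil`, `snow`, `capacity` (mm); see
#'   [bucket_state()]. `soil` and `snow` may be vectors of cells.
#' @param n Days in the month.
#' @param melt_coef Degree-day melt coefficient, mm degC-1 day-1.
#' @param snow_T_low,snow_T_high Mixed-phase temperature bounds, degC.
#' @return List with `aet` (mm, `0 <= aet <= pet`), `state` (updated) and
#'   `runoff` (mm). The balance
#'   `precip = aet + runoff + d(soil) + d(snow)` closes to numerical
#'   precision.
#' @export
aet_bucket <- function(precip, pet, T, state, n = 30, melt_coef = 2.5,
                       snow_T_low = 0, snow_T_high = 3) {
  stopifnot(all(precip >= 0), all(pet >= 0), all(state$soil >= 0),
            all(state$soil <= state$capacity + 1e-9), all(state$snow >= 0))
  snow_frac <- pmin(pmax((snow_T_high - T) / (snow_T_high - snow_T_low),
                         0), 1)
  snowfall <- precip * snow_frac
  rain <- precip - snowfall
  pack <- state$snow + snowfall
  melt <- pmin(pack, melt_coef * pmax(T, 0) * n)
  supply <- rain + melt
  deficit <- pmax(pet - supply, 0)
  # exponential extraction: 1 - exp(-x) <= x and soil <= capacity together
  # guarantee draw <= deficit, hence aet <= pet
  draw <- state$soil * (1 - exp(-deficit / state$capacity))
  aet <- pmin(supply, pet) + draw
  surplus <- pmax(supply - pet, 0)
  soil_drawn <- state$soil - draw
  soil_new <- pmin(state$capacity, soil_drawn + surplus)
  runoff <- surplus - (soil_new - soil_drawn)
  list(aet = aet,
       state = bucket_state(soil = soil_new, snow = pack - melt,
                            capacity = state$capacity),
       runoff = runoff)
}

#' Construct a soil-bucket state
#'
#' @param soil Soil water, mm, in `[0, capacity]`.
#' @param snow Snowpack water equivalent, mm.
#' @param capacity Soil water holding capacity, mm (constant 150 in the
#'   reference configuration).
#' @return A `pd_bucket` list.
#' @export
bucket_state <- function(soil = 75, snow = 0, capacity = 150) {
  stopifnot(all(soil >= -1e-9), all(snow >= -1e-9), capacity > 0)
  structure(list(soil = pmax(soil, 0), snow = pmax(snow, 0),
                 capacity = capacity), class = "pd_bucket")
}

#' Run the soil bucket over a monthly series
#'
#' Starts from soil at half capacity and an empty snowpack, cycles the
#' forcing for a spin-up period that is discarded (removing
#' initial-condition sensitivity), then steps through the series.
#'
#' @param precip,pet,T Equal-length monthly forcing vectors (mm, mm, degC).
#' @param n_days Days per month, recycled to the series length.
#' @param capacity Soil capacity, mm.
#' @param spinup_months Months of discarded spin-up (forcing recycled).
#' @param ... Passed to [aet_bucket()].
#' @return List of vectors `aet`, `runoff`, `soil`, `snow`.
#' @export
run_bucket <- function(precip, pet, T, n_days = month_days(),
                       capacity = 150, spinup_months = 24, ...) {
  m <- length(precip)
  stopifnot(length(pet) == m, length(T) == m)
  nd <- rep_len(n_days, m)
  state <- bucket_state(soil = capacity / 2, snow = 0, capacity = capacity)
  if (spinup_months > 0) {
    idx <- rep_len(seq_len(m), spinup_months)
    for (k in idx) {
      state <- aet_bucket(precip[k], pet[k], T[k], state, n = nd[k],
                          ...)$state
    }
  }
  aet <- runoff <- soil <- snow <- numeric(m)
  for (k in seq_len(m)) {
    step <- aet_bucket(precip[k], pet[k], T[k], state, n = nd[k], ...)
    aet[k] <- step$aet; runoff[k] <- step$runoff
    state <- step$state
    soil[k] <- state$soil; snow[k] <- state$snow
  }
  list(aet = aet, runoff = runoff, soil = soil, snow = snow)
}

#' Run the soil bucket over a 12-month cycle for many cells at once
#'
#' Vectorized counterpart of [run_bucket()] for raster work: every row of
#' the forcing matrices is one cell, columns are the 12 calendar months.
#' The annual cycle is assumed periodic (decadal-mean forcing); spin-up
#' cycles the same 12 months and is discarded.
#'
#' @param precip,pet,T Matrices `n_cells x 12` (mm, mm, degC).
#' @param n_days Days per month (length 12).
#' @param capacity Soil capacity, mm.
#' @param spinup_months Discarded spin-up months.
#' @param ... Passed to [aet_bucket()].
#' @return List of `n_cells x 12` matrices `aet` and `runoff`.
#' @export
run_bucket_field <- function(precip, pet, T, n_days = month_days(),
                             capacity = 150, spinup_months = 24, ...) {
  stopifnot(ncol(precip) == 12, all(dim(pet) == dim(precip)),
            all(dim(T) == dim(precip)))
  nc <- nrow(precip)
  state <- bucket_state(soil = rep(capacity / 2, nc), snow = rep(0, nc),
                        capacity = capacity)
  for (k in rep_len(1:12, spinup_months)) {
    state <- aet_bucket(precip[, k], pet[, k], T[, k], state,
                        n = n_days[k], ...)$state
  }
  aet <- runoff <- matrix(0, nc, 12)
  for (k in 1:12) {
    step <- aet_bucket(precip[, k], pet[, k], T[, k], state,
                       n = n_days[k], ...)
    aet[, k] <- step$aet; runoff[, k] <- step$runoff
    state <- step$state
  }
  list(aet = aet, runoff = runoff)
}

#' Surface air pressure from elevation
#'
#' Standard-atmosphere barometric relation used by the FAO-56 guidelines:
#' `P = 101.3 ((293 - 0.0065 z) / 293)^5.26` kPa. Monotone decreasing in
#' elevation.
#'
#' @param elevation Elevation above sea level, m (>= -500).
#' @return Pressure, kPa.
#' @export
surface_pressure <- function(elevation) {
  if (any(elevation < -500)) stop("elevation below -500 m not supported")
  101.3 * ((293 - 0.0065 * elevation) / 293)^5.26
}
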