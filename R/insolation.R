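# Solve Kepler's equation M = E - e sin(E) for the eccentric anomaly by
# Newton iteration (e << 1 here so convergence is fast).
kepler_E <- function(M, e, tol = 1e-12) {
  E <- M
  for (k in 1:50) {
    dE <- (E - e * sin(E) - M) / (1 - e * cos(E))
    E <- E - dE
    if (max(abs(dE)) < tol) break
  }
  E
}

# True anomaly nu -> time since perihelion, in fractions of the orbital
# period (Kepler's equation applied in reverse).
time_from_perihelion <- function(nu, e) {
  E <- 2 * atan2(sqrt(1 - e) * sin(nu / 2), sqrt(1 + e) * cos(nu / 2))
  M <- E - e * sin(E)
  (M %% (2 * pi)) / (2 * pi)
}

# Solar longitude (radians from the vernal equinox) at a time expressed in
# fractions of a year since the vernal equinox.
solar_longitude <- function(t_frac, e, lon_perihelion_rad) {
  nu_eq <- -lon_perihelion_rad            # true anomaly at the equinox
  t_eq <- time_from_perihelion(nu_eq, e)  # perihelion -> equinox
  M <- 2 * pi * ((t_eq + t_frac) %% 1)
  E <- kepler_E(M, e)
  nu <- 2 * atan2(sqrt(1 + e) * sin(E / 2), sqrt(1 - e) * cos(E / 2))
  (nu + lon_perihelion_rad) %% (2 * pi)
}

# Daily-mean TOA insolation (W m-2) at latitude phi (rad) for solar
# longitude lambda (rad), given eccentricity and obliquity (rad).
daily_insolation <- function(phi, lambda, e, obliquity, lon_perihelion_rad,
                             S0 = 1361) {
  delta <- asin(sin(obliquity) * sin(lambda))
  nu <- lambda - lon_perihelion_rad
  rho <- (1 + e * cos(nu)) / (1 - e^2)    # inverse distance (AU^-1)
  cosH0 <- pmin(pmax(-tan(phi) * tan(delta), -1), 1)
  H0 <- acos(cosH0)
  S0 / pi * rho^2 * (H0 * sin(phi) * sin(delta) +
                       cos(phi) * cos(delta) * sin(H0))
}

#' Present-day orbital elements
#'
#' Eccentricity, obliquity (degrees) and true solar longitude of
#' perihelion (degrees from the vernal equinox). Past elements (e.g. for
#' 21 ka BP) are supplied by the user from an orbital solution.
#'
#' @return Named list `eccentricity`, `obliquity`, `lon_perihelion`.
#' @export
orbital_present <- function() {
  list(eccentricity = 0.0167, obliquity = 23.44, lon_perihelion = 282.95)
}

#' Monthly-mean top-of-atmosphere insolation
#'
#' Computes the downward solar flux at the top of the atmosphere as a
#' function of latitude, calendar month and orbital configuration, by
#' averaging the daily-mean insolation (standard day-length/zenith-angle
#' geometry with Kepler-timed earth-sun distance) over the days of the
#' month. Calendar months follow [month_days()] on a 365.25-day year,
#' anchored so the vernal equinox falls on 20 March. Polar-night months
#' return 0.
#'
#' @param lat Latitude in degrees (vectorized).
#' @param month Calendar month 1-12 (scalar).
#' @param orbital List with `eccentricity`, `obliquity` (deg),
#'   `lon_perihelion` (deg); defaults to [orbital_present()].
#' @param n_sub Sub-month quadrature points.
#' @param S0 Solar constant, W m-2.
#' @return Insolation in W m-2, same length as `lat`; always >= 0.
#' @export
toa_insolation <- function(lat, month, orbital = orbital_present(),
                           n_sub = 16, S0 = 1361) {
  stopifnot(length(month) == 1, month %in% 1:12)
  e <- orbital$eccentricity
  obl <- orbital$obliquity * pi / 180
  lp <- orbital$lon_perihelion * pi / 180
  nd <- month_days()
  year_len <- sum(nd)
  bounds <- c(0, cumsum(nd))
  equinox_day <- bounds[3] + 20  # 20 March in day-of-year terms
  mid <- bounds[month] + (seq_len(n_sub) - 0.5) / n_sub * nd[month]
  t_frac <- (mid - equinox_day) / year_len
  phi <- lat * pi / 180
  out <- numeric(length(lat))
  for (tf in t_frac) {
    lambda <- solar_longitude(tf, e, lp)
    out <- out + daily_insolation(phi, lambda, e, obl, lp, S0)
  }
  pmax(out / n_sub, 0)
}

#' Top-of-atmosphere insolation on a grid, all months
#'
#' @param grid A `pd_grid`.
#' @inheritParams toa_insolation
#' @return Array `n_lon x n_lat x 12` (constant along longitude).
#' @export
toa_insolation_field <- function(grid, orbital = orbital_present(),
                                 n_sub = 16) {
  out <- array(NA_real_, c(grid$n_lon, grid$n_lat, 12))
  for (m in 1:12) {
    row <- toa_insolation(grid$lat, m, orbital, n_sub)
    out[, , m] <- matrix(row, grid$n_lon, grid$n_lat, byrow = TRUE)
  }
  out
}
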