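#' Regular latitude-longitude raster geometry
#'
#' Constructs a cell-centre registered, regular lon/lat grid. Cell ownership
#' is half-open, `[edge, edge + resolution)`, and centres sit at
#' `edge + resolution/2`. Longitudes are signed degrees east; the reference
#' production domain for North America is `(-173, -48, 10, 80)` at 0.5
#' degrees, which yields a 250 x 140 grid.
#'
#' @param lon_min,lon_max,lat_min,lat_max Domain edges in degrees. Must be
#'   exact multiples of `resolution` apart.
#' @param resolution Grid spacing in degrees (same in both axes).
#' @param land_mask Optional logical matrix (`n_lon` x `n_lat`, longitude
#'   varying along rows) flagging land cells. Defaults to all-land.
#' @return An object of class `pd_grid` with cell counts, centre coordinate
#'   vectors (`lon`, `lat`) and the land mask.
#' @examples
#' g <- make_grid(-173, -48, 10, 80, 0.5)
#' c(g$n_lon, g$n_lat)  # 250 140
#' @export
make_grid <- function(lon_min, lon_max, lat_min, lat_max, resolution,
                      land_mask = NULL) {
  stopifnot(is.numeric(resolution), resolution > 0,
            lon_max > lon_min, lat_max > lat_min)
  n_lon <- (lon_max - lon_min) / resolution
  n_lat <- (lat_max - lat_min) / resolution
  if (abs(n_lon - round(n_lon)) > 1e-9)
    stop("longitude span ", lon_max - lon_min,
         " is not divisible by resolution ", resolution)
  if (abs(n_lat - round(n_lat)) > 1e-9)
    stop("latitude span ", lat_max - lat_min,
         " is not divisible by resolution ", resolution)
  n_lon <- as.integer(round(n_lon))
  n_lat <- as.integer(round(n_lat))
  if (is.null(land_mask)) {
    land_mask <- matrix(TRUE, n_lon, n_lat)
  } else {
    land_mask <- as.matrix(land_mask)
    storage.mode(land_mask) <- "logical"
    if (!all(dim(land_mask) == c(n_lon, n_lat)))
      stop("land_mask must be ", n_lon, " x ", n_lat)
  }
  structure(list(
    lon_min = lon_min, lon_max = lon_max,
    lat_min = lat_min, lat_max = lat_max,
    resolution = resolution,
    n_lon = n_lon, n_lat = n_lat,
    lon = lon_min + resolution * (seq_len(n_lon) - 0.5),
    lat = lat_min + resolution * (seq_len(n_lat) - 0.5),
    land_mask = land_mask
  ), class = "pd_grid")
}

#' @export
print.pd_grid <- function(x, ...) {
  cat("<pd_grid> ", x$n_lon, "x", x$n_lat, " cells at ", x$resolution,
      " deg; lon [", x$lon_min, ", ", x$lon_max, "], lat [",
      x$lat_min, ", ", x$lat_max, "]; ", sum(x$land_mask),
      " land cells\n", sep = "")
  invisible(x)
}

#' Variable downscaling semantics
#'
#' Couples a variable name with its units, physical bounds and the
#' debiasing arithmetic it requires: `additive` (differences; temperature,
#' net longwave), `factor` (ratios; zero-bounded variables such as
#' precipitation, vapour pressure, wind speed) or `gamma` (shortwave
#' radiation normalized by top-of-atmosphere insolation and transformed
#' through a power law).
#'
#' @param name Variable identifier.
#' @param units Unit string, e.g. `"degC"`, `"mm month-1"`, `"hPa"`,
#'   `"W m-2"`, `"m s-1"`, `"kPa"`, `"degC day"`.
#' @param kind One of `"additive"`, `"factor"`, `"gamma"`.
#' @param lower_bound,upper_bound Optional physical bounds. `factor`
#'   variables are forced to `lower_bound = 0`.
#' @return A `pd_varspec` list.
#' @export
variable_spec <- function(name, units, kind = c("additive", "factor", "gamma"),
                          lower_bound = NULL, upper_bound = NULL) {
  kind <- match.arg(kind)
  if (kind == "factor") lower_bound <- 0
  structure(list(name = name, units = units, kind = kind,
                 lower_bound = lower_bound, upper_bound = upper_bound),
            class = "pd_varspec")
}

#' Decade-index time convention
#'
#' Decade 0 spans 1 January 1951 to 31 December 1960; decade `d` spans
#' calendar years `1951 + 10 d` through `1960 + 10 d`. The long transient
#' paleo archives run from decade -2200 to +3 (ending 1990) or -2100 to -1
#' (ending 1950) depending on the source model.
#'
#' @param decade_index Integer decade index (vectorized).
#' @return A two-column matrix with `start_year` and `end_year`.
#' @examples
#' decade_to_years(0)   # 1951 1960
#' decade_to_years(3)   # 1981 1990
#' @export
decade_to_years <- function(decade_index) {
  if (any(decade_index != round(decade_index)))
    stop("decade_index must be integer-valued")
  cbind(start_year = 1951 + 10 * decade_index,
        end_year   = 1960 + 10 * decade_index)
}

#' Age of a decade in years before present (1950 AD)
#'
#' Uses the decade's midpoint (`1955.5 + 10 d` AD) and the radiocarbon
#' convention that present is 1950 AD.
#'
#' @param decade_index Integer decade index (vectorized).
#' @return Age in years BP (positive in the past).
#' @export
decade_age_bp <- function(decade_index) {
  1950 - (1955.5 + 10 * decade_index)
}

#' Days per calendar month
#'
#' Decadal climatologies have no leap-year structure, so February carries
#' 28.25 days; used wherever monthly values are day-weighted.
#'
#' @return Numeric vector of length 12.
#' @export
month_days <- function() {
  c(31, 28.25, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
}

# Season membership: 1 = DJF (months 12,1,2), 2 = MAM, 3 = JJA, 4 = SON.
# The annual cycle is treated as periodic, so winter is months {1,2,12} of
# the same climatological year.
season_months <- function() {
  list(c(1L, 2L, 12L), c(3L, 4L, 5L), c(6L, 7L, 8L), c(9L, 10L, 11L))
}

#' Season index of each calendar month
#'
#' @return Integer vector of length 12 mapping month to season (1 = DJF).
#' @export
season_of_month <- function() {
  s <- integer(12)
  for (k in 1:4) s[season_months()[[k]]] <- k
  s
}

#' Collapse monthly values to seasonal means
#'
#' Seasons are the unweighted mean of their three member months (DJF, MAM,
#' JJA, SON), with winter taken cyclically from the same climatological
#' year, so that e.g. `T1 + T2 + T12 = 3 S1`. Accepts a 12-vector or an
#' array whose last dimension has length 12.
#'
#' @param monthly Numeric 12-vector, or array with last dim 12.
#' @return 4-vector or array with last dim 4 (DJF, MAM, JJA, SON).
#' @export
seasonal_from_monthly <- function(monthly) {
  sm <- season_months()
  if (is.null(dim(monthly))) {
    stopifnot(length(monthly) == 12)
    return(vapply(sm, function(m) mean(monthly[m]), numeric(1)))
  }
  d <- dim(monthly)
  stopifnot(d[length(d)] == 12)
  m <- matrix(monthly, ncol = 12)
  out <- vapply(sm, function(idx) rowMeans(m[, idx, drop = FALSE]),
                numeric(nrow(m)))
  out <- matrix(out, ncol = 4)
  dim(out) <- c(d[-length(d)], 4)
  out
}
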