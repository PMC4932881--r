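# Mean earth radius (m) used for all great-circle arithmetic.
EARTH_RADIUS_M <- 6371000

#' Ellipse-weighted distance for coastal extrapolation
#'
#' Climate varies less along latitude circles than across them, so the
#' search neighbourhood for filling submerged cells is an east-west
#' ellipse rather than a circle:
#' `a = sqrt((1 - w) d^2 + w (R |dphi|)^2)`, where `d` is the great-circle
#' distance, `R` the earth radius and `dphi` the latitude difference in
#' radians. At `w = 0` it reduces to the great-circle distance; for pure
#' north-south pairs both terms collapse to `d`.
#'
#' @param p1,p2 Length-2 vectors or 2-column matrices of (lon, lat) in
#'   degrees.
#' @param w Ellipticity weight in `[0, 1)` (default 0.75).
#' @return Distance-like scalar(s) in metres; symmetric, zero iff equal
#'   points.
#' @export
elliptical_distance <- function(p1, p2, w = 0.75) {
  stopifnot(w >= 0, w < 1)
  d <- geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_M)
  lat1 <- if (is.matrix(p1)) p1[, 2] else p1[2]
  lat2 <- if (is.matrix(p2)) p2[, 2] else p2[2]
  dphi <- abs(lat2 - lat1) * pi / 180
  sqrt((1 - w) * d^2 + w * (EARTH_RADIUS_M * dphi)^2)
}

#' Fill formerly exposed (now submerged) cells by elliptical search
#'
#' Cells that were land under a paleo shoreline but are sea today have no
#' observational baseline; their climate is extrapolated from present-land
#' cells. The elliptical search radius starts at `1.5 eps` (with `eps` the
#' latitudinal grid spacing expressed as a distance) and grows by `eps`
#' until at least one donor falls inside; donors are then combined with
#' inverse-distance weights `1/a`. Present-land cells are never modified
#' and only cells with valid (finite) values can donate; filled values are
#' convex combinations of donor values.
#'
#' @param field Matrix on `grid` valid on present land.
#' @param grid A `pd_grid`.
#' @param present_land,past_land Logical matrices on `grid`.
#' @param w Ellipticity weight (see [elliptical_distance()]).
#' @return `field` with every past-land/present-sea cell filled.
#' @export
fill_submerged <- function(field, grid, present_land, past_land, w = 0.75) {
  stopifnot(all(dim(field) == c(grid$n_lon, grid$n_lat)),
            all(dim(present_land) == dim(field)),
            all(dim(past_land) == dim(field)))
  donors <- which(present_land & is.finite(field), arr.ind = TRUE)
  if (nrow(donors) == 0L) stop("no valid land cells to extrapolate from")
  targets <- which(past_land & !present_land, arr.ind = TRUE)
  if (nrow(targets) == 0L) return(field)
  donor_pts <- cbind(grid$lon[donors[, 1]], grid$lat[donors[, 2]])
  donor_vals <- field[donors]
  eps <- grid$resolution * pi / 180 * EARTH_RADIUS_M
  out <- field
  for (k in seq_len(nrow(targets))) {
    tp <- c(grid$lon[targets[k, 1]], grid$lat[targets[k, 2]])
    a <- elliptical_distance(donor_pts, matrix(tp, nrow = 1), w)
    a_max <- 1.5 * eps
    repeat {
      inside <- a <= a_max
      if (any(inside)) break
      a_max <- a_max + eps
    }
    wts <- 1 / a[inside]
    out[targets[k, 1], targets[k, 2]] <-
      sum(wts * donor_vals[inside]) / sum(wts)
  }
  out
}

#' Shoreline epoch for a decade
#'
#' Paleoshoreline reconstructions exist at 1 ka intervals; each decade is
#' assigned the temporally closest epoch (e.g. ages from 0.5 to 1.5 ka BP
#' map to the 1 ka shoreline). Exact half-interval ages are assigned to
#' the older epoch. Decades at or after 1950 AD map to the present (0 ka)
#' shoreline.
#'
#' @param decade_index Integer decade index (vectorized); see
#'   [decade_to_years()].
#' @return Shoreline epoch in ka BP (non-negative integers).
#' @export
shoreline_for_decade <- function(decade_index) {
  age_ka <- decade_age_bp(decade_index) / 1000
  epoch <- floor(age_ka + 0.5)  # x.5 rounds up = older epoch
  pmax(epoch, 0)
}
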