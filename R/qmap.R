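#' Empirical quantile map between model and observed precipitation
#'
#' Sorts the observed and modelled series independently (per coarse cell
#' and calendar month) and pairs them rank by rank: the monotone piecewise
#' linear function through `(q_j, p_j)` transforms the modelled sample
#' distribution into the observed one. Ties are kept in stable order.
#'
#' @param obs_series,model_series Equal-length non-negative series (e.g.
#'   100 Julys of observed and modelled precipitation at one cell).
#' @return A `pd_qmap` object with `mode = "empirical"`.
#' @export
fit_empirical_qmap <- function(obs_series, model_series) {
  if (length(obs_series) != length(model_series))
    stop("series must have equal length")
  if (length(obs_series) < 3) stop("need at least 3 values to fit a map")
  if (any(obs_series < 0) || any(model_series < 0))
    stop("precipitation series must be non-negative")
  structure(list(p = sort(obs_series, method = "radix"),
                 q = sort(model_series, method = "radix"),
                 mode = "empirical"),
            class = "pd_qmap")
}

# Piecewise-linear evaluation with linear extension of the end segments.
# Flat regions (tied knots) are skipped when choosing extension slopes.
pwlin_extrap <- function(x, xs, ys) {
  n <- length(xs)
  out <- stats::approx(xs, ys, xout = pmin(pmax(x, xs[1]), xs[n]),
                       ties = "ordered")$y
  lo <- x < xs[1]
  hi <- x > xs[n]
  if (any(lo)) {
    k <- which(xs > xs[1])[1]
    slope <- if (is.na(k)) 0 else (ys[k] - ys[1]) / (xs[k] - xs[1])
    out[lo] <- ys[1] + slope * (x[lo] - xs[1])
  }
  if (any(hi)) {
    k <- rev(which(xs < xs[n]))[1]
    slope <- if (is.na(k)) 0 else (ys[n] - ys[k]) / (xs[n] - xs[k])
    out[hi] <- ys[n] + slope * (x[hi] - xs[n])
  }
  out
}

#' Apply an empirical quantile map
#'
#' Evaluates the fitted map at new model values, linearly interpolating
#' between sample quantiles and linearly extending the end segments beyond
#' the observed model range. Results are floored at zero.
#'
#' @param map A `pd_qmap` with `mode = "empirical"`.
#' @param q_alt Model values to transform (non-negative).
#' @return Mapped values `p_alt >= 0`.
#' @export
apply_empirical_qmap <- function(map, q_alt) {
  stopifnot(inherits(map, "pd_qmap"), map$mode == "empirical")
  pmax(pwlin_extrap(q_alt, map$q, map$p), 0)
}

#' Linear quantile map for short decadal baselines
#'
#' With only 11 overlapping decades of observed and modelled baseline
#' precipitation, the rank-paired points are too few for a stable empirical
#' map, so a least-squares line `p = a q + b` is fitted through the sorted
#' pairs instead.
#'
#' @param p_decades,q_decades Sorted-or-not decadal series (sorted
#'   internally); typically 11 values from a 1901-2011 baseline.
#' @return A `pd_qmap` with `mode = "linear"`, slope `a`, intercept `b`
#'   and the smallest sorted model value `q1`.
#' @export
fit_paleo_linear_qmap <- function(p_decades, q_decades) {
  if (length(p_decades) != length(q_decades))
    stop("series must have equal length")
  if (length(p_decades) < 3) stop("need at least 3 decades")
  p <- sort(p_decades, method = "radix")
  q <- sort(q_decades, method = "radix")
  if (max(q) - min(q) < .Machine$double.eps * max(1, max(q)))
    stop("degenerate fit: all model values identical")
  fit <- stats::lm.fit(cbind(1, q), p)
  b <- unname(fit$coefficients[1])
  a <- unname(fit$coefficients[2])
  structure(list(p = p, q = q, a = a, b = b, q1 = q[1], mode = "linear"),
            class = "pd_qmap")
}

#' Apply the paleo linear quantile map with its dry-end rule
#'
#' Uses `p = a q + b` when `b >= 0` or `q_alt >= q1`. When `b < 0` and
#' `q_alt < q1` the line would cross zero at positive precipitation, so the
#' map switches to the origin-passing chord `p = q (a q1 + b) / q1`, which
#' is continuous with the line at `q1` and keeps `p > 0` whenever `q > 0`.
#'
#' @param map A `pd_qmap` with `mode = "linear"`.
#' @param q_alt Model values to transform (non-negative).
#' @return Mapped values, floored at zero.
#' @export
apply_paleo_linear_qmap <- function(map, q_alt) {
  stopifnot(inherits(map, "pd_qmap"), map$mode == "linear")
  out <- map$a * q_alt + map$b
  if (map$b < 0) {
    low <- q_alt < map$q1
    out[low] <- q_alt[low] * (map$a * map$q1 + map$b) / map$q1
  }
  pmax(out, 0)
}

#' @export
print.pd_qmap <- function(x, ...) {
  if (x$mode == "empirical") {
    cat("<pd_qmap> empirical,", length(x$q), "sample quantiles\n")
  } else {
    cat(sprintf("<pd_qmap> linear: p = %.4f q + %.4f (q1 = %.4f)\n",
                x$a, x$b, x$q1))
  }
  invisible(x)
}

#' Downscale quantile-mapped coarse precipitation to the fine grid
#'
#' The mapped coarse precipitation is normalized by the coarse observed
#' climatology, the resulting change factors are bilinearly interpolated,
#' and the fine observed climatology is multiplied by them. Cells with zero
#' coarse climatology get factor 1 (no information to rescale).
#'
#' @param p_alt_coarse Mapped coarse precipitation matrix.
#' @param coarse_clim Coarse observed climatology matrix (>= 0).
#' @param obs_fine Fine observed climatology matrix.
#' @param coarse_grid,fine_grid `pd_grid` objects.
#' @param max_factor Cap on change factors where the climatology is tiny.
#' @return Fine-grid precipitation, non-negative.
#' @export
qmap_to_fine <- function(p_alt_coarse, coarse_clim, obs_fine,
                         coarse_grid, fine_grid, max_factor = 10) {
  check_same_grid(p_alt_coarse, coarse_clim, "mapped field and climatology")
  fac <- p_alt_coarse / coarse_clim
  fac[coarse_clim == 0] <- 1
  fac[!is.finite(fac)] <- 1
  fac <- pmin(fac, max_factor)
  pmax(obs_fine * bilinear_regrid(fac, coarse_grid, fine_grid), 0)
}
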