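# Raster-name grammar for centennial/decadal summaries:
# <period>-<stat>-<VAR>, with period in {an, qt, mo}, stat in
# {avg, sum, sd, cv, lwr, hgr}. Only the populated combinations exist;
# e.g. minimum temperature has qt-lwr-TMIN but no qt-hgr-TMIN.
SUMMARY_VARS <- c("TMIN", "TMAX", "PRCP", "GDD", "AET", "PET", "ETR", "WDI")
SUM_TYPE <- c(TMIN = FALSE, TMAX = FALSE, PRCP = TRUE, GDD = TRUE,
              AET = TRUE, PET = TRUE, ETR = FALSE, WDI = TRUE)
CV_TYPE <- c(TMIN = FALSE, TMAX = FALSE, PRCP = TRUE, GDD = FALSE,
             AET = TRUE, PET = TRUE, ETR = TRUE, WDI = TRUE)

#' Valid summary-raster names for a variable
#'
#' @param var One of `TMIN, TMAX, PRCP, GDD, AET, PET, ETR, WDI`.
#' @return Character vector of statistic names for that variable.
#' @export
summary_names <- function(var) {
  var <- match.arg(var, SUMMARY_VARS)
  annual <- paste0("an-", if (SUM_TYPE[[var]]) "sum" else "avg", "-", var)
  variab <- paste0("an-", if (CV_TYPE[[var]]) "cv" else "sd", "-", var)
  ext <- switch(var,
    TMIN = c("qt-lwr", "mo-lwr"),
    TMAX = c("qt-hgr", "mo-hgr"),
    c("qt-lwr", "qt-hgr", "mo-lwr", "mo-hgr"))
  c(annual, variab, paste0(ext, "-", var))
}

#' Centennial/decadal summary windows
#'
#' Paleo mode: 200-year windows centred every 500 years from the start of
#' the run to 0 ka BP (1950 AD), each normally holding 20 decadal members;
#' the 0 ka window is truncated by the end of the run (1850-1990 for a run
#' ending at decade +3, 1850-1950 for one ending at decade -1). Future
#' mode: the 1950-2005 historical climatology followed by 20-year windows
#' at 10-year steps (2011-2030 ... 2081-2100); consecutive ladder windows
#' overlap by 10 years.
#'
#' @param mode `"paleo"` or `"future"`.
#' @param run_range For paleo, integer decade-index range of the run,
#'   e.g. `c(-2200, 3)`; ignored for future.
#' @return List of windows; paleo windows have `center_ka`, `label` and
#'   member `decades`, future windows have `start_year`, `end_year`,
#'   `label` and member `years`.
#' @export
build_windows <- function(mode = c("paleo", "future"),
                          run_range = c(-2200, 3)) {
  mode <- match.arg(mode)
  if (mode == "future") {
    starts <- c(1950, seq(2011, 2081, by = 10))
    ends <- c(2005, starts[-1] + 19)
    return(lapply(seq_along(starts), function(k) {
      list(start_year = starts[k], end_year = ends[k],
           label = if (k == 1) "1950-2005" else as.character(ends[k]),
           years = starts[k]:ends[k])
    }))
  }
  d_min <- run_range[1]; d_max <- run_range[2]
  oldest_ka <- ceiling(decade_age_bp(d_min) / 1000)
  centers <- seq(oldest_ka, 0, by = -0.5)
  out <- list()
  for (ka in centers) {
    cy <- 1950 - 1000 * ka
    dec <- seq(ceiling((cy - 99 - 1951) / 10), floor((cy + 100 - 1960) / 10))
    dec <- dec[dec >= d_min & dec <= d_max]
    if (length(dec) == 0L) {
      warning("window at ", ka, " ka has no member decades; excluded")
      next
    }
    out[[length(out) + 1L]] <- list(center_ka = ka,
                                    label = sprintf("%gka", ka),
                                    decades = dec)
  }
  out
}

# Per-member statistics from one member's 12 monthly values (vectorized
# over cells: x is a matrix n_cells x 12).
member_stats <- function(x, var) {
  sumtype <- SUM_TYPE[[var]]
  annual <- if (sumtype) rowSums(x) else rowMeans(x)
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / 11)
  variab <- if (CV_TYPE[[var]]) ifelse(mu == 0, NA_real_, sdv / abs(mu))
            else sdv
  sm <- season_months()
  qt <- vapply(sm, function(idx) {
    if (sumtype) rowSums(x[, idx, drop = FALSE])
    else rowMeans(x[, idx, drop = FALSE])
  }, numeric(nrow(x)))
  qt <- matrix(qt, ncol = 4)
  list(annual = annual, variab = variab,
       qt_lwr = apply(qt, 1, min), qt_hgr = apply(qt, 1, max),
       mo_lwr = apply(x, 1, min), mo_hgr = apply(x, 1, max))
}

#' Statistical summaries of a window of monthly members
#'
#' For each member (a decade's or a year's 12 monthly fields) the annual
#' statistic (sum for water/energy totals, average for temperatures and
#' ETR), the intra-annual variability (standard deviation for
#' temperature-scale variables, coefficient of variation for the rest),
#' and the lowest/highest monthly and quarterly values are computed;
#' member statistics are then averaged across the window. Quarters are
#' the fixed calendar seasons (DJF, MAM, JJA, SON), aggregated by sum or
#' mean to match the variable's annual statistic.
#'
#' @param members List of member arrays, each `n_lon x n_lat x 12` (or a
#'   12-vector for a single cell).
#' @param var Variable code (see [summary_names()]).
#' @return Named list of matrices (or scalars), one per summary name.
#' @export
summarize_window <- function(members, var) {
  var <- match.arg(var, SUMMARY_VARS)
  stopifnot(length(members) >= 1)
  single <- is.null(dim(members[[1]]))
  shape <- if (single) c(1, 1) else dim(members[[1]])[1:2]
  acc <- NULL
  for (m in members) {
    x <- if (single) matrix(m, 1, 12) else matrix(m, ncol = 12)
    st <- member_stats(x, var)
    if (is.null(acc)) acc <- lapply(st, function(v) v * 0)
    acc <- Map(`+`, acc, st)
  }
  acc <- lapply(acc, function(v) v / length(members))
  nm <- summary_names(var)
  out <- list()
  out[[nm[1]]] <- acc$annual
  out[[nm[2]]] <- acc$variab
  for (ext in nm[-(1:2)]) {
    key <- sub(paste0("-", var, "$"), "", ext)
    out[[ext]] <- switch(key,
      "qt-lwr" = acc$qt_lwr, "qt-hgr" = acc$qt_hgr,
      "mo-lwr" = acc$mo_lwr, "mo-hgr" = acc$mo_hgr)
  }
  lapply(out, function(v) {
    if (!single) dim(v) <- shape
    v
  })
}

#' Moisture indices from evapotranspiration and precipitation
#'
#' Evapotranspiration ratio `ETR = AET / PET` (in `[0, 1]` where PET is
#' positive, missing where PET is zero) and water deficit index
#' `WDI = PET - precipitation` (negative where precipitation exceeds
#' demand).
#'
#' @param aet,pet,precip Aligned monthly arrays, mm.
#' @return List with `etr` and `wdi` of the same shape.
#' @export
derive_etr_wdi <- function(aet, pet, precip) {
  stopifnot(all(dim(aet) == dim(pet)), all(dim(pet) == dim(precip)))
  etr <- aet / pet
  etr[pet == 0] <- NA_real_
  list(etr = etr, wdi = pet - precip)
}

#' Cross-correlation of monthly anomalies between two series
#'
#' Validation utility: per cell, removes each series' own mean annual
#' cycle and computes the Pearson correlation of the residual monthly
#' anomalies; used to check that downscaling preserves the covariance
#' structure between variables.
#'
#' @param series_a,series_b Arrays `n_lon x n_lat x T` with `T` a
#'   multiple of 12 and at least 24.
#' @return Correlation matrix in `[-1, 1]`, `NA` where a series has zero
#'   anomaly variance.
#' @export
crosscorr_monthly_anomalies <- function(series_a, series_b) {
  da <- dim(series_a)
  stopifnot(length(da) == 3, all(da == dim(series_b)),
            da[3] >= 24, da[3] %% 12 == 0)
  anom <- function(x) {
    n_yr <- dim(x)[3] / 12
    clim <- array(0, c(dim(x)[1:2], 12))
    for (m in 1:12)
      clim[, , m] <- apply(x[, , seq(m, by = 12, length.out = n_yr),
                             drop = FALSE], c(1, 2), mean)
    x - clim[, , rep(1:12, n_yr)]
  }
  a <- anom(series_a); b <- anom(series_b)
  out <- matrix(NA_real_, da[1], da[2])
  for (i in seq_len(da[1])) for (j in seq_len(da[2])) {
    va <- a[i, j, ]; vb <- b[i, j, ]
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) next
    out[i, j] <- stats::cor(va, vb)
  }
  out
}

#' Write a set of summary rasters under the archive directory grammar
#'
#' Paleo layout: `model/time/name.tif`; future layout:
#' `scenario/model/time/name.tif` (e.g.
#' `RCP4.5/ACCESS1-3/2100/mo-lwr-TMIN.tif`).
#'
#' @param stats Named list of matrices from [summarize_window()].
#' @param grid A `pd_grid`.
#' @param root Output root directory.
#' @param model Model name component.
#' @param time Time-period component (window label).
#' @param scenario Optional scenario component (future mode).
#' @return Character vector of files written.
#' @export
write_summary_tree <- function(stats, grid, root, model, time,
                               scenario = NULL) {
  parts <- if (is.null(scenario)) c(root, model, time)
           else c(root, scenario, model, time)
  dir <- do.call(file.path, as.list(parts))
  out <- character(0)
  for (nm in names(stats)) {
    p <- file.path(dir, paste0(nm, ".tif"))
    write_raster_tiff(stats[[nm]], grid, p)
    out <- c(out, p)
  }
  out
}
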