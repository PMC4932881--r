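# Synthetic fixtures: a coarse "climate model" archive nested in a fine
# "observational" grid with planted, recoverable signals, standing in for
# the CRU/GEWEX-style baselines and transient model archives at desk
# scale. Everything is deterministic under the scenario seed.

#' Fixture scenario description
#'
#' Defines the synthetic study conditions: a coarse model grid (10 x 7
#' cells at 2.5 degrees) nested in a fine 0.5-degree observational grid,
#' an 11-decade overlapping baseline (the 1901-2011 convention), planted
#' epoch signals (+3 degC temperature anomaly, precipitation change
#' factor 1.4, shortwave exponent 1.2), a 4 degC daily temperature
#' standard deviation for the station series, and 20 member decades per
#' centennial window.
#'
#' @param seed Integer seed; regeneration with the same seed is
#'   bit-identical.
#' @param coarse_nx,coarse_ny Coarse grid cell counts.
#' @param res_coarse,res_fine Grid spacings, degrees.
#' @param lon_min,lat_min Domain origin, degrees.
#' @param n_baseline_decades Overlapping baseline decades for quantile
#'   mapping.
#' @param temp_anomaly Planted epoch temperature anomaly, degC.
#' @param prcp_factor Planted epoch precipitation change factor.
#' @param gamma_true Planted shortwave exponent.
#' @param sigma_daily_true Daily temperature standard deviation for
#'   station series, degC.
#' @param n_member_decades Member decades per summary window.
#' @param decadal_rel_sd Relative decade-to-decade variability of
#'   precipitation.
#' @param station_years Years of daily station data.
#' @param seasonal_only Archive the paleo epoch as seasonal means only
#'   (emulates a model that did not store monthly output).
#' @return A `pd_scenario` list.
#' @export
fixture_scenario <- function(seed = 1L, coarse_nx = 10, coarse_ny = 7,
                             res_coarse = 2.5, res_fine = 0.5,
                             lon_min = -100, lat_min = 30,
                             n_baseline_decades = 11,
                             temp_anomaly = 3, prcp_factor = 1.4,
                             gamma_true = 1.2, sigma_daily_true = 4,
                             n_member_decades = 20, decadal_rel_sd = 0.1,
                             station_years = 10, seasonal_only = FALSE) {
  structure(as.list(environment()), class = "pd_scenario")
}

# Smooth random spatial field on a grid: a few low-order Fourier modes
# with random coefficients, scaled to unit-ish amplitude.
smooth_field <- function(grid, n_modes = 3, amp = 1) {
  lon01 <- (grid$lon - grid$lon_min) / (grid$lon_max - grid$lon_min)
  lat01 <- (grid$lat - grid$lat_min) / (grid$lat_max - grid$lat_min)
  out <- matrix(0, grid$n_lon, grid$n_lat)
  for (k in seq_len(n_modes)) {
    a <- stats::rnorm(4, sd = 1 / k)
    out <- out + outer(a[1] * sin(pi * k * lon01) + a[2] * cos(pi * k * lon01),
                       a[3] * sin(pi * k * lat01) + a[4] * cos(pi * k * lat01))
  }
  amp * out / max(abs(out))
}

# Two-harmonic annual cycle factory: returns a length-12 weight vector.
annual_cycle <- function(mean_val, amp1, phase1, amp2 = 0, phase2 = 0) {
  m <- 1:12
  mean_val + amp1 * cos(2 * pi * (m - phase1) / 12) +
    amp2 * cos(4 * pi * (m - phase2) / 12)
}

# Aggregate a fine field to the coarse grid by block averaging (the
# coarse/fine resolution ratio must be an integer).
#' Block-average a fine field onto a nested coarse grid
#'
#' @param field Matrix on `fine_grid`.
#' @param fine_grid,coarse_grid `pd_grid` objects with identical bounds
#'   and an integer resolution ratio.
#' @return Matrix on the coarse grid.
#' @export
aggregate_to_coarse <- function(field, fine_grid, coarse_grid) {
  r <- coarse_grid$resolution / fine_grid$resolution
  stopifnot(abs(r - round(r)) < 1e-9)
  r <- as.integer(round(r))
  out <- matrix(NA_real_, coarse_grid$n_lon, coarse_grid$n_lat)
  for (i in seq_len(coarse_grid$n_lon)) for (j in seq_len(coarse_grid$n_lat)) {
    out[i, j] <- mean(field[(i - 1) * r + 1:r, (j - 1) * r + 1:r],
                      na.rm = TRUE)
  }
  out
}

clim_to_coarse <- function(clim, fine_grid, coarse_grid) {
  out <- array(NA_real_, c(coarse_grid$n_lon, coarse_grid$n_lat, 12))
  for (m in 1:12)
    out[, , m] <- aggregate_to_coarse(clim[, , m], fine_grid, coarse_grid)
  out
}

#' Generate a synthetic fixture archive
#'
#' Produces, in memory: fine-grid monthly "observed" climatologies with
#' smooth two-harmonic annual cycles for the eight primary variables
#' (tmax, tmin, prcp, vap, wnd, swd, swu, lwn); a biased coarse model
#' reference climatology (the bias cancels under change-factor
#' debiasing, which is what end-to-end truth recovery tests exploit); an
#' 11-decade overlapping precipitation baseline for quantile mapping; a
#' paleo epoch with planted anomaly/factor/exponent signals and member
#' decades; land masks for the present and a paleo shoreline with exposed
#' shelf cells; an elevation field; daily station temperature series with
#' known daily standard deviation; and the truth values needed to score
#' every stage.
#'
#' @param scenario A `pd_scenario` from [fixture_scenario()].
#' @return A `pd_fixture` list (grids, climatologies, model archives,
#'   masks, stations, truth).
#' @export
make_fixture <- function(scenario = fixture_scenario()) {
  stopifnot(inherits(scenario, "pd_scenario"))
  set.seed(scenario$seed)
  sc <- scenario
  lon_max <- sc$lon_min + sc$coarse_nx * sc$res_coarse
  lat_max <- sc$lat_min + sc$coarse_ny * sc$res_coarse
  coarse <- make_grid(sc$lon_min, lon_max, sc$lat_min, lat_max,
                      sc$res_coarse)
  fine <- make_grid(sc$lon_min, lon_max, sc$lat_min, lat_max, sc$res_fine)

  # masks: an ocean bay in the southeast corner; the paleo shoreline
  # exposes the inner half of the bay as shelf
  lonm <- matrix(fine$lon, fine$n_lon, fine$n_lat)
  latm <- matrix(fine$lat, fine$n_lon, fine$n_lat, byrow = TRUE)
  ocean <- lonm > lon_max - 5 & latm < sc$lat_min + 5
  present_land <- !ocean
  shelf <- ocean & lonm <= lon_max - 2.5 & latm >= sc$lat_min + 2.5
  past_land <- present_land | shelf

  # fine observed climatologies
  B <- toa_insolation_field(fine)
  lat_dev <- latm - (sc$lat_min + lat_max) / 2
  tmax_sp <- 18 - 0.6 * lat_dev + smooth_field(fine, amp = 1.5)
  cyc_t <- annual_cycle(0, -12, 1)           # winter minimum in January
  prcp_sp <- 70 * exp(smooth_field(fine, amp = 0.6))
  cyc_p <- pmax(1 + 0.5 * cos(2 * pi * ((1:12) - 7) / 12), 0.2)
  vap_sp <- 12 + smooth_field(fine, amp = 2)
  wnd_sp <- 4 + smooth_field(fine, amp = 1)
  lwn_sp <- -60 + smooth_field(fine, amp = 8)
  shat0 <- pmin(pmax(0.55 + 0.06 * smooth_field(fine, amp = 1), 0.3), 0.8)
  albedo <- 0.2 + 0.03 * smooth_field(fine, amp = 1)

  mk <- function(spat, cyc) {
    out <- array(NA_real_, c(fine$n_lon, fine$n_lat, 12))
    for (m in 1:12) out[, , m] <- spat + cyc[m]
    out
  }
  obs <- list(
    tmax = mk(tmax_sp, cyc_t),
    tmin = mk(tmax_sp - 10, cyc_t),
    prcp = array(rep(prcp_sp, 12), c(dim(prcp_sp), 12)) *
      rep(cyc_p, each = length(prcp_sp)),
    vap = mk(vap_sp, annual_cycle(0, -3, 1)),
    wnd = mk(wnd_sp, annual_cycle(0, 0.5, 4)),
    lwn = mk(lwn_sp, annual_cycle(0, 10, 7)),
    swd = B * array(rep(shat0, 12), c(dim(shat0), 12)),
    swu = B * array(rep(shat0 * albedo, 12), c(dim(shat0), 12))
  )
  obs$prcp <- pmax(obs$prcp, 0.5)
  for (v in names(obs)) obs[[v]][array(ocean, dim(obs[[v]]))] <- NA_real_

  # coarse model reference climatology: obs aggregated + constant bias
  bias_add <- list(tmax = 2, tmin = 2, lwn = -5)
  bias_mul <- list(prcp = 1.25, vap = 1.1, wnd = 0.9)
  model_ref <- list()
  for (v in names(obs)) {
    cc <- clim_to_coarse(obs[[v]], fine, coarse)
    for (m in 1:12) cc[, , m] <- extend_nearest(cc[, , m], coarse)
    if (v %in% names(bias_add)) cc <- cc + bias_add[[v]]
    if (v %in% names(bias_mul)) cc <- cc * bias_mul[[v]]
    model_ref[[v]] <- cc
  }
  B_coarse <- toa_insolation_field(coarse)

  # paleo epoch: planted signals on the coarse model
  epoch <- list(
    tmax = model_ref$tmax + sc$temp_anomaly,
    tmin = model_ref$tmin + sc$temp_anomaly,
    lwn = model_ref$lwn - 5,
    prcp = model_ref$prcp * sc$prcp_factor,
    vap = model_ref$vap * 0.85,
    wnd = model_ref$wnd * 1.1,
    swd = B_coarse * (model_ref$swd / B_coarse)^sc$gamma_true,
    swu = B_coarse * (model_ref$swu / B_coarse)^sc$gamma_true
  )

  # member decades: epoch plus small decadal variability
  members <- vector("list", sc$n_member_decades)
  for (k in seq_len(sc$n_member_decades)) {
    mem <- list()
    for (v in names(epoch)) {
      d3 <- dim(epoch[[v]])
      if (v %in% c("tmax", "tmin", "lwn")) {
        mem[[v]] <- epoch[[v]] + stats::rnorm(1, sd = 0.3) +
          array(rep(smooth_field(coarse, amp = 0.2), 12), d3)
      } else {
        mem[[v]] <- epoch[[v]] *
          exp(stats::rnorm(1, sd = 0.04) +
                array(rep(smooth_field(coarse, amp = 0.03), 12), d3))
      }
    }
    members[[k]] <- mem
  }

  # 11-decade precipitation baseline, per coarse cell and month
  nd <- sc$n_baseline_decades
  obs_clim_coarse_prcp <- clim_to_coarse(obs$prcp, fine, coarse)
  for (m in 1:12)
    obs_clim_coarse_prcp[, , m] <- extend_nearest(obs_clim_coarse_prcp[, , m],
                                                  coarse)
  dims <- c(coarse$n_lon, coarse$n_lat, 12)
  base_obs <- array(NA_real_, c(dims, nd))
  base_mod <- array(NA_real_, c(dims, nd))
  for (d in seq_len(nd)) {
    zo <- pmax(1 + sc$decadal_rel_sd * stats::rnorm(prod(dims)), 0.2)
    zm <- pmax(1 + sc$decadal_rel_sd * stats::rnorm(prod(dims)), 0.2)
    base_obs[, , , d] <- obs_clim_coarse_prcp * array(zo, dims)
    base_mod[, , , d] <- model_ref$prcp * array(zm, dims)
  }

  # daily station series: smooth annual cycle plus normal weather noise
  # with known standard deviation; Tmax/Tmin straddle the mean by 4 degC
  n_days_year <- 365
  month_of_day <- rep(1:12, times = c(31, 28, 31, 30, 31, 30, 31, 31, 30,
                                      31, 30, 31))
  stations <- list()
  st_cells <- cbind(c(10, 25, 40), c(30, 20, 10))
  for (s in 1:3) {
    cyc <- obs$tmax[st_cells[s, 1], st_cells[s, 2], ] - 5
    if (anyNA(cyc)) cyc <- annual_cycle(12, -12, 1)
    day_cyc <- stats::approx(
      x = cumsum(c(0, rep(365 / 12, 12))) - 365 / 24,
      y = c(cyc[12], cyc), xout = seq_len(n_days_year) - 0.5,
      rule = 2)$y
    tm <- rep(day_cyc, sc$station_years) +
      stats::rnorm(n_days_year * sc$station_years,
                   sd = sc$sigma_daily_true)
    stations[[s]] <- data.frame(
      station = s,
      year = rep(seq_len(sc$station_years), each = n_days_year),
      month = rep(month_of_day, sc$station_years),
      tmax = tm + 4, tmin = tm - 4)
  }
  stations <- do.call(rbind, stations)

  elevation <- pmax(200 + 600 * smooth_field(fine, amp = 1), 0)

  # monthly-mean interannual standard deviation consistent with the
  # planted daily standard deviation: inverting the memory relation
  # sigma_daily^2 = a n sigma_monthly^2 + sigma_annual^2 at every cell
  nd_m <- month_days()
  tmean <- (obs$tmax + obs$tmin) / 2
  sig_mon <- array(NA_real_, dim(tmean))
  for (m in 1:12) {
    mp <- if (m == 1) 12 else m - 1
    mn <- if (m == 12) 1 else m + 1
    s_ann <- sigma_annual(tmean[, , mp], tmean[, , m], tmean[, , mn],
                          nd_m[mp], nd_m[m], nd_m[mn])
    sig_mon[, , m] <- sqrt(pmax(sc$sigma_daily_true^2 - s_ann^2, 0) /
                             (0.178 * nd_m[m]))
  }

  # 55-year interannual precipitation series (historical baseline for the
  # empirical quantile map used in future mode)
  n_hist <- 55
  dims_h <- c(coarse$n_lon, coarse$n_lat, 12)
  hist_obs_prcp <- array(NA_real_, c(dims_h, n_hist))
  hist_mod_prcp <- array(NA_real_, c(dims_h, n_hist))
  for (y in seq_len(n_hist)) {
    hist_obs_prcp[, , , y] <- obs_clim_coarse_prcp *
      array(stats::rlnorm(prod(dims_h), -0.03, 0.25), dims_h)
    hist_mod_prcp[, , , y] <- model_ref$prcp *
      array(stats::rlnorm(prod(dims_h), -0.03, 0.25), dims_h)
  }

  list(
    scenario = sc,
    coarse_grid = coarse, fine_grid = fine,
    present_land = present_land, past_land = past_land,
    obs_clim = obs,
    model_ref = model_ref,
    epoch = epoch,
    epoch_seasonal = if (sc$seasonal_only)
      lapply(epoch, seasonal_from_monthly) else NULL,
    members = members,
    baseline_obs = base_obs, baseline_mod = base_mod,
    hist_obs_prcp = hist_obs_prcp, hist_mod_prcp = hist_mod_prcp,
    obs_sigma_monthly = sig_mon,
    obs_clim_coarse_prcp = obs_clim_coarse_prcp,
    B_fine = B, B_coarse = B_coarse,
    elevation = elevation,
    stations = stations,
    truth = list(temp_anomaly = sc$temp_anomaly,
                 prcp_factor = sc$prcp_factor,
                 gamma = sc$gamma_true,
                 sigma_daily = sc$sigma_daily_true)
  )
}

#' Two correlated monthly anomaly series with a planted correlation
#'
#' Builds a pair of monthly series sharing a seasonal cycle whose
#' anomalies correlate at exactly the planted population value; used to
#' validate the cross-correlation utility against its sampling bounds.
#'
#' @param grid A `pd_grid`.
#' @param n_months Series length (multiple of 12).
#' @param rho Planted anomaly correlation.
#' @return List of two arrays `n_lon x n_lat x n_months`.
#' @export
make_correlated_series <- function(grid, n_months = 660, rho = 0.6) {
  stopifnot(n_months %% 12 == 0)
  d <- c(grid$n_lon, grid$n_lat, n_months)
  cyc <- array(rep(annual_cycle(10, -8, 1), each = prod(d[1:2])), d)
  e1 <- array(stats::rnorm(prod(d)), d)
  e2 <- array(stats::rnorm(prod(d)), d)
  list(a = cyc + e1,
       b = 0.5 * cyc + rho * e1 + sqrt(1 - rho^2) * e2)
}

#' Write a fixture archive to disk
#'
#' Serializes the fixture the way the production archives are laid out:
#' packed-integer NetCDF per variable for the observed climatology and
#' the model epoch, the station series as CSV, masks as NetCDF 0/1
#' fields, and the planted truths as JSON.
#'
#' @param fixture From [make_fixture()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fg <- fixture$fine_grid
  dims <- list(month = 12L, lat = fg$n_lat, lon = fg$n_lon)
  coord_vars <- list(
    lon = list(data = fg$lon, dims = "lon", type = "double",
               attrs = list(units = "degrees_east")),
    lat = list(data = fg$lat, dims = "lat", type = "double",
               attrs = list(units = "degrees_north")))
  for (v in names(fixture$obs_clim)) {
    spec <- choose_packing(fixture$obs_clim[[v]])
    packed <- pack_field(fixture$obs_clim[[v]], spec, v)
    vars <- c(coord_vars, stats::setNames(list(list(
      data = packed, dims = c("month", "lat", "lon"), type = "short",
      attrs = list(add_offset = spec$add_offset,
                   scale_factor = spec$scale_factor,
                   missing_value = structure(spec$fill, nc_short = TRUE)))),
      v))
    nc_write(file.path(dir, paste0("obs_", v, ".nc")), dims, vars)
  }
  mask_vars <- c(coord_vars, list(
    present_land = list(data = matrix(as.integer(fixture$present_land),
                                      fg$n_lon, fg$n_lat),
                        dims = c("lat", "lon"), type = "int"),
    past_land = list(data = matrix(as.integer(fixture$past_land),
                                   fg$n_lon, fg$n_lat),
                     dims = c("lat", "lon"), type = "int")))
  nc_write(file.path(dir, "masks.nc"),
           list(lat = fg$n_lat, lon = fg$n_lon), mask_vars)
  utils::write.csv(fixture$stations, file.path(dir, "stations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
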