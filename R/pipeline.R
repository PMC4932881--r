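# End-to-end pipeline driver: debias -> (seasonal-to-monthly) ->
# downscale -> derived variables -> coastal extrapolation (paleo) ->
# window summaries -> packed NetCDF + GeoTIFF-style tree.

ADDITIVE_VARS <- c("tmax", "tmin", "lwn")
FACTOR_VARS <- c("vap", "wnd")
GAMMA_VARS <- c("swd", "swu")

# Downscale one coarse member state to the fine grid. Returns a list of
# fine monthly arrays per variable.
downscale_member <- function(member, fx, variables, qmaps, seasonal) {
  cg <- fx$coarse_grid; fg <- fx$fine_grid
  out <- list()
  for (v in intersect(variables, ADDITIVE_VARS)) {
    if (seasonal) {
      s_anom <- seasonal_from_monthly(member[[v]]) -
        seasonal_from_monthly(fx$model_ref[[v]])
      anom <- s2m_field(s_anom, "additive")
    } else {
      anom <- member[[v]] - fx$model_ref[[v]]
    }
    f <- array(NA_real_, c(fg$n_lon, fg$n_lat, 12))
    for (m in 1:12)
      f[, , m] <- fx$obs_clim[[v]][, , m] +
        bilinear_regrid(anom[, , m], cg, fg)
    out[[v]] <- f
  }
  for (v in intersect(variables, FACTOR_VARS)) {
    if (seasonal) {
      Fs <- seasonal_from_monthly(member[[v]]) /
        seasonal_from_monthly(fx$model_ref[[v]])
      P_coarse <- fx$coarse_obs_clim[[v]]
      fac <- s2m_field(Fs, "factor", P_clim = P_coarse)
    } else {
      fac <- member[[v]] / fx$model_ref[[v]]
    }
    f <- array(NA_real_, c(fg$n_lon, fg$n_lat, 12))
    for (m in 1:12)
      f[, , m] <- pmax(fx$obs_clim[[v]][, , m] *
                         bilinear_regrid(fac[, , m], cg, fg), 0)
    out[[v]] <- f
  }
  if ("prcp" %in% variables) {
    f <- array(NA_real_, c(fg$n_lon, fg$n_lat, 12))
    for (m in 1:12) {
      p_alt <- matrix(NA_real_, cg$n_lon, cg$n_lat)
      for (i in seq_len(cg$n_lon)) for (j in seq_len(cg$n_lat)) {
        p_alt[i, j] <- apply_qmap_any(qmaps[[m]][[i, j]],
                                      member$prcp[i, j, m])
      }
      f[, , m] <- qmap_to_fine(p_alt, fx$obs_clim_coarse_prcp[, , m],
                               fx$obs_clim$prcp[, , m], cg, fg)
    }
    out$prcp <- f
  }
  for (v in intersect(variables, GAMMA_VARS)) {
    gam_c <- shortwave_gamma(member[[v]], fx$model_ref[[v]],
                             fx$B_coarse, fx$B_coarse)
    if (seasonal) {
      gam_seas <- array(NA_real_, c(cg$n_lon, cg$n_lat, 4))
      lg <- log(gam_c)
      for (s in 1:4) {
        idx <- season_months()[[s]]
        gam_seas[, , s] <- exp((lg[, , idx[1]] + lg[, , idx[2]] +
                                  lg[, , idx[3]]) / 3)
      }
      gam_c <- s2m_field(gam_seas, "gamma")
    }
    shat0_fine <- normalize_shortwave(fx$obs_clim[[v]], fx$B_fine)
    f <- array(NA_real_, c(fg$n_lon, fg$n_lat, 12))
    for (m in 1:12) {
      gmat <- gam_c[, , m]
      gmat[!is.finite(gmat) | gmat <= 0] <- 1   # polar-night / flagged
      gam_f <- bilinear_regrid(gmat, cg, fg)
      s0 <- shat0_fine[, , m]
      s0[!is.finite(s0)] <- 0.5
      f[, , m] <- apply_gamma(s0, pmax(gam_f, 1e-6), fx$B_fine[, , m])
    }
    out[[v]] <- f
  }
  out
}

apply_qmap_any <- function(map, q) {
  if (map$mode == "linear") apply_paleo_linear_qmap(map, q)
  else apply_empirical_qmap(map, q)
}

# Fit per-cell, per-month precipitation quantile maps.
fit_qmaps <- function(fx, mode) {
  cg <- fx$coarse_grid
  out <- vector("list", 12)
  for (m in 1:12) {
    maps <- vector("list", cg$n_lon * cg$n_lat)
    dim(maps) <- c(cg$n_lon, cg$n_lat)
    for (i in seq_len(cg$n_lon)) for (j in seq_len(cg$n_lat)) {
      maps[[i, j]] <- if (mode == "paleo") {
        fit_paleo_linear_qmap(fx$baseline_obs[i, j, m, ],
                              fx$baseline_mod[i, j, m, ])
      } else {
        fit_empirical_qmap(fx$hist_obs_prcp[i, j, m, ],
                           fx$hist_mod_prcp[i, j, m, ])
      }
    }
    out[[m]] <- maps
  }
  out
}

# Secondary variables on the fine grid from one member's primaries.
derive_member <- function(ds, fx, land) {
  fg <- fx$fine_grid
  nd <- month_days()
  cells <- which(land)
  n_cells <- length(cells)
  take <- function(arr) {
    m <- matrix(arr, ncol = 12)[cells, , drop = FALSE]
    m
  }
  tmax <- take(ds$tmax); tmin <- take(ds$tmin)
  tmean <- (tmax + tmin) / 2
  prcp <- take(ds$prcp)
  sig_mon <- take(fx$obs_sigma_monthly)
  gdd <- matrix(0, n_cells, 12)
  for (m in 1:12) {
    mp <- if (m == 1) 12 else m - 1
    mn <- if (m == 12) 1 else m + 1
    s_ann <- sigma_annual(tmean[, mp], tmean[, m], tmean[, mn],
                          nd[mp], nd[m], nd[mn])
    s_day <- sigma_daily(sig_mon[, m], nd[m], s_ann)
    gdd[, m] <- gdd_month(tmean[, m], s_day, T0 = 5, n = nd[m])
  }
  out <- list(GDD = gdd, TMIN = tmin, TMAX = tmax, PRCP = prcp)
  if (!is.null(ds$vap) && !is.null(ds$wnd)) {
    pres <- surface_pressure(fx$elevation[cells])
    pet <- matrix(0, n_cells, 12)
    vap <- take(ds$vap); wnd <- take(ds$wnd)
    swd <- take(ds$swd); swu <- take(ds$swu); lwn <- take(ds$lwn)
    for (m in 1:12) {
      pet[, m] <- pet_penman_monteith(tmax[, m], tmin[, m], vap[, m],
                                      wnd[, m], swd[, m], swu[, m],
                                      lwn[, m], pres, n = nd[m])
    }
    bw <- run_bucket_field(prcp, pet, tmean, nd)
    ew <- derive_etr_wdi(bw$aet, pet, prcp)
    out <- c(out, list(PET = pet, AET = bw$aet, ETR = ew$etr,
                       WDI = ew$wdi))
  }
  out
}

cells_to_field <- function(vals, cells, fg) {
  out <- matrix(NA_real_, fg$n_lon, fg$n_lat)
  out[cells] <- vals
  out
}

#' Run the full downscaling pipeline on a fixture archive
#'
#' Executes the workflow end to end: change-factor debiasing (additive,
#' factor and shortwave-exponent variables), quantile mapping for
#' precipitation (the linear decadal variant in paleo mode, the
#' empirical map in future mode), seasonal-to-monthly harmonization when
#' the archive is seasonal-only, bilinear downscaling to the fine grid,
#' derived bioclimatic variables, coastal extrapolation onto formerly
#' exposed shelf cells (paleo mode), window summaries, and output as
#' packed NetCDF plus a TIFF summary tree under the archive directory
#' grammar.
#'
#' When vapour pressure and wind speed are absent from the variable set
#' (as in archives that never stored them), the evapotranspiration-based
#' summaries (PET, AET, ETR, WDI) are skipped and the remaining
#' variables are still produced.
#'
#' @param fixture A `pd_fixture` from [make_fixture()].
#' @param out_root Output directory root.
#' @param mode `"paleo"` or `"future"`.
#' @param model Model name component of the output tree.
#' @param scenario Scenario component (future mode only), e.g.
#'   `"RCP4.5"`.
#' @param members Indices of member decades/years to process.
#' @param variables Primary variables available in the archive.
#' @param window_label Time component of the output tree.
#' @param verbose Log stage progress.
#' @return Invisibly, a list with the summary statistics, the fine-grid
#'   epoch-mean downscaled primaries and the files written.
#' @export
run_pipeline <- function(fixture, out_root,
                         mode = c("paleo", "future"),
                         model = "FIXTURE-ESM", scenario = NULL,
                         members = seq_along(fixture$members),
                         variables = c("tmax", "tmin", "prcp", "vap",
                                       "wnd", "swd", "swu", "lwn"),
                         window_label = if (mode == "paleo") "0.5ka"
                                        else "2030",
                         verbose = FALSE) {
  mode <- match.arg(mode)
  fx <- fixture
  fg <- fx$fine_grid
  say <- function(...) if (verbose) message("[", mode, "] ", ...)
  seasonal <- isTRUE(fx$scenario$seasonal_only) && mode == "paleo"

  # coarse observed climatologies for factor constraints
  fx$coarse_obs_clim <- list()
  for (v in intersect(variables, FACTOR_VARS)) {
    cc <- clim_to_coarse(fx$obs_clim[[v]], fx$fine_grid, fx$coarse_grid)
    for (m in 1:12) cc[, , m] <- extend_nearest(cc[, , m], fx$coarse_grid)
    fx$coarse_obs_clim[[v]] <- cc
  }

  say("fitting precipitation quantile maps")
  qmaps <- if ("prcp" %in% variables) fit_qmaps(fx, mode) else NULL

  land <- fx$present_land
  fill_land <- if (mode == "paleo") fx$past_land else fx$present_land
  cells <- which(fill_land)
  if (mode == "paleo") {
    # observational helper fields must also cover the exposed shelf
    for (m in 1:12)
      fx$obs_sigma_monthly[, , m] <- fill_submerged(
        fx$obs_sigma_monthly[, , m], fg, fx$present_land, fx$past_land)
    fx$elevation <- fill_submerged(fx$elevation, fg, fx$present_land,
                                   fx$past_land)
  }

  say("downscaling ", length(members), " member states")
  derived_members <- list()
  mean_primaries <- NULL
  for (k in members) {
    ds <- downscale_member(fx$members[[k]], fx, variables, qmaps, seasonal)
    if (mode == "paleo") {
      say("coastal extrapolation, member ", k)
      for (v in names(ds)) for (m in 1:12) {
        ds[[v]][, , m] <- fill_submerged(ds[[v]][, , m], fg,
                                         fx$present_land, fx$past_land)
      }
    }
    derived_members[[length(derived_members) + 1L]] <-
      derive_member(ds, fx, fill_land)
    if (is.null(mean_primaries)) {
      mean_primaries <- ds
    } else {
      for (v in names(ds)) mean_primaries[[v]] <- mean_primaries[[v]] +
          ds[[v]]
    }
  }
  for (v in names(mean_primaries))
    mean_primaries[[v]] <- mean_primaries[[v]] / length(members)

  say("window summaries")
  have_et <- !is.null(derived_members[[1]]$PET)
  sum_vars <- c("TMIN", "TMAX", "PRCP", "GDD",
                if (have_et) c("AET", "PET", "ETR", "WDI"))
  all_stats <- list()
  for (sv in sum_vars) {
    mem_list <- lapply(derived_members, function(dm) {
      arr <- array(NA_real_, c(fg$n_lon, fg$n_lat, 12))
      for (m in 1:12) arr[, , m] <- cells_to_field(dm[[sv]][, m], cells, fg)
      arr
    })
    all_stats <- c(all_stats, summarize_window(mem_list, sv))
  }

  files <- write_summary_tree(all_stats, fg, out_root, model,
                              window_label, scenario)

  say("writing packed NetCDF archives")
  nc_dir <- if (is.null(scenario)) file.path(out_root, model)
            else file.path(out_root, scenario, model)
  dir.create(nc_dir, recursive = TRUE, showWarnings = FALSE)
  dims <- list(month = 12L, lat = fg$n_lat, lon = fg$n_lon)
  coord_vars <- list(
    lon = list(data = fg$lon, dims = "lon", type = "double",
               attrs = list(units = "degrees_east")),
    lat = list(data = fg$lat, dims = "lat", type = "double",
               attrs = list(units = "degrees_north")))
  for (v in names(mean_primaries)) {
    spec <- choose_packing(mean_primaries[[v]])
    packed <- pack_field(mean_primaries[[v]], spec, v)
    path <- file.path(nc_dir, paste0(v, ".nc"))
    nc_write(path, dims, c(coord_vars, stats::setNames(list(list(
      data = packed, dims = c("month", "lat", "lon"), type = "short",
      attrs = list(add_offset = spec$add_offset,
                   scale_factor = spec$scale_factor,
                   missing_value = structure(spec$fill,
                                             nc_short = TRUE)))), v)))
    files <- c(files, path)
  }
  say("done: ", length(files), " files")
  invisible(list(stats = all_stats, primaries = mean_primaries,
                 files = files))
}

#' Read a pipeline configuration from YAML
#'
#' A single YAML file with fields `mode`, `seed`, `out_root`, `model`,
#' optional `scenario`, `members` (count), `variables` and
#' `window_label`; missing fields take the [run_pipeline()] defaults.
#'
#' @param path YAML file.
#' @return Named list of configuration values.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$mode), !is.null(cfg$out_root))
  cfg
}
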