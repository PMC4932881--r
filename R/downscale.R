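#' Bilinear regridding between cell-centre grids
#'
#' Interpolates a coarse field to the cell centres of a fine grid using the
#' four surrounding coarse cell centres. Reproduces any function linear in
#' lon and lat exactly and is monotone (each output lies within the range of
#' its four neighbours). Fine centres outside the coarse centre hull are
#' clamped to the nearest inside position when `extend = TRUE` (the
#' default), otherwise set to `NA`.
#'
#' @param coarse_field Matrix `n_lon` x `n_lat` on `coarse_grid`.
#' @param coarse_grid,fine_grid `pd_grid` objects.
#' @param extend Use nearest-inside extension at the domain edge.
#' @return Matrix on the fine grid.
#' @export
bilinear_regrid <- function(coarse_field, coarse_grid, fine_grid,
                            extend = TRUE) {
  stopifnot(inherits(coarse_grid, "pd_grid"), inherits(fine_grid, "pd_grid"))
  coarse_field <- as.matrix(coarse_field)
  if (!all(dim(coarse_field) == c(coarse_grid$n_lon, coarse_grid$n_lat)))
    stop("coarse_field dimensions do not match coarse_grid")
  xs <- coarse_grid$lon; ys <- coarse_grid$lat
  fx <- fine_grid$lon;   fy <- fine_grid$lat
  if (extend) {
    fx <- pmin(pmax(fx, xs[1]), xs[length(xs)])
    fy <- pmin(pmax(fy, ys[1]), ys[length(ys)])
  }
  ix <- findInterval(fx, xs, rightmost.closed = FALSE)
  iy <- findInterval(fy, ys, rightmost.closed = FALSE)
  out <- matrix(NA_real_, fine_grid$n_lon, fine_grid$n_lat)
  bad_x <- ix < 1L | fx > xs[length(xs)]
  bad_y <- iy < 1L | fy > ys[length(ys)]
  ix <- pmin(pmax(ix, 1L), length(xs) - 1L)
  iy <- pmin(pmax(iy, 1L), length(ys) - 1L)
  tx <- (fx - xs[ix]) / (xs[ix + 1L] - xs[ix])
  ty <- (fy - ys[iy]) / (ys[iy + 1L] - ys[iy])
  for (j in seq_along(fy)) {
    if (bad_y[j]) next
    v00 <- coarse_field[cbind(ix, iy[j])]
    v10 <- coarse_field[cbind(ix + 1L, iy[j])]
    v01 <- coarse_field[cbind(ix, iy[j] + 1L)]
    v11 <- coarse_field[cbind(ix + 1L, iy[j] + 1L)]
    v <- (1 - tx) * (1 - ty[j]) * v00 + tx * (1 - ty[j]) * v10 +
         (1 - tx) * ty[j] * v01 + tx * ty[j] * v11
    v[bad_x] <- NA_real_
    out[, j] <- v
  }
  out
}

#' Fill missing coarse cells from the nearest valid cell
#'
#' Coarse ocean-only cells next to coastlines carry no model value but
#' still enter the bilinear stencil of nearby fine land cells; they are
#' filled with the value of the nearest (in degrees, longitude/latitude
#' Euclidean) non-missing cell before interpolation.
#'
#' @param field Matrix with `NA` at invalid cells.
#' @param grid `pd_grid` the field lives on.
#' @return Matrix with all cells filled (error if no valid cell exists).
#' @export
extend_nearest <- function(field, grid) {
  field <- as.matrix(field)
  ok <- which(is.finite(field), arr.ind = TRUE)
  if (nrow(ok) == 0L) stop("no valid cells to extend from")
  bad <- which(!is.finite(field), arr.ind = TRUE)
  if (nrow(bad) == 0L) return(field)
  ok_lon <- grid$lon[ok[, 1]]; ok_lat <- grid$lat[ok[, 2]]
  vals <- field[ok]
  for (k in seq_len(nrow(bad))) {
    d2 <- (grid$lon[bad[k, 1]] - ok_lon)^2 + (grid$lat[bad[k, 2]] - ok_lat)^2
    field[bad[k, 1], bad[k, 2]] <- vals[which.min(d2)]
  }
  field
}

check_same_grid <- function(a, b, what = "model fields") {
  if (!all(dim(a) == dim(b)))
    stop("grid mismatch between ", what, ": ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
}

#' Change-factor downscaling, additive (difference) form
#'
#' The model anomaly `model_t - model_ref` is formed on the coarse grid,
#' bilinearly interpolated to the fine grid and added to the observed
#' climatology. Time-constant model bias cancels exactly: when
#' `model_t == model_ref` the output is the observed climatology.
#'
#' @param model_t,model_ref Coarse matrices (target state and reference
#'   state of the model).
#' @param obs Fine-grid observed climatology matrix.
#' @param coarse_grid,fine_grid `pd_grid` objects.
#' @return Fine-grid downscaled field.
#' @export
downscale_additive <- function(model_t, model_ref, obs, coarse_grid,
                               fine_grid) {
  check_same_grid(model_t, model_ref)
  anom <- bilinear_regrid(model_t - model_ref, coarse_grid, fine_grid)
  obs + anom
}

#' Change-factor downscaling, ratio (factor) form
#'
#' For zero-bounded variables (vapour pressure, wind speed): the ratio
#' `model_t / model_ref` is interpolated and multiplied onto the observed
#' climatology. Cells where both model values are zero get factor 1; a zero
#' reference with nonzero target is capped at `max_factor`.
#'
#' @inheritParams downscale_additive
#' @param max_factor Cap applied when the reference is (near) zero.
#' @return Fine-grid downscaled field, non-negative.
#' @export
downscale_factor <- function(model_t, model_ref, obs, coarse_grid, fine_grid,
                             max_factor = 10) {
  check_same_grid(model_t, model_ref)
  if (any(model_t < 0, na.rm = TRUE) || any(model_ref < 0, na.rm = TRUE))
    stop("factor-kind variables must be non-negative")
  ratio <- model_t / model_ref
  both_zero <- model_ref == 0 & model_t == 0
  ratio[both_zero] <- 1
  ratio[!is.finite(ratio) | ratio > max_factor] <- max_factor
  out <- obs * bilinear_regrid(ratio, coarse_grid, fine_grid)
  pmax(out, 0)
}

#' Normalize surface shortwave by top-of-atmosphere insolation
#'
#' `Shat = S / B`, clipped into `(0, 1)` so the power-law transform is
#' well defined. Cells with `B` below `b_min` (polar night) are flagged
#' `NA`.
#'
#' @param S Surface shortwave radiation, W m-2.
#' @param B Top-of-atmosphere downward insolation, W m-2.
#' @param clip Clamp interval half-width; values are forced into
#'   `[clip, 1 - clip]`.
#' @param b_min Insolation threshold below which a cell is polar night.
#' @return Normalized shortwave with `NA` where `B < b_min`.
#' @export
normalize_shortwave <- function(S, B, clip = 1e-6, b_min = 1) {
  shat <- S / B
  shat <- pmin(pmax(shat, clip), 1 - clip)
  shat[B < b_min] <- NA_real_
  shat
}

#' Power-law change factor for normalized shortwave
#'
#' Solves `Shat_alt = Shat_0 ^ gamma` for `gamma`:
#' `gamma = log(Shat_alt) / log(Shat_0)`. Because both arguments lie in
#' (0, 1), gamma is positive, and gamma = 1 wherever the model shows no
#' change; the transform guarantees the downscaled shortwave stays within
#' the range allowed by the orbital configuration.
#'
#' @param model_S_alt,model_S0 Coarse surface shortwave at the alternate
#'   and reference times, W m-2.
#' @param B_alt,B0 Matching top-of-atmosphere insolation fields.
#' @inheritParams normalize_shortwave
#' @return Matrix of exponents gamma (`NA` where polar night).
#' @export
shortwave_gamma <- function(model_S_alt, model_S0, B_alt, B0,
                            clip = 1e-6, b_min = 1) {
  s_alt <- normalize_shortwave(model_S_alt, B_alt, clip, b_min)
  s0 <- normalize_shortwave(model_S0, B0, clip, b_min)
  log(s_alt) / log(s0)
}

#' Apply a shortwave gamma field to the observed baseline
#'
#' `S_alt = B_alt * Shat_0 ^ gamma`. Polar-night cells (`B_alt < b_min` or
#' missing gamma) return 0.
#'
#' @param obs_Shat0 Fine-grid observed normalized shortwave, in (0, 1).
#' @param gamma_fine Fine-grid exponent field (positive).
#' @param B_alt Fine-grid top-of-atmosphere insolation at the target time.
#' @inheritParams normalize_shortwave
#' @return Shortwave radiation field, bounded by `[0, B_alt]`.
#' @export
apply_gamma <- function(obs_Shat0, gamma_fine, B_alt, b_min = 1) {
  if (any(gamma_fine <= 0, na.rm = TRUE))
    stop("gamma must be positive")
  out <- B_alt * obs_Shat0^gamma_fine
  out[!is.finite(out) | B_alt < b_min] <- 0
  out
}
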