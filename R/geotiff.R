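#' Write a summary raster as TIFF with georeferencing sidecars
#'
#' Writes a 32-bit TIFF image (north-up: first row is the northernmost
#' cells) together with a plain-text ESRI world file (`.tfw`) carrying the
#' affine geotransform and a JSON sidecar (`.tifmeta.json`) carrying the
#' value offset/scale used to map the data into the TIFF's [0, 1] sample
#' range. Sample value 0 is reserved for missing cells; data occupy
#' `[1/65535, 1]`. [read_raster_tiff()] inverts the mapping exactly (to
#' 32-bit float precision).
#'
#' @param field Matrix `n_lon x n_lat` on `grid` (latitude ascending along
#'   columns, as produced throughout the package).
#' @param grid A `pd_grid`.
#' @param path Output `.tif` path (directories created as needed).
#' @return `path`, invisibly.
#' @export
write_raster_tiff <- function(field, grid, path) {
  stopifnot(all(dim(field) == c(grid$n_lon, grid$n_lat)))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  img <- t(field)[rev(seq_len(grid$n_lat)), , drop = FALSE]  # north-up
  fin <- is.finite(img)
  if (!any(fin)) {
    off <- 0; sc <- 1
  } else {
    r <- range(img[fin])
    off <- r[1]
    sc <- max(r[2] - r[1], 1e-12)
  }
  lo <- 1 / 65535
  norm <- matrix(0, nrow(img), ncol(img))
  norm[fin] <- lo + (img[fin] - off) / sc * (1 - lo)
  tiff::writeTIFF(norm, path, bits.per.sample = 32L)
  res <- grid$resolution
  tfw <- c(res, 0, 0, -res, grid$lon[1], grid$lat[grid$n_lat])
  writeLines(format(tfw, digits = 15), sub("\\.tif$", ".tfw", path))
  jsonlite::write_json(
    list(value_offset = off, value_scale = sc, nodata_sample = 0,
         n_lon = grid$n_lon, n_lat = grid$n_lat),
    sub("\\.tif$", ".tifmeta.json", path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raster written by [write_raster_tiff()]
#'
#' @param path `.tif` path with its sidecars alongside.
#' @return Matrix `n_lon x n_lat`, latitude ascending, `NA` at missing
#'   cells.
#' @export
read_raster_tiff <- function(path) {
  meta <- jsonlite::read_json(sub("\\.tif$", ".tifmeta.json", path),
                              simplifyVector = TRUE)
  img <- tiff::readTIFF(path)
  lo <- 1 / 65535
  vals <- meta$value_offset + (img - lo) / (1 - lo) * meta$value_scale
  vals[img == 0] <- NA_real_
  t(vals[rev(seq_len(nrow(vals))), , drop = FALSE])
}
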