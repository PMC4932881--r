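#' Short-integer packing specification
#'
#' Downscaled archives store fields as 16-bit integers with the standard
#' attribute convention `unpacked = add_offset + packed * scale_factor`;
#' the missing-value sentinel is -32768 and is used only outside the
#' downscaling domain.
#'
#' @param add_offset,scale_factor Affine unpacking coefficients.
#' @param fill Integer sentinel for missing cells.
#' @return A `pd_packing` list.
#' @export
packing_spec <- function(add_offset, scale_factor, fill = -32768L) {
  stopifnot(is.finite(add_offset), is.finite(scale_factor),
            scale_factor > 0)
  structure(list(add_offset = add_offset, scale_factor = scale_factor,
                 fill = as.integer(fill)), class = "pd_packing")
}

#' Choose a packing specification for a field
#'
#' Deterministic midrange/span rule: the offset is the midpoint of the
#' finite value range and the scale spreads the range over 65000 integer
#' steps, leaving headroom inside the 16-bit range. A constant field gets
#' the floor scale `1e-6` and is recovered exactly.
#'
#' @param values Numeric array (NA allowed).
#' @return A `pd_packing`.
#' @export
choose_packing <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) == 0L) stop("no finite values to pack")
  r <- range(v)
  packing_spec(add_offset = mean(r),
               scale_factor = max((r[2] - r[1]) / 65000, 1e-6))
}

#' Pack a field into 16-bit integers
#'
#' `packed = round((value - add_offset) / scale_factor)`; missing cells
#' get the sentinel. Unpacking inverts within half a scale factor.
#'
#' @param values Numeric array.
#' @param spec A `pd_packing`.
#' @param name Variable name used in overflow error messages.
#' @return Integer array of the same shape.
#' @export
pack_field <- function(values, spec, name = "field") {
  stopifnot(inherits(spec, "pd_packing"))
  packed <- round((values - spec$add_offset) / spec$scale_factor)
  bad <- is.finite(packed) & abs(packed) > 32767
  if (any(bad))
    stop("packing overflow for variable '", name, "': ", sum(bad),
         " value(s) outside the 16-bit range")
  packed[!is.finite(values)] <- spec$fill
  out <- as.integer(packed)
  dim(out) <- dim(values)
  out
}

#' Unpack 16-bit integers to floating point
#'
#' @param packed Integer array from [pack_field()].
#' @param spec The `pd_packing` used to pack.
#' @return Numeric array with `NA` at sentinel cells.
#' @export
unpack_field <- function(packed, spec) {
  stopifnot(inherits(spec, "pd_packing"))
  out <- spec$add_offset + as.numeric(packed) * spec$scale_factor
  out[packed == spec$fill] <- NA_real_
  dim(out) <- dim(packed)
  out
}
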