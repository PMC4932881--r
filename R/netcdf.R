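# Lightweight reader/writer for the NetCDF-3 "classic" on-disk format
# (CDF-1), covering the subset the archives use: fixed-size dimensions,
# global and per-variable attributes, and variables of type short, int,
# float or double. All multi-byte values are big-endian; variable data
# follow the header in declaration order, padded to 4-byte boundaries.

NC_BYTE <- 1L; NC_CHAR <- 2L; NC_SHORT <- 3L
NC_INT <- 4L; NC_FLOAT <- 5L; NC_DOUBLE <- 6L

nc_type_of <- function(type) {
  switch(type, short = NC_SHORT, int = NC_INT, float = NC_FLOAT,
         double = NC_DOUBLE, char = NC_CHAR,
         stop("unsupported NetCDF type: ", type))
}

nc_type_size <- function(nct) {
  c(1L, 1L, 2L, 4L, 4L, 8L)[nct]
}

pad4 <- function(n) as.integer((4 - n %% 4) %% 4)

write_nc_name <- function(con, name) {
  raw_name <- charToRaw(name)
  writeBin(length(raw_name), con, size = 4, endian = "big")
  writeBin(raw_name, con)
  if (pad4(length(raw_name)) > 0)
    writeBin(raw(pad4(length(raw_name))), con)
}

write_nc_values <- function(con, values, nct) {
  if (nct == NC_CHAR) {
    raw_v <- charToRaw(values)
    writeBin(length(raw_v), con, size = 4, endian = "big")  # caller wrote it
    stop("internal: char values written via write_nc_attr")
  }
  size <- nc_type_size(nct)
  if (nct == NC_SHORT || nct == NC_INT) {
    writeBin(as.integer(values), con, size = size, endian = "big")
  } else {
    writeBin(as.numeric(values), con, size = size, endian = "big")
  }
  nbytes <- length(values) * size
  if (pad4(nbytes) > 0) writeBin(raw(pad4(nbytes)), con)
}

write_nc_attr <- function(con, name, value) {
  write_nc_name(con, name)
  if (is.character(value)) {
    raw_v <- charToRaw(value)
    writeBin(NC_CHAR, con, size = 4, endian = "big")
    writeBin(length(raw_v), con, size = 4, endian = "big")
    writeBin(raw_v, con)
    if (pad4(length(raw_v)) > 0) writeBin(raw(pad4(length(raw_v))), con)
  } else if (is.integer(value)) {
    nct <- if (identical(attr(value, "nc_short"), TRUE)) NC_SHORT else NC_INT
    writeBin(nct, con, size = 4, endian = "big")
    writeBin(length(value), con, size = 4, endian = "big")
    writeBin(as.vector(value), con, size = nc_type_size(nct), endian = "big")
    nb <- length(value) * nc_type_size(nct)
    if (pad4(nb) > 0) writeBin(raw(pad4(nb)), con)
  } else {
    writeBin(NC_DOUBLE, con, size = 4, endian = "big")
    writeBin(length(value), con, size = 4, endian = "big")
    writeBin(as.numeric(value), con, size = 8, endian = "big")
  }
}

attr_bytes <- function(value) {
  hdr <- function(name_len) 4L + name_len + pad4(name_len) + 8L
  if (is.character(value)) {
    n <- length(charToRaw(value)); n + pad4(n)
  } else if (is.integer(value)) {
    sz <- if (identical(attr(value, "nc_short"), TRUE)) 2L else 4L
    n <- length(value) * sz; n + pad4(n)
  } else {
    length(value) * 8L
  }
}

name_bytes <- function(name) {
  n <- nchar(name, type = "bytes")
  4L + n + pad4(n)
}

#' Write a NetCDF (classic format) file
#'
#' Writes fixed dimensions, global attributes, and data variables with
#' their attributes in NetCDF-3 classic layout, readable by any standard
#' NetCDF library. Packed archive variables should carry `add_offset`,
#' `scale_factor` and `missing_value` attributes (see [pack_field()]).
#'
#' @param path Output file.
#' @param dims Named list of dimension lengths, in declaration order.
#' @param vars Named list; each element a list with `data` (vector/array),
#'   `dims` (character vector of dimension names, slowest first; the last
#'   named dimension varies fastest on disk), `type` (`"short"`, `"int"`,
#'   `"float"`, `"double"`) and optional `attrs` (named list). R arrays are
#'   laid out column-major, so an array with R dims `(lon, lat, time)`
#'   should declare `dims = c("time", "lat", "lon")`.
#' @param global_attrs Named list of global attributes.
#' @return `path`, invisibly.
#' @export
nc_write <- function(path, dims, vars, global_attrs = list()) {
  stopifnot(length(dims) > 0, length(vars) > 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("CDF"), con)
  writeBin(as.raw(1L), con)                       # version byte: classic
  writeBin(0L, con, size = 4, endian = "big")     # numrecs

  # dim_list
  writeBin(10L, con, size = 4, endian = "big")    # NC_DIMENSION
  writeBin(length(dims), con, size = 4, endian = "big")
  for (nm in names(dims)) {
    write_nc_name(con, nm)
    writeBin(as.integer(dims[[nm]]), con, size = 4, endian = "big")
  }

  # global attributes
  if (length(global_attrs) > 0) {
    writeBin(12L, con, size = 4, endian = "big")  # NC_ATTRIBUTE
    writeBin(length(global_attrs), con, size = 4, endian = "big")
    for (nm in names(global_attrs)) write_nc_attr(con, nm, global_attrs[[nm]])
  } else {
    writeBin(c(0L, 0L), con, size = 4, endian = "big")
  }

  # pre-compute header size to assign data offsets
  header_bytes <- 4L + 4L                                  # magic + numrecs
  header_bytes <- header_bytes + 8L +
    sum(vapply(names(dims), function(nm) name_bytes(nm) + 4L, integer(1)))
  header_bytes <- header_bytes + 8L
  if (length(global_attrs) > 0)
    header_bytes <- header_bytes +
      sum(vapply(names(global_attrs), name_bytes, integer(1))) +
      sum(vapply(global_attrs, function(v) 8L + attr_bytes(v), integer(1)))
  header_bytes <- header_bytes + 8L                        # var_list tag
  vsizes <- integer(length(vars))
  for (k in seq_along(vars)) {
    v <- vars[[k]]
    nct <- nc_type_of(v$type)
    nelem <- prod(vapply(v$dims, function(d) dims[[d]], numeric(1)))
    vsizes[k] <- as.integer(nelem * nc_type_size(nct))
    vsizes[k] <- vsizes[k] + pad4(vsizes[k])
    header_bytes <- header_bytes + name_bytes(names(vars)[k]) +
      4L + 4L * length(v$dims) + 8L
    va <- v$attrs
    if (length(va) > 0)
      header_bytes <- header_bytes +
        sum(vapply(names(va), name_bytes, integer(1))) +
        sum(vapply(va, function(x) 8L + attr_bytes(x), integer(1)))
    header_bytes <- header_bytes + 4L + 4L + 4L  # nc_type, vsize, begin
  }
  begins <- header_bytes + c(0L, cumsum(vsizes))[seq_along(vars)]

  # var_list
  writeBin(11L, con, size = 4, endian = "big")    # NC_VARIABLE
  writeBin(length(vars), con, size = 4, endian = "big")
  dim_ids <- setNames(seq_along(dims) - 1L, names(dims))
  for (k in seq_along(vars)) {
    v <- vars[[k]]
    write_nc_name(con, names(vars)[k])
    writeBin(length(v$dims), con, size = 4, endian = "big")
    writeBin(unname(dim_ids[v$dims]), con, size = 4, endian = "big")
    va <- v$attrs
    if (length(va) > 0) {
      writeBin(12L, con, size = 4, endian = "big")
      writeBin(length(va), con, size = 4, endian = "big")
      for (nm in names(va)) write_nc_attr(con, nm, va[[nm]])
    } else {
      writeBin(c(0L, 0L), con, size = 4, endian = "big")
    }
    writeBin(nc_type_of(v$type), con, size = 4, endian = "big")
    writeBin(vsizes[k], con, size = 4, endian = "big")
    writeBin(begins[k], con, size = 4, endian = "big")
  }

  # data, declaration order
  for (k in seq_along(vars)) {
    v <- vars[[k]]
    write_nc_values(con, as.vector(v$data), nc_type_of(v$type))
  }
  invisible(path)
}

read_nc_name <- function(con) {
  n <- readBin(con, integer(), 1, size = 4, endian = "big")
  nm <- rawToChar(readBin(con, raw(), n))
  if (pad4(n) > 0) readBin(con, raw(), pad4(n))
  nm
}

read_nc_values <- function(con, nct, nelem) {
  size <- nc_type_size(nct)
  out <- if (nct %in% c(NC_SHORT, NC_INT)) {
    readBin(con, integer(), nelem, size = size, endian = "big")
  } else if (nct %in% c(NC_FLOAT, NC_DOUBLE)) {
    readBin(con, numeric(), nelem, size = size, endian = "big")
  } else if (nct == NC_CHAR) {
    rawToChar(readBin(con, raw(), nelem))
  } else stop("unsupported type id ", nct)
  nb <- nelem * size
  if (pad4(nb) > 0) readBin(con, raw(), pad4(nb))
  out
}

read_nc_attrs <- function(con) {
  tag <- readBin(con, integer(), 1, size = 4, endian = "big")
  count <- readBin(con, integer(), 1, size = 4, endian = "big")
  if (tag == 0L) return(list())
  out <- list()
  for (k in seq_len(count)) {
    nm <- read_nc_name(con)
    nct <- readBin(con, integer(), 1, size = 4, endian = "big")
    nelem <- readBin(con, integer(), 1, size = 4, endian = "big")
    out[[nm]] <- read_nc_values(con, nct, nelem)
  }
  out
}

#' Read a NetCDF (classic format) file
#'
#' Counterpart to [nc_write()]. Data are returned raw (packed); use
#' [unpack_field()] with the variable's `add_offset` / `scale_factor`
#' attributes, or set `unpack = TRUE` to apply them automatically.
#'
#' @param path File to read.
#' @param unpack Apply packing attributes (`add_offset`, `scale_factor`,
#'   `missing_value`) when present.
#' @return List with `dims`, `global_attrs` and `vars`; each variable has
#'   `data` (array with R dims in fastest-first order), `dims`, `attrs`.
#' @export
nc_read <- function(path, unpack = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), 4)
  if (!identical(rawToChar(magic[1:3]), "CDF"))
    stop(path, " is not a NetCDF classic file")
  readBin(con, integer(), 1, size = 4, endian = "big")  # numrecs
  tag <- readBin(con, integer(), 1, size = 4, endian = "big")
  ndims <- readBin(con, integer(), 1, size = 4, endian = "big")
  dims <- list()
  if (tag != 0L) {
    for (k in seq_len(ndims)) {
      nm <- read_nc_name(con)
      dims[[nm]] <- readBin(con, integer(), 1, size = 4, endian = "big")
    }
  }
  global_attrs <- read_nc_attrs(con)
  tag <- readBin(con, integer(), 1, size = 4, endian = "big")
  nvars <- readBin(con, integer(), 1, size = 4, endian = "big")
  vars <- list()
  meta <- list()
  if (tag != 0L) {
    for (k in seq_len(nvars)) {
      nm <- read_nc_name(con)
      nd <- readBin(con, integer(), 1, size = 4, endian = "big")
      dimids <- readBin(con, integer(), nd, size = 4, endian = "big")
      attrs <- read_nc_attrs(con)
      nct <- readBin(con, integer(), 1, size = 4, endian = "big")
      readBin(con, integer(), 1, size = 4, endian = "big")  # vsize
      begin <- readBin(con, integer(), 1, size = 4, endian = "big")
      meta[[nm]] <- list(dimids = dimids, attrs = attrs, nct = nct,
                         begin = begin)
    }
  }
  for (nm in names(meta)) {
    m <- meta[[nm]]
    seek(con, m$begin)
    dnames <- names(dims)[m$dimids + 1L]
    nelem <- prod(unlist(dims[dnames]))
    data <- read_nc_values(con, m$nct, nelem)
    if (length(dnames) > 1)
      dim(data) <- rev(unlist(dims[dnames]))  # fastest dim first in R
    attrs <- m$attrs
    if (unpack && !is.null(attrs$scale_factor)) {
      fill <- if (!is.null(attrs$missing_value)) attrs$missing_value else NA
      spec <- packing_spec(
        add_offset = if (is.null(attrs$add_offset)) 0 else attrs$add_offset,
        scale_factor = attrs$scale_factor,
        fill = if (is.na(fill)) -32768L else fill)
      data <- unpack_field(data, spec)
    }
    vars[[nm]] <- list(data = data, dims = rev(dnames), attrs = attrs)
  }
  list(dims = dims, global_attrs = global_attrs, vars = vars)
}
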