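# Minimal MATLAB MAT-file (v5) reader/writer for numeric arrays, sufficient
# for hyperspectral exports (intensity matrix + wavenumber vector). Supports
# little- and big-endian files, small-data-element tags and zlib-compressed
# elements on read; writes uncompressed little-endian double arrays.

.MI_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 2L, `5` = 4L,
                   `6` = 4L, `7` = 4L, `9` = 8L)

.read_mi_data <- function(buf, type, n, endian) {
  sz <- .MI_TYPE_SIZE[as.character(type)]
  if (is.na(sz)) stop(sprintf("unsupported MAT data type %d", type), call. = FALSE)
  con <- rawConnection(buf)
  on.exit(close(con))
  if (type %in% c(7L, 9L)) {
    readBin(con, "double", n = n, size = sz, endian = endian)
  } else if (type %in% c(1L, 3L, 5L)) {
    as.numeric(readBin(con, "integer", n = n, size = sz, signed = TRUE,
                       endian = endian))
  } else if (type %in% c(2L, 4L)) {
    as.numeric(readBin(con, "integer", n = n, size = sz, signed = FALSE,
                       endian = endian))
  } else { # miUINT32: read signed, fold negatives back
    v <- readBin(con, "integer", n = n, size = 4L, endian = endian)
    v <- as.numeric(v)
    v[v < 0] <- v[v < 0] + 2^32
    v
  }
}

.read_uint32 <- function(buf, pos, endian) {
  v <- readBin(buf[pos:(pos + 3L)], "integer", size = 4L, endian = endian)
  if (v < 0) v + 2^32 else v
}

# Returns list(type, nbytes, data_start, next_pos) for the element at pos
# (1-based), handling the packed small-data-element format.
.read_tag <- function(buf, pos, endian) {
  w <- .read_uint32(buf, pos, endian)
  small <- w %/% 65536
  if (small > 0) {
    list(type = w %% 65536, nbytes = small, data_start = pos + 4L,
         next_pos = pos + 8L)
  } else {
    nbytes <- .read_uint32(buf, pos + 4L, endian)
    payload <- nbytes
    pad <- if (w == 15L) 0L else (8L - payload %% 8L) %% 8L
    list(type = w, nbytes = nbytes, data_start = pos + 8L,
         next_pos = pos + 8L + payload + pad)
  }
}

.parse_matrix_element <- function(buf, endian) {
  pos <- 1L
  # array flags
  tg <- .read_tag(buf, pos, endian)
  flags <- .read_uint32(buf, tg$data_start, endian)
  class_id <- flags %% 256
  pos <- tg$next_pos
  # dimensions
  tg <- .read_tag(buf, pos, endian)
  nd <- tg$nbytes %/% 4L
  dims <- .read_mi_data(buf[tg$data_start:(tg$data_start + tg$nbytes - 1L)],
                        5L, nd, endian)
  pos <- tg$next_pos
  # name
  tg <- .read_tag(buf, pos, endian)
  nm <- if (tg$nbytes > 0) {
    rawToChar(buf[tg$data_start:(tg$data_start + tg$nbytes - 1L)])
  } else ""
  pos <- tg$next_pos
  if (!class_id %in% 6:13) {
    return(list(name = nm, value = NULL)) # non-numeric class: name only
  }
  # real part
  tg <- .read_tag(buf, pos, endian)
  sz <- .MI_TYPE_SIZE[as.character(tg$type)]
  n <- tg$nbytes %/% sz
  vals <- .read_mi_data(buf[tg$data_start:(tg$data_start + tg$nbytes - 1L)],
                        tg$type, n, endian)
  if (prod(dims) != n) {
    stop(sprintf("corrupt MAT variable '%s': %d values for dims [%s]",
                 nm, n, paste(dims, collapse = ",")), call. = FALSE)
  }
  dim(vals) <- as.integer(dims)
  list(name = nm, value = vals)
}

#' Read numeric variables from a MATLAB MAT-file (v5)
#'
#' Parses the level-5 MAT format directly; numeric array variables (including
#' zlib-compressed elements) are returned, other classes are listed by name
#' with a `NULL` value.
#'
#' @param path Path to a v5 MAT-file.
#' @return Named list of numeric arrays (MATLAB column-major dims preserved).
#' @export
read_matfile <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 128L) stop("not a v5 MAT-file (truncated header)", call. = FALSE)
  ind <- rawToChar(buf[127:128])
  endian <- if (ind == "IM") "little" else if (ind == "MI") "big" else {
    stop("not a v5 MAT-file (bad endian indicator)", call. = FALSE)
  }
  out <- list()
  pos <- 129L
  while (pos + 7L <= length(buf)) {
    tg <- .read_tag(buf, pos, endian)
    payload <- buf[tg$data_start:(tg$data_start + tg$nbytes - 1L)]
    if (tg$type == 15L) { # compressed element: decompress, then parse inner
      payload <- memDecompress(payload, type = "gzip")
      inner <- .read_tag(payload, 1L, endian)
      if (inner$type == 14L) {
        el <- .parse_matrix_element(
          payload[inner$data_start:(inner$data_start + inner$nbytes - 1L)],
          endian
        )
        out[[el$name]] <- el$value
      }
    } else if (tg$type == 14L) {
      el <- .parse_matrix_element(payload, endian)
      out[[el$name]] <- el$value
    }
    pos <- tg$next_pos
  }
  out
}

#' Write numeric arrays to a MATLAB MAT-file (v5)
#'
#' Writes each element of `vars` as an uncompressed little-endian
#' double-precision array (vectors become 1 x n row vectors, as MATLAB
#' requires at least two dimensions).
#'
#' @param vars Named list of numeric vectors/matrices/arrays.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matfile <- function(vars, path) {
  if (is.null(names(vars)) || any(!nzchar(names(vars)))) {
    stop("all variables must be named", call. = FALSE)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("MATLAB 5.0 MAT-file, written by ramanspec on %s",
                           format(Sys.time(), "%Y-%m-%d")))
  hdr <- c(hdr, rep(charToRaw(" "), 116L - length(hdr)))
  writeBin(hdr, con)
  writeBin(raw(8L), con)                                  # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)                    # version 0x0100
  writeChar("IM", con, eos = NULL)                        # endian indicator

  pad8 <- function(nb) (8L - nb %% 8L) %% 8L
  for (nm in names(vars)) {
    v <- vars[[nm]]
    storage.mode(v) <- "double"
    dims <- dim(v) %||% c(1L, length(v))
    if (length(dims) < 2L) dims <- c(1L, dims)
    nd <- length(dims)
    name_raw <- charToRaw(nm)
    dims_bytes <- 4L * nd
    total <- 16L +
      8L + dims_bytes + pad8(dims_bytes) +
      8L + length(name_raw) + pad8(length(name_raw)) +
      8L + 8L * length(v)
    writeBin(c(14L, total), con, size = 4L, endian = "little")
    # array flags: mxDOUBLE_CLASS = 6
    writeBin(c(6L, 8L), con, size = 4L, endian = "little")
    writeBin(c(6L, 0L), con, size = 4L, endian = "little")
    # dimensions
    writeBin(c(5L, dims_bytes), con, size = 4L, endian = "little")
    writeBin(as.integer(dims), con, size = 4L, endian = "little")
    writeBin(raw(pad8(dims_bytes)), con)
    # name
    writeBin(c(1L, length(name_raw)), con, size = 4L, endian = "little")
    writeBin(name_raw, con)
    writeBin(raw(pad8(length(name_raw))), con)
    # real part
    writeBin(c(9L, 8L * length(v)), con, size = 4L, endian = "little")
    writeBin(as.numeric(v), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Load a spectral container from a MAT-file export
#'
#' Loads hyperspectral data exported to MATLAB files (e.g. by vendor
#' acquisition software) given explicit variable names: vendor schemas vary,
#' so nothing is guessed. A flattened N x B intensity matrix is reshaped
#' row-major to `spatial_shape` when one is supplied.
#'
#' @param path Path to the MAT-file.
#' @param intensity_var Name of the intensity variable (vector, N x B matrix,
#'   or higher-dimensional array with the spectral axis last).
#' @param axis_var Name of the wavenumber axis variable (vector of length B).
#' @param spatial_shape Optional integer vector of spatial dimensions used to
#'   reshape an N x B matrix (N must equal `prod(spatial_shape)`).
#' @return A `spectral_container`.
#' @export
load_matfile <- function(path, intensity_var, axis_var, spatial_shape = NULL) {
  vars <- read_matfile(path)
  for (v in c(intensity_var, axis_var)) {
    if (!v %in% names(vars)) {
      stop(sprintf(
        "variable '%s' not found; available: %s",
        v, paste(names(vars), collapse = ", ")
      ), call. = FALSE)
    }
  }
  axis <- as.numeric(vars[[axis_var]])
  x <- vars[[intensity_var]]
  dims <- dim(x) %||% length(x)
  dims <- dims[dims > 1L] # drop singleton dims (1 x B row vectors etc.)
  if (length(dims) <= 1L) {
    return(spectral_container(as.numeric(x), axis))
  }
  x <- array(as.numeric(x), dim = dims)
  b <- dims[length(dims)]
  if (b != length(axis)) {
    stop(sprintf(
      "last dimension of '%s' (%d) does not match axis length (%d)",
      intensity_var, b, length(axis)
    ), call. = FALSE)
  }
  if (!is.null(spatial_shape)) {
    if (length(dims) != 2L) {
      stop("spatial_shape applies to flattened N x B matrices", call. = FALSE)
    }
    if (prod(spatial_shape) != dims[1L]) {
      stop(sprintf(
        "spatial_shape [%s] incompatible with %d spectra",
        paste(spatial_shape, collapse = ","), dims[1L]
      ), call. = FALSE)
    }
    return(unflatten_container(x, spatial_shape, axis))
  }
  spectral_container(x, axis)
}
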