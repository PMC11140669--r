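#' Array-based spectral container
#'
#' The common currency of the package: an intensity array whose last axis is
#' the spectral (wavenumber) axis, plus the wavenumber axis itself. Four
#' modalities are supported, inferred from the number of leading spatial
#' dimensions: a single spectrum (none), a stack of spectra (one), a
#' hyperspectral image (two) and a volumetric scan (three).
#'
#' The wavenumber axis is normalized to strictly increasing order at
#' construction; an axis supplied in decreasing order is reversed together
#' with the spectral axis of the intensities, so the (wavenumber, intensity)
#' pairing is preserved.
#'
#' @param intensities Numeric vector or array. The last dimension must match
#'   the length of `axis`. A plain vector is treated as a single spectrum.
#' @param axis Numeric vector of wavenumbers (cm^-1), strictly monotone in
#'   either direction, length >= 2, all finite.
#' @param nan_policy How to treat non-finite intensities: `"error"` (default)
#'   rejects them; `"zero"` replaces them with 0 and warns, which accommodates
#'   vendor exports with masked pixels.
#'
#' @return An object of class `spectral_container` with fields `intensities`,
#'   `axis` and `kind` (one of `"spectrum"`, `"spectra_stack"`, `"image"`,
#'   `"volume"`).
#' @examples
#' sc <- spectral_container(matrix(runif(6), 2, 3), c(700, 710, 720))
#' sc$kind # "spectra_stack"
#' @export
spectral_container <- function(intensities, axis,
                               nan_policy = c("error", "zero")) {
  nan_policy <- match.arg(nan_policy)
  axis <- as.numeric(axis)
  if (length(axis) < 2L) {
    stop("spectral axis must have at least 2 bands", call. = FALSE)
  }
  if (!all(is.finite(axis))) {
    stop("spectral axis contains non-finite values", call. = FALSE)
  }
  d <- diff(axis)
  if (all(d > 0)) {
    reversed <- FALSE
  } else if (all(d < 0)) {
    reversed <- TRUE
  } else {
    stop("spectral axis must be strictly monotone", call. = FALSE)
  }

  intensities <- if (is.null(dim(intensities))) {
    as.numeric(intensities)
  } else {
    storage.mode(intensities) <- "double"
    intensities
  }
  dims <- dim(intensities) %||% length(intensities)
  nb <- dims[length(dims)]
  if (nb != length(axis)) {
    stop(sprintf(
      "last dimension of intensities (%d) does not match axis length (%d)",
      nb, length(axis)
    ), call. = FALSE)
  }
  n_spatial <- length(dims) - 1L
  if (is.null(dim(intensities))) n_spatial <- 0L
  if (n_spatial > 3L) {
    stop(sprintf("unsupported shape: %d spatial dimensions (max 3)", n_spatial),
      call. = FALSE
    )
  }

  if (!all(is.finite(intensities))) {
    if (nan_policy == "error") {
      stop("intensities contain non-finite values (see nan_policy)",
        call. = FALSE
      )
    }
    n_bad <- sum(!is.finite(intensities))
    warning(sprintf("replaced %d non-finite intensities with 0", n_bad))
    intensities[!is.finite(intensities)] <- 0
  }

  if (reversed) {
    axis <- rev(axis)
    intensities <- .reverse_spectral(intensities)
  }

  kind <- c("spectrum", "spectra_stack", "image", "volume")[n_spatial + 1L]
  structure(
    list(intensities = intensities, axis = axis, kind = kind),
    class = "spectral_container"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reverse the last (spectral) axis of a vector or array.
.reverse_spectral <- function(x) {
  if (is.null(dim(x))) {
    return(rev(x))
  }
  nd <- length(dim(x))
  idx <- rep(list(quote(expr = )), nd)
  idx[[nd]] <- rev(seq_len(dim(x)[nd]))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' @export
print.spectral_container <- function(x, ...) {
  dims <- dim(x$intensities) %||% length(x$intensities)
  cat(sprintf(
    "<spectral_container: %s, %s, %d bands, %.1f-%.1f cm^-1>\n",
    x$kind, paste(dims, collapse = " x "), length(x$axis),
    min(x$axis), max(x$axis)
  ))
  invisible(x)
}

is_spectral_container <- function(x) inherits(x, "spectral_container")

.assert_container <- function(x) {
  if (!is_spectral_container(x)) {
    stop("expected a spectral_container", call. = FALSE)
  }
  invisible(x)
}

#' Spatial shape of a container
#'
#' @param x A `spectral_container`.
#' @return Integer vector of spatial dimensions (length 0 for a single
#'   spectrum).
#' @export
spatial_shape <- function(x) {
  .assert_container(x)
  dims <- dim(x$intensities)
  if (is.null(dims)) integer(0) else as.integer(dims[-length(dims)])
}

#' Number of spectral bands
#' @param x A `spectral_container`.
#' @return Integer band count.
#' @export
n_bands <- function(x) {
  .assert_container(x)
  length(x$axis)
}

#' Flatten a container to an N x B spectra matrix
#'
#' Spatial positions are enumerated row-major (the last spatial index varies
#' fastest), the canonical form consumed by unmixing and profiling. The
#' operation round-trips exactly with [unflatten_container()].
#'
#' @param x A `spectral_container`.
#' @return A list with `spectra` (N x B numeric matrix, N = product of the
#'   spatial dimensions, 1 for a single spectrum) and `spatial` (the spatial
#'   shape, an integer vector).
#' @export
flatten_container <- function(x) {
  .assert_container(x)
  sp <- spatial_shape(x)
  b <- n_bands(x)
  arr <- x$intensities
  if (length(sp) == 0L) {
    m <- matrix(arr, nrow = 1L)
  } else if (length(sp) == 1L) {
    m <- arr
    dim(m) <- c(sp, b)
  } else {
    # row-major spatial enumeration: reverse spatial dims so the original last
    # spatial index becomes column-major-fastest, then collapse
    perm <- c(rev(seq_along(sp)), length(sp) + 1L)
    m <- aperm(arr, perm)
    dim(m) <- c(prod(sp), b)
  }
  list(spectra = m, spatial = sp)
}

#' Rebuild a container from a flattened spectra matrix
#'
#' Inverse of [flatten_container()].
#'
#' @param spectra N x B numeric matrix.
#' @param spatial Integer vector of spatial dimensions (possibly empty).
#' @param axis Wavenumber axis of length B.
#' @return A `spectral_container`.
#' @export
unflatten_container <- function(spectra, spatial, axis) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra)
  b <- ncol(spectra)
  spatial <- as.integer(spatial)
  if (length(spatial) == 0L) {
    if (n != 1L) stop("spectrum kind requires a single row", call. = FALSE)
    return(spectral_container(as.numeric(spectra[1L, ]), axis))
  }
  if (prod(spatial) != n) {
    stop("spatial shape does not match number of spectra", call. = FALSE)
  }
  if (length(spatial) == 1L) {
    return(spectral_container(spectra, axis))
  }
  arr <- spectra
  dim(arr) <- c(rev(spatial), b)
  arr <- aperm(arr, c(rev(seq_along(spatial)), length(spatial) + 1L))
  spectral_container(arr, axis)
}

#' Extract the spatial intensity map at one wavenumber band
#'
#' Selects the band whose axis value is nearest to `target` (ties broken
#' toward the lower index), e.g. a slice across the 1008 cm^-1
#' protein-associated band of an image or volume.
#'
#' @param x A `spectral_container`.
#' @param target Target wavenumber (cm^-1).
#' @param tol Allowed excursion of `target` beyond the axis range; defaults to
#'   the median axis spacing.
#' @return A list with `values` (intensities at the selected band, shaped like
#'   the spatial grid; a scalar for a single spectrum), `wavenumber` (the
#'   selected axis value) and `index` (its band index).
#' @export
band_slice <- function(x, target, tol = NULL) {
  .assert_container(x)
  if (is.null(tol)) tol <- stats::median(diff(x$axis))
  if (target < min(x$axis) - tol || target > max(x$axis) + tol) {
    stop(sprintf(
      "target %.6g cm^-1 outside axis range [%.6g, %.6g] (tol %.4g)",
      target, min(x$axis), max(x$axis), tol
    ), call. = FALSE)
  }
  i <- which.min(abs(x$axis - target)) # which.min keeps the lower index on ties
  sp <- spatial_shape(x)
  if (length(sp) == 0L) {
    vals <- x$intensities[i]
  } else {
    nd <- length(sp) + 1L
    idx <- rep(list(quote(expr = )), nd)
    idx[[nd]] <- i
    vals <- do.call(`[`, c(list(x$intensities), idx, list(drop = FALSE)))
    dim(vals) <- sp
  }
  list(values = vals, wavenumber = x$axis[i], index = i)
}
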