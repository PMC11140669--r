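# Preprocessing suite: every operation maps container -> container, applied
# independently per spectrum along the spectral axis, and never mutates its
# input. Only crop changes the spectral axis; nothing changes spatial shape.

# internal constructor: trusted inputs, allows B = 1 (e.g. a single-band crop)
.new_container <- function(intensities, axis, kind) {
  structure(
    list(intensities = intensities, axis = as.numeric(axis), kind = kind),
    class = "spectral_container"
  )
}

# apply fn (vector -> vector, same length) to every spectrum
.map_spectra <- function(x, fn) {
  f <- flatten_container(x)
  m <- f$spectra
  out <- m
  for (i in seq_len(nrow(m))) out[i, ] <- fn(m[i, ])
  res <- .new_container(out, x$axis, "spectra_stack")
  .reshape_like(res, x)
}

# reshape a flattened (N x B) container back to the spatial layout of `ref`
.reshape_like <- function(flat, ref) {
  sp <- spatial_shape(ref)
  m <- flat$intensities
  if (!is.matrix(m)) m <- matrix(m, nrow = 1L)
  b <- ncol(m)
  if (length(sp) == 0L) {
    return(.new_container(as.numeric(m[1L, ]), flat$axis, "spectrum"))
  }
  if (length(sp) == 1L) {
    return(.new_container(m, flat$axis, "spectra_stack"))
  }
  arr <- m
  dim(arr) <- c(rev(sp), b)
  arr <- aperm(arr, c(rev(seq_along(sp)), length(sp) + 1L))
  .new_container(arr, flat$axis, ref$kind)
}

#' Crop to a wavenumber region
#'
#' Retains exactly the bands with `min_wn <= axis <= max_wn` (inclusive),
#' e.g. cropping to the 700-1800 cm^-1 fingerprint region. Spatial dimensions
#' are unchanged.
#'
#' @param x A `spectral_container`.
#' @param min_wn,max_wn Region bounds in cm^-1, `min_wn < max_wn` (equality
#'   selects a single band).
#' @return The cropped container.
#' @export
crop_spectra <- function(x, min_wn, max_wn) {
  .assert_container(x)
  if (min_wn > max_wn) stop("min_wn must not exceed max_wn", call. = FALSE)
  keep <- which(x$axis >= min_wn & x$axis <= max_wn)
  if (length(keep) == 0L) {
    stop(sprintf("no bands in [%.6g, %.6g]", min_wn, max_wn), call. = FALSE)
  }
  f <- flatten_container(x)
  flat <- .new_container(f$spectra[, keep, drop = FALSE], x$axis[keep],
                         "spectra_stack")
  .reshape_like(flat, x)
}

#' Remove cosmic-ray spikes (modified z-score method)
#'
#' Cosmic-ray removal in the style of Whitaker & Hayes: per spectrum, first
#' differences `d[i] = y[i] - y[i-1]` are scored with the modified z-score
#' `Z[i] = 0.6745 * (d[i] - median(d)) / MAD(d)`; band `i` is flagged when
#' `|Z[i]|` exceeds `z_threshold`. Flagged intensities are replaced by the
#' mean of unflagged neighbours within `(window - 1) / 2` bands, falling back
#' to linear interpolation between the nearest unflagged points when the
#' window holds none. Unflagged values pass through bit-identically.
#'
#' If `MAD(d)` is zero while `d` is non-constant, the mean absolute deviation
#' is used instead; a fully constant spectrum is returned unchanged.
#'
#' @param x A `spectral_container` with at least 3 bands.
#' @param z_threshold Positive flagging threshold on `|Z|` (default 6.5, a
#'   conservative low-false-positive setting).
#' @param window Odd neighbourhood width for replacement (default 5).
#' @param return_mask If `TRUE`, also return the logical flag mask.
#' @return The despiked container; with `return_mask = TRUE`, a list with
#'   `container` and `mask` (same shape as the intensities).
#' @export
despike_whitaker_hayes <- function(x, z_threshold = 6.5, window = 5L,
                                   return_mask = FALSE) {
  .assert_container(x)
  if (n_bands(x) < 3L) stop("despiking needs at least 3 bands", call. = FALSE)
  if (z_threshold <= 0) stop("z_threshold must be positive", call. = FALSE)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    stop("window must be odd and >= 3", call. = FALSE)
  }
  half <- (window - 1L) %/% 2L

  f <- flatten_container(x)
  m <- f$spectra
  mask <- matrix(FALSE, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    y <- m[r, ]
    if (all(y == y[1L])) next
    d <- diff(y)
    med <- stats::median(d)
    mad0 <- stats::median(abs(d - med))
    if (mad0 == 0) mad0 <- mean(abs(d - med))
    if (mad0 == 0) next
    z <- 0.6745 * (d - med) / mad0
    flag <- c(FALSE, abs(z) > z_threshold)
    if (!any(flag)) next
    idx_ok <- which(!flag)
    y_new <- y
    for (i in which(flag)) {
      nb <- idx_ok[idx_ok >= i - half & idx_ok <= i + half]
      if (length(nb) > 0L) {
        y_new[i] <- mean(y[nb])
      } else {
        lo <- idx_ok[idx_ok < i]
        hi <- idx_ok[idx_ok > i]
        if (length(lo) && length(hi)) {
          l <- max(lo); h <- min(hi)
          y_new[i] <- y[l] + (y[h] - y[l]) * (i - l) / (h - l)
        } else if (length(lo)) {
          y_new[i] <- y[max(lo)]
        } else if (length(hi)) {
          y_new[i] <- y[min(hi)]
        }
      }
    }
    m[r, ] <- y_new
    mask[r, ] <- flag
  }
  out <- .reshape_like(.new_container(m, x$axis, "spectra_stack"), x)
  if (!return_mask) return(out)
  msk <- .reshape_like(.new_container(mask * 1, x$axis, "spectra_stack"), x)
  list(container = out, mask = msk$intensities > 0)
}

#' Savitzky-Golay denoising
#'
#' Per spectrum, each point is replaced by the centre value of the
#' least-squares polynomial of order `polyorder` fitted over a sliding window
#' of `window` bands; edges are handled by polynomial fits over the available
#' one-sided windows. Polynomials of degree `<= polyorder` are reproduced
#' exactly at interior points.
#'
#' @param x A `spectral_container`.
#' @param polyorder Polynomial order (default 3).
#' @param window Odd window length, `polyorder < window <= B` (default 7).
#' @return The smoothed container.
#' @export
denoise_savgol <- function(x, polyorder = 3L, window = 7L) {
  .assert_container(x)
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window < 3L) {
    stop("window must be odd and >= 3", call. = FALSE)
  }
  if (polyorder >= window) stop("polyorder must be < window", call. = FALSE)
  if (window > n_bands(x)) {
    stop(sprintf("window (%d) exceeds band count (%d)", window, n_bands(x)),
      call. = FALSE
    )
  }
  filt <- signal::sgolay(p = polyorder, n = window)
  .map_spectra(x, function(y) as.numeric(signal::sgolayfilt(y, filt)))
}

#' Gaussian denoising
#'
#' Convolution along the spectral axis with a unit-sum Gaussian kernel
#' truncated at 4 standard deviations, with reflect padding at the edges.
#'
#' @param x A `spectral_container`.
#' @param sigma_bands Kernel standard deviation in bands (default 1).
#' @return The smoothed container.
#' @export
denoise_gaussian <- function(x, sigma_bands = 1) {
  .assert_container(x)
  if (sigma_bands <= 0) stop("sigma_bands must be positive", call. = FALSE)
  r <- as.integer(ceiling(4 * sigma_bands))
  k <- stats::dnorm(seq(-r, r), sd = sigma_bands)
  k <- k / sum(k)
  b <- n_bands(x)
  if (r >= b) stop("kernel radius exceeds band count", call. = FALSE)
  .map_spectra(x, function(y) {
    yp <- c(rev(y[seq_len(r)]), y, rev(y[(b - r + 1L):b]))
    as.numeric(stats::filter(yp, k, sides = 2L))[(r + 1L):(r + b)]
  })
}

# second-difference penalty lambda * t(D) %*% D, optionally row-scaled
.whittaker_penalty <- function(b, lambda, alpha = NULL) {
  d <- Matrix::bandSparse(b - 2L, b,
    k = 0:2,
    diagonals = list(rep(1, b - 2L), rep(-2, b - 2L), rep(1, b - 2L))
  )
  if (is.null(alpha)) {
    lambda * Matrix::crossprod(d)
  } else {
    lambda * Matrix::crossprod(d, Matrix::Diagonal(x = alpha) %*% d)
  }
}

#' Baseline correction by asymmetric least squares (ASLS)
#'
#' Per spectrum, estimates a smooth baseline `z` minimising
#' `sum(w * (y - z)^2) + lambda * sum(diff(z, differences = 2)^2)`, iterating
#' the asymmetric weights `w[i] = p` where `y[i] > z[i]` and `1 - p`
#' elsewhere, starting from uniform weights. Iteration stops when fewer than
#' a fraction `tol` of the weights change, or after `max_iter` iterations
#' (with a warning). Returns the corrected signal `y - z`.
#'
#' @param x A `spectral_container`.
#' @param lambda Smoothness penalty, > 0 (default 1e5).
#' @param p Asymmetry parameter in (0, 1) (default 0.01; small values push
#'   the baseline under the peaks).
#' @param max_iter Iteration cap (default 30).
#' @param tol Weight-change fraction below which iteration stops (default 1e-3).
#' @param return_baseline If `TRUE`, return a list with the corrected
#'   container and the fitted `baseline` container.
#' @return The baseline-corrected container (or a list, see `return_baseline`).
#' @export
baseline_asls <- function(x, lambda = 1e5, p = 0.01, max_iter = 30L,
                          tol = 1e-3, return_baseline = FALSE) {
  .assert_container(x)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)", call. = FALSE)
  b <- n_bands(x)
  if (b < 4L) stop("baseline correction needs at least 4 bands", call. = FALSE)
  pen <- .whittaker_penalty(b, lambda)

  fit_one <- function(y) {
    w <- rep(1, b)
    z <- y
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      a <- Matrix::Diagonal(x = w) + pen
      z <- as.numeric(Matrix::solve(a, w * y))
      w_new <- ifelse(y > z, p, 1 - p)
      if (mean(w_new != w) < tol) {
        converged <- TRUE
        w <- w_new
        break
      }
      w <- w_new
    }
    if (!converged) {
      warning("ASLS did not reach weight stability; returning best iterate",
        call. = FALSE
      )
    }
    z
  }

  f <- flatten_container(x)
  m <- f$spectra
  base <- m
  for (i in seq_len(nrow(m))) base[i, ] <- fit_one(m[i, ])
  corrected <- .reshape_like(
    .new_container(m - base, x$axis, "spectra_stack"), x
  )
  if (!return_baseline) return(corrected)
  list(
    container = corrected,
    baseline = .reshape_like(.new_container(base, x$axis, "spectra_stack"), x)
  )
}

#' Baseline correction by adaptive smoothness penalized least squares (asPLS)
#'
#' As [baseline_asls()], but with residual-driven adaptive weights
#' `w[i] = 1 / (1 + exp(2 * (r[i] - sigma_neg) / sigma_neg))` where
#' `r = y - z` and `sigma_neg` is the standard deviation of the negative
#' residuals, and a per-point penalty scaling `alpha[i] = |r[i]| / max|r|`
#' applied to `lambda`. Iterates to weight stability; a zero `sigma_neg`
#' (perfect fit) terminates.
#'
#' @inheritParams baseline_asls
#' @return The baseline-corrected container (or a list with `baseline`).
#' @export
baseline_aspls <- function(x, lambda = 1e5, max_iter = 30L, tol = 1e-3,
                           return_baseline = FALSE) {
  .assert_container(x)
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  b <- n_bands(x)
  if (b < 4L) stop("baseline correction needs at least 4 bands", call. = FALSE)

  fit_one <- function(y) {
    w <- rep(1, b)
    alpha <- rep(1, b - 2L)
    z <- y
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      a <- Matrix::Diagonal(x = w) + .whittaker_penalty(b, lambda, alpha)
      z <- as.numeric(Matrix::solve(a, w * y))
      r <- y - z
      neg <- r[r < 0]
      sigma_neg <- if (length(neg) > 1L) stats::sd(neg) else 0
      if (sigma_neg == 0 || max(abs(r)) == 0) {
        converged <- TRUE
        break
      }
      w_new <- 1 / (1 + exp(2 * (r - sigma_neg) / sigma_neg))
      alpha <- abs(r)[2:(b - 1L)] / max(abs(r))
      if (sqrt(sum((w_new - w)^2)) / sqrt(sum(w^2)) < tol) {
        converged <- TRUE
        w <- w_new
        break
      }
      w <- w_new
    }
    if (!converged) {
      warning("asPLS did not reach weight stability; returning best iterate",
        call. = FALSE
      )
    }
    z
  }

  f <- flatten_container(x)
  m <- f$spectra
  base <- m
  for (i in seq_len(nrow(m))) base[i, ] <- fit_one(m[i, ])
  corrected <- .reshape_like(
    .new_container(m - base, x$axis, "spectra_stack"), x
  )
  if (!return_baseline) return(corrected)
  list(
    container = corrected,
    baseline = .reshape_like(.new_container(base, x$axis, "spectra_stack"), x)
  )
}

#' Normalize spectra
#'
#' Three modes: `minmax_global` rescales the whole container to the interval
#' \[0, 1\]; `minmax_pixel` rescales each spectrum to \[0, 1\] independently;
#' `auc_pixel` divides each spectrum by its trapezoidal integral over the
#' wavenumber axis, setting the area under the curve to 1.
#'
#' @param x A `spectral_container`.
#' @param mode One of `"minmax_global"`, `"minmax_pixel"`, `"auc_pixel"`.
#' @return The normalized container.
#' @export
normalize_spectra <- function(x, mode = c("minmax_global", "minmax_pixel",
                                          "auc_pixel")) {
  .assert_container(x)
  mode <- match.arg(mode)
  f <- flatten_container(x)
  m <- f$spectra
  if (mode == "minmax_global") {
    rng <- range(m)
    if (rng[1L] == rng[2L]) {
      stop("degenerate range: global min equals global max", call. = FALSE)
    }
    m <- (m - rng[1L]) / (rng[2L] - rng[1L])
  } else if (mode == "minmax_pixel") {
    for (i in seq_len(nrow(m))) {
      rng <- range(m[i, ])
      if (rng[1L] == rng[2L]) {
        stop(sprintf("degenerate range in pixel %d (constant spectrum)", i),
          call. = FALSE
        )
      }
      m[i, ] <- (m[i, ] - rng[1L]) / (rng[2L] - rng[1L])
    }
  } else {
    for (i in seq_len(nrow(m))) {
      auc <- pracma::trapz(x$axis, m[i, ])
      if (auc <= 0) {
        stop(sprintf("non-positive area under the curve in pixel %d", i),
          call. = FALSE
        )
      }
      m[i, ] <- m[i, ] / auc
    }
  }
  .reshape_like(.new_container(m, x$axis, "spectra_stack"), x)
}

#' Subtract a background spectrum
#'
#' Subtracts a single background spectrum from every spectrum in the
#' container. The background axis must match the container axis exactly; no
#' implicit resampling is performed.
#'
#' @param x A `spectral_container`.
#' @param background A `spectral_container` of kind `spectrum` on the same
#'   axis, or a numeric vector of length B.
#' @return The background-subtracted container.
#' @export
subtract_background <- function(x, background) {
  .assert_container(x)
  if (is_spectral_container(background)) {
    if (background$kind != "spectrum") {
      stop("background must be a single spectrum", call. = FALSE)
    }
    if (length(background$axis) != length(x$axis) ||
          any(background$axis != x$axis)) {
      stop("background axis does not match container axis (no resampling)",
        call. = FALSE
      )
    }
    bg <- background$intensities
  } else {
    bg <- as.numeric(background)
    if (length(bg) != n_bands(x)) {
      stop("background length does not match band count", call. = FALSE)
    }
  }
  .map_spectra(x, function(y) y - bg)
}
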