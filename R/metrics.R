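# Spectral comparison metrics used for denoiser and unmixing validation:
# mean squared error, spectral angle distance, spectral information
# divergence, plus a per-spectrum report with mean and SEM.

#' Mean squared error between two spectra
#' @param x,y Numeric vectors of equal length.
#' @return Mean of squared differences.
#' @export
mse <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  mean((x - y)^2)
}

#' Spectral angle distance (radians)
#'
#' The angle between two spectra viewed as vectors,
#' `acos(<x, y> / (||x|| ||y||))` with the argument clamped to \[-1, 1\].
#' Invariant to positive rescaling of either argument; values lie in
#' \[0, pi\].
#'
#' @param x,y Numeric vectors of equal length, neither all-zero.
#' @return Angle in radians.
#' @export
sad <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    stop("spectral angle undefined for a zero vector", call. = FALSE)
  }
  acos(min(1, max(-1, sum(x * y) / (nx * ny))))
}

#' Spectral information divergence (nats)
#'
#' Symmetrized Kullback-Leibler divergence between the two spectra after
#' normalization to unit sum: `sum(p*log(p/q)) + sum(q*log(q/p))` with
#' natural logarithms. An `1e-12` floor is added to both normalized vectors
#' before the logarithms. Negative intensities (e.g. from baseline-corrected
#' spectra) are handled by shifting the affected vector up by its minimum,
#' with a warning.
#'
#' @param x,y Nonnegative numeric vectors of equal length with positive sum
#'   (after the negativity shift).
#' @return Divergence in nats (>= 0, symmetric, 0 iff the normalized vectors
#'   coincide up to the floor).
#' @export
sid <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  fix_neg <- function(v, label) {
    if (min(v) < 0) {
      warning(sprintf("negative entries in %s shifted by %.6g before SID",
                      label, -min(v)), call. = FALSE)
      v <- v - min(v)
    }
    v
  }
  x <- fix_neg(x, "x")
  y <- fix_neg(y, "y")
  if (sum(x) <= 0 || sum(y) <= 0) {
    stop("SID undefined for an all-zero vector", call. = FALSE)
  }
  eps <- 1e-12
  p <- x / sum(x) + eps
  q <- y / sum(y) + eps
  sum(p * log(p / q)) + sum(q * log(q / p))
}

#' Per-spectrum metric report
#'
#' Applies a metric row-wise to two matched sets of spectra and reports the
#' per-spectrum values, their mean and the standard deviation of the sample
#' mean (`sd / sqrt(N)`, the error-bar convention for method comparisons).
#'
#' @param metric `"mse"`, `"sad"`, `"sid"`, or a function `(x, y) -> scalar`.
#' @param x,y N x B numeric matrices (or `spectral_container`s, flattened),
#'   with matching shapes.
#' @return A `metric_report`: list with `values` (length N), `mean` and `sem`
#'   (0 for N = 1).
#' @export
metric_report <- function(metric, x, y) {
  fn <- if (is.function(metric)) {
    metric
  } else {
    switch(match.arg(metric, c("mse", "sad", "sid")),
      mse = mse, sad = sad, sid = sid
    )
  }
  if (is_spectral_container(x)) x <- flatten_container(x)$spectra
  if (is_spectral_container(y)) y <- flatten_container(y)$spectra
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!all(dim(x) == dim(y))) stop("shape mismatch", call. = FALSE)
  vals <- vapply(seq_len(nrow(x)), function(i) fn(x[i, ], y[i, ]), 0)
  structure(
    list(
      values = vals,
      mean = mean(vals),
      sem = if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals)) else 0
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report: n=%d, mean=%.6g, sem=%.6g>\n",
    length(x$values), x$mean, x$sem
  ))
  invisible(x)
}
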