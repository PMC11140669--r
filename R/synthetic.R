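# Ground-truth-bearing synthetic Raman scene generator: peak-structured
# endmember spectra (Gaussian/Lorentzian bands), Dirichlet-mixed abundances
# on a spatial grid with optional pure-pixel planting, smooth polynomial
# baselines, sparse high-amplitude cosmic spikes and additive Gaussian noise.
# Noiseless, spike-free, baseline-free scenes satisfy the linear mixing model
# exactly, so unmixing can be validated to near machine precision.

#' Configuration for a synthetic Raman scene
#'
#' All randomness in [gen_scene()] flows from the single `seed`. Amplitude
#' parameters (`baseline_amplitude`, `spike_amplitude`, `noise_sigma`) are
#' expressed as fractions of the clean scene's global intensity range, so the
#' same configuration produces comparable contamination whatever the absolute
#' intensity scale. With `paper_noise = TRUE` the contamination instead
#' follows the low-SNR emulation protocol: each spectrum is min-max
#' normalized to \[0, 1\] first and Gaussian noise of standard deviation
#' `noise_sigma` (default there 0.15) is added on that scale.
#'
#' @param spatial_shape Integer vector of spatial dimensions (default a
#'   20 x 20 image; use `integer(0)` for one spectrum).
#' @param k Number of endmembers (default 4).
#' @param axis_range Wavenumber range in cm^-1 (default 600-1900, bracketing
#'   the 700-1800 fingerprint region so cropping has work to do).
#' @param n_bands Number of bands (default 650).
#' @param n_peaks Peaks per endmember (default 5).
#' @param peak_range Range containing the peak centres (default 700-1800).
#' @param peak_width Range of peak widths in cm^-1 (default 4-20).
#' @param peak_amplitude Range of raw peak amplitudes (default 0.5-1).
#' @param normalize_area Scale each endmember to unit area under the curve
#'   (default `TRUE`): the standard pure-component convention, under which
#'   abundance fractions are invariant to per-spectrum area normalization.
#' @param min_sad Minimum pairwise spectral angle between endmembers, rad
#'   (default 0.25); sets are resampled until separated.
#' @param concentration Symmetric Dirichlet concentration for the abundances
#'   (default 0.5, moderately sparse mixtures).
#' @param pure_pixels Plant one pure pixel per endmember (default `TRUE`;
#'   N-FINDR is only correct under the pure-pixel assumption).
#' @param baseline_degree Polynomial degree of the smooth baseline (default 3).
#' @param baseline_amplitude Baseline amplitude as a fraction of the clean
#'   intensity range (default 0.5).
#' @param spike_rate Per-value Bernoulli probability of a cosmic spike
#'   (default 0.001).
#' @param spike_amplitude Spike amplitude range, as fractions of the clean
#'   intensity range (default 3-8).
#' @param noise_sigma Gaussian noise standard deviation, as a fraction of the
#'   clean intensity range, or on the \[0, 1\] scale when
#'   `paper_noise = TRUE` (default 0.05).
#' @param paper_noise Use the min-max-then-noise contamination order
#'   (default `FALSE`).
#' @param seed Integer seed (default 1).
#' @return A `scene_config` list.
#' @export
scene_config <- function(spatial_shape = c(20L, 20L), k = 4L,
                         axis_range = c(600, 1900), n_bands = 650L,
                         n_peaks = 5L, peak_range = c(700, 1800),
                         peak_width = c(4, 20), peak_amplitude = c(0.5, 1),
                         normalize_area = TRUE, min_sad = 0.25,
                         concentration = 0.5, pure_pixels = TRUE,
                         baseline_degree = 3L, baseline_amplitude = 0.5,
                         spike_rate = 0.001, spike_amplitude = c(3, 8),
                         noise_sigma = 0.05, paper_noise = FALSE, seed = 1L) {
  cfg <- list(
    spatial_shape = as.integer(spatial_shape), k = as.integer(k),
    axis_range = as.numeric(axis_range), n_bands = as.integer(n_bands),
    n_peaks = as.integer(n_peaks), peak_range = as.numeric(peak_range),
    peak_width = as.numeric(peak_width),
    peak_amplitude = as.numeric(peak_amplitude),
    normalize_area = isTRUE(normalize_area), min_sad = as.numeric(min_sad),
    concentration = as.numeric(concentration),
    pure_pixels = isTRUE(pure_pixels),
    baseline_degree = as.integer(baseline_degree),
    baseline_amplitude = as.numeric(baseline_amplitude),
    spike_rate = as.numeric(spike_rate),
    spike_amplitude = as.numeric(spike_amplitude),
    noise_sigma = as.numeric(noise_sigma),
    paper_noise = isTRUE(paper_noise), seed = as.integer(seed)
  )
  stopifnot(
    cfg$k >= 2L, cfg$n_bands >= 2L, cfg$n_peaks >= 1L,
    cfg$axis_range[1L] < cfg$axis_range[2L],
    all(cfg$peak_width > 0), all(cfg$peak_amplitude > 0),
    cfg$spike_rate >= 0, cfg$spike_rate < 1,
    cfg$noise_sigma >= 0, cfg$concentration > 0,
    cfg$baseline_amplitude >= 0, length(cfg$spatial_shape) <= 3L
  )
  if (cfg$peak_range[1L] < cfg$axis_range[1L] ||
        cfg$peak_range[2L] > cfg$axis_range[2L]) {
    stop("peak_range must lie within axis_range", call. = FALSE)
  }
  structure(cfg, class = "scene_config")
}

.eval_peak <- function(axis, center, width, amplitude, shape) {
  if (shape == "gaussian") {
    amplitude * exp(-(axis - center)^2 / (2 * width^2))
  } else {
    amplitude * width^2 / ((axis - center)^2 + width^2)
  }
}

.scene_axis <- function(cfg) {
  seq(cfg$axis_range[1L], cfg$axis_range[2L], length.out = cfg$n_bands)
}

#' Generate peak-structured endmember spectra
#'
#' Each endmember is a sum of `n_peaks` Gaussian or Lorentzian bands with
#' random centres, widths and amplitudes; sets whose minimum pairwise
#' spectral angle falls below `min_sad` are resampled (bounded retries).
#'
#' @param config A [scene_config()].
#' @param seed Optional seed (defaults to the config seed; pass `NULL` to use
#'   the ambient RNG stream).
#' @param max_retries Resampling budget for the separation constraint.
#' @return List with `spectra` (K x B matrix), `peaks` (per-endmember data
#'   frames of centre/width/amplitude/shape) and `axis`.
#' @export
gen_endmembers <- function(config, seed = config$seed, max_retries = 100L) {
  axis <- .scene_axis(config)
  draw_set <- function() {
    peaks <- vector("list", config$k)
    e <- matrix(0, config$k, config$n_bands)
    for (j in seq_len(config$k)) {
      pk <- data.frame(
        center = stats::runif(config$n_peaks, config$peak_range[1L],
                              config$peak_range[2L]),
        width = stats::runif(config$n_peaks, config$peak_width[1L],
                             config$peak_width[2L]),
        amplitude = stats::runif(config$n_peaks, config$peak_amplitude[1L],
                                 config$peak_amplitude[2L]),
        shape = sample(c("gaussian", "lorentzian"), config$n_peaks,
                       replace = TRUE)
      )
      y <- rep(0, config$n_bands)
      for (q in seq_len(config$n_peaks)) {
        y <- y + .eval_peak(axis, pk$center[q], pk$width[q], pk$amplitude[q],
                            pk$shape[q])
      }
      if (config$normalize_area) {
        area <- pracma::trapz(axis, y)
        y <- y / area
        pk$amplitude <- pk$amplitude / area
      }
      e[j, ] <- y
      peaks[[j]] <- pk
    }
    list(spectra = e, peaks = peaks)
  }
  .with_seed(seed, {
    for (try in seq_len(max_retries)) {
      s <- draw_set()
      sads <- utils::combn(config$k, 2L, function(ij) {
        sad(s$spectra[ij[1L], ], s$spectra[ij[2L], ])
      })
      if (min(sads) >= config$min_sad) {
        return(c(s, list(axis = axis)))
      }
    }
    stop(sprintf(
      "could not generate %d endmembers with pairwise SAD >= %.3g in %d tries; reduce k or add peaks",
      config$k, config$min_sad, max_retries
    ), call. = FALSE)
  })
}

#' Generate Dirichlet abundance maps
#'
#' Per-pixel draws from a symmetric Dirichlet distribution; optionally one
#' pure pixel (a unit abundance vector) is planted per endmember so the
#' pure-pixel assumption underlying N-FINDR holds.
#'
#' @param spatial_shape Integer vector of spatial dimensions.
#' @param k Number of endmembers (>= 2).
#' @param concentration Symmetric Dirichlet concentration (> 0).
#' @param seed Optional integer seed.
#' @param pure_pixels Plant pure pixels (default `TRUE`).
#' @return List with `abundances` (array of shape `c(spatial_shape, k)`, or
#'   N x K when the shape has one dimension) and `pure_indices` (flattened
#'   row-major pixel indices of the planted pure pixels, one per endmember;
#'   `NULL` when not planted).
#' @export
gen_abundances <- function(spatial_shape, k, concentration = 0.5, seed = NULL,
                           pure_pixels = TRUE) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  n <- prod(as.integer(spatial_shape))
  if (pure_pixels && n < k) {
    stop("need at least k pixels to plant pure pixels", call. = FALSE)
  }
  .with_seed(seed, {
    g <- matrix(stats::rgamma(n * k, shape = concentration), n, k)
    zero <- rowSums(g) == 0 # gamma underflow at very small concentration
    if (any(zero)) {
      g[cbind(which(zero), sample.int(k, sum(zero), replace = TRUE))] <- 1
    }
    a <- g / rowSums(g)
    pure_idx <- NULL
    if (pure_pixels) {
      pure_idx <- sample.int(n, k)
      a[pure_idx, ] <- 0
      a[cbind(pure_idx, seq_len(k))] <- 1
    }
    shaped <- if (length(spatial_shape) >= 2L) {
      ref <- .new_container(
        array(0, dim = c(as.integer(spatial_shape), k)),
        seq_len(k), "stack"
      )
      .reshape_like(.new_container(a, seq_len(k), "spectra_stack"),
                    ref)$intensities
    } else {
      a
    }
    list(abundances = shaped, pure_indices = pure_idx)
  })
}

# flatten an array of shape c(spatial, B) to N x B, row-major spatial order
.flatten_array <- function(arr, spatial) {
  if (length(spatial) <= 1L) {
    return(if (is.matrix(arr)) arr else matrix(arr, nrow = 1L))
  }
  b <- dim(arr)[length(dim(arr))]
  perm <- c(rev(seq_along(spatial)), length(spatial) + 1L)
  m <- aperm(arr, perm)
  dim(m) <- c(prod(spatial), b)
  m
}

#' Generate a synthetic Raman scene with full ground truth
#'
#' Builds `intensities = abundances %*% endmembers + baseline + spikes +
#' noise` on the configured spatial grid. The baseline is a shared smooth
#' polynomial (degree `baseline_degree`) with a small (+-10%) per-pixel
#' scale variation, shifted to be nonnegative; spikes occur at
#' Bernoulli(`spike_rate`) positions with amplitudes uniform in
#' `spike_amplitude` times the clean intensity range. With
#' `paper_noise = TRUE`, each spectrum is min-max normalized to \[0, 1\]
#' before Gaussian noise of sd `noise_sigma` is added, emulating the low-SNR
#' test-data protocol.
#'
#' @param config A [scene_config()].
#' @return List with `container` (the contaminated scene) and `truth`, a
#'   ground-truth bundle holding `endmembers` (K x B), `peaks`, `abundances`
#'   (`c(spatial, K)` array), `pure_indices`, `baseline` (same shape as the
#'   intensities), `spike_mask` (logical, same shape), `clean` (the pre-noise
#'   intensities the residuals should be measured against), `noise_sigma`
#'   and the `config` itself.
#' @export
gen_scene <- function(config) {
  if (!inherits(config, "scene_config")) config <- do.call(scene_config, config)
  axis <- .scene_axis(config)
  sp <- config$spatial_shape
  n <- prod(sp)
  if (length(sp) == 0L) n <- 1L
  b <- config$n_bands

  .with_seed(config$seed, {
    em <- gen_endmembers(config, seed = NULL)
    ab <- gen_abundances(if (length(sp) == 0L) 1L else sp, config$k,
      concentration = config$concentration, seed = NULL,
      pure_pixels = config$pure_pixels
    )
    a_flat <- .flatten_array(ab$abundances, sp)
    clean <- a_flat %*% em$spectra
    scale <- diff(range(clean))

    # shared smooth baseline with per-pixel scale variation
    base_flat <- matrix(0, n, b)
    if (config$baseline_amplitude > 0 && config$baseline_degree >= 0L) {
      t01 <- seq(-1, 1, length.out = b)
      coef <- stats::rnorm(config$baseline_degree + 1L)
      shared <- drop(outer(t01, 0:config$baseline_degree, `^`) %*% coef)
      shared <- shared - min(shared)
      if (max(shared) > 0) shared <- shared / max(shared)
      shared <- shared * config$baseline_amplitude * scale
      pix_scale <- stats::runif(n, 0.9, 1.1)
      base_flat <- outer(pix_scale, shared)
    }

    spike_mask <- matrix(stats::runif(n * b) < config$spike_rate, n, b)
    spikes <- matrix(0, n, b)
    if (any(spike_mask)) {
      spikes[spike_mask] <- stats::runif(
        sum(spike_mask),
        config$spike_amplitude[1L], config$spike_amplitude[2L]
      ) * scale
    }

    pre_noise <- clean + base_flat + spikes
    if (config$paper_noise) {
      rng_lo <- apply(pre_noise, 1L, min)
      rng_hi <- apply(pre_noise, 1L, max)
      pre_noise <- (pre_noise - rng_lo) / (rng_hi - rng_lo)
      noisy <- pre_noise +
        matrix(stats::rnorm(n * b, sd = config$noise_sigma), n, b)
    } else {
      noisy <- pre_noise +
        matrix(stats::rnorm(n * b, sd = config$noise_sigma * scale), n, b)
    }

    to_shape <- function(m) {
      if (length(sp) == 0L) {
        as.numeric(m[1L, ])
      } else if (length(sp) == 1L) {
        m
      } else {
        ref <- .new_container(array(0, dim = c(sp, b)), axis, "scene")
        .reshape_like(.new_container(m, axis, "spectra_stack"),
                      ref)$intensities
      }
    }

    container <- spectral_container(to_shape(noisy), axis)
    truth <- list(
      endmembers = em$spectra,
      peaks = em$peaks,
      abundances = ab$abundances,
      pure_indices = ab$pure_indices,
      baseline = to_shape(base_flat),
      spike_mask = to_shape(spike_mask * 1) > 0,
      clean = to_shape(pre_noise),
      noise_sigma = config$noise_sigma,
      axis = axis,
      config = config
    )
    list(container = container, truth = truth)
  })
}

#' Generate uniform random spectra for throughput profiling
#'
#' An n x B stack of i.i.d. uniform \[0, 1) values on a unit-spaced band
#' axis, the standard input for timing preprocessing protocols at scale
#' (e.g. 1000 / 10,000 / 100,000 spectra of 1500 values).
#'
#' @param n Number of spectra (>= 1).
#' @param n_bands Bands per spectrum (default 1500).
#' @param seed Optional integer seed.
#' @return A `spectral_container` of kind `spectra_stack`.
#' @export
gen_uniform_spectra <- function(n, n_bands = 1500L, seed = NULL) {
  n <- as.integer(n)
  n_bands <- as.integer(n_bands)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (n_bands < 2L) stop("n_bands must be >= 2", call. = FALSE)
  .with_seed(seed, {
    spectral_container(
      matrix(stats::runif(n * n_bands), n, n_bands),
      seq_len(n_bands)
    )
  })
}
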