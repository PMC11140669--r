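test_that("crop keeps exactly the in-range bands, inclusively", {
  axis <- seq(400, 3000, by = 2)
  sc <- spectral_container(matrix(rnorm(2 * length(axis)), 2), axis)
  cr <- crop_spectra(sc, 700, 1800)
  expect_true(all(cr$axis >= 700 & cr$axis <= 1800))
  expect_equal(cr$axis[1], 700)
  expect_equal(cr$axis[length(cr$axis)], 1800)
  expect_identical(crop_spectra(sc, min(axis), max(axis))$intensities,
                   sc$intensities)
  one <- crop_spectra(spectral_container(c(1, 2, 3), c(1, 2, 3)), 2, 2)
  expect_equal(one$axis, 2)
  expect_equal(one$intensities, 2)
  expect_error(crop_spectra(sc, 3500, 3600), "no bands")
})

test_that("despiking flags and repairs an isolated spike, touching nothing else", {
  y <- rep(2, 100)
  y[40] <- 200 # 100x the signal level
  sc <- spectral_container(y, seq_len(100))
  out <- despike_whitaker_hayes(sc, return_mask = TRUE)
  expect_true(out$mask[40])
  # replacement = mean of unflagged neighbours, all of which equal 2
  expect_equal(out$container$intensities[40], 2)
  expect_identical(out$container$intensities[-c(39, 40, 41)], y[-c(39, 40, 41)])
})

test_that("despiking is the identity on constant and smooth noisy spectra", {
  const <- spectral_container(rep(5, 50), seq_len(50))
  expect_identical(despike_whitaker_hayes(const)$intensities, rep(5, 50))
  axis <- seq(600, 1898, by = 2)
  y <- peaky_spectrum(axis, noise_sd = 0.02, seed = 8)
  sc <- spectral_container(y, axis)
  out <- despike_whitaker_hayes(sc, return_mask = TRUE)
  expect_false(any(out$mask))
  expect_identical(out$container$intensities, y)
})

test_that("despiking is idempotent on spike fixtures", {
  axis <- seq_len(200)
  y <- 1 + (axis / 200) + (axis / 200)^2
  y[c(50, 120)] <- c(30, 25)
  sc <- spectral_container(y, axis)
  once <- despike_whitaker_hayes(sc)
  twice <- despike_whitaker_hayes(once)
  expect_identical(twice$intensities, once$intensities)
})

test_that("Savitzky-Golay reproduces polynomials of its order exactly", {
  b <- 200
  i <- seq_len(b)
  y <- 2 + 0.01 * i - 1e-5 * i^2 + 3e-8 * i^3
  sc <- spectral_container(y, i)
  for (w in c(7L, 9L)) {
    out <- denoise_savgol(sc, 3L, w)
    h <- (w - 1L) / 2L
    interior <- (h + 1L):(b - h)
    expect_lt(max(abs((out$intensities - y) / y)[interior]), 1e-12)
  }
  const <- spectral_container(rep(3, 30), seq_len(30))
  expect_equal(denoise_savgol(const, 2L, 5L)$intensities, rep(3, 30))
})

test_that("Savitzky-Golay denoises a noisy cubic", {
  b <- 400
  i <- seq_len(b)
  clean <- 1 + 0.02 * i - 4e-5 * i^2 + 5e-8 * i^3
  set.seed(9)
  noisy <- clean + rnorm(b, sd = 0.1)
  out <- denoise_savgol(spectral_container(noisy, i), 3L, 9L)
  rmse <- function(a) sqrt(mean((a - clean)^2))
  expect_lt(rmse(out$intensities), rmse(noisy))
  expect_error(denoise_savgol(spectral_container(noisy, i), 3L, 401L), "window")
  expect_error(denoise_savgol(spectral_container(noisy, i), 5L, 5L), "polyorder")
})

test_that("Gaussian denoising has a unit-sum kernel and reduces noise", {
  const <- spectral_container(rep(2, 60), seq_len(60))
  expect_equal(denoise_gaussian(const, 1)$intensities, rep(2, 60),
    tolerance = 1e-12
  )
  imp <- rep(0, 101)
  imp[51] <- 1
  out <- denoise_gaussian(spectral_container(imp, seq_len(101)), 2)
  expect_equal(sum(out$intensities), 1, tolerance = 1e-12)
  expect_equal(which.max(out$intensities), 51L)
  # profile matches the normalized discrete Gaussian (direct convolution oracle)
  r <- ceiling(4 * 2)
  k <- dnorm(seq(-r, r), sd = 2)
  expect_equal(out$intensities[(51 - r):(51 + r)], k / sum(k),
    tolerance = 1e-12
  )
  b <- 300
  i <- seq_len(b)
  clean <- 0.5 + 0.01 * i - 2e-5 * i^2
  set.seed(10)
  noisy <- clean + rnorm(b, sd = 0.2)
  sm <- denoise_gaussian(spectral_container(noisy, i), 1.5)
  expect_lt(var(sm$intensities - clean), var(noisy - clean))
})

test_that("ASLS removes lines exactly and matches a dense Whittaker solve", {
  b <- 500
  i <- seq_len(b)
  line <- 1 + 0.005 * i
  out <- baseline_asls(spectral_container(line, i))
  expect_lt(sqrt(mean(out$intensities^2)) / diff(range(line)), 0.01)
  zero <- baseline_asls(spectral_container(rep(0, 50), seq_len(50)))
  expect_equal(zero$intensities, rep(0, 50), tolerance = 1e-12)

  # dense-matrix oracle for the penalized system at fixed uniform weights
  bb <- 60
  set.seed(11)
  y <- peaky_spectrum(seq(700, by = 20, length.out = bb), noise_sd = 0.05)
  d2 <- diff(diag(bb), differences = 2)
  z_dense <- solve(diag(bb) + 1e5 * t(d2) %*% d2, y)
  one_iter <- suppressWarnings(
    baseline_asls(spectral_container(y, seq_len(bb)), lambda = 1e5,
                  max_iter = 1L, return_baseline = TRUE)
  )
  expect_equal(as.numeric(one_iter$baseline$intensities), as.numeric(z_dense),
    tolerance = 1e-8
  )
})

test_that("ASLS preserves peak height over a linear baseline", {
  axis <- seq(400, 2398, by = 2)
  line <- 1 + 0.005 * seq_along(axis)
  peak <- 5 * exp(-(axis - 1200)^2 / (2 * 10^2))
  out <- baseline_asls(spectral_container(line + peak, axis),
                       return_baseline = TRUE)
  height <- max(out$container$intensities)
  expect_lt(abs(height - 5) / 5, 0.1)
  # baseline under the peak stays close to the true line
  under <- abs(axis - 1200) < 50
  z <- flatten_container(out$baseline)$spectra[1, ]
  expect_lt(max(abs(z[under] - line[under])), 0.1 * 5)
})

test_that("asPLS corrects smooth baselines and bounds negative excursions", {
  zero <- baseline_aspls(spectral_container(rep(0, 50), seq_len(50)))
  expect_equal(zero$intensities, rep(0, 50), tolerance = 1e-12)
  b <- 1000
  i <- seq_len(b)
  cubic <- 2 + 0.004 * i - 6e-6 * i^2 + 4e-9 * i^3
  out <- suppressWarnings(baseline_aspls(spectral_container(cubic, i)))
  expect_lt(sqrt(mean(out$intensities^2)) / diff(range(cubic)), 0.02)
  axis <- seq(400, 2398, by = 2)
  noise_sd <- 0.01
  set.seed(12)
  y <- 1 + 0.005 * seq_along(axis) +
    5 * exp(-(axis - 1200)^2 / (2 * 10^2)) +
    rnorm(length(axis), sd = noise_sd)
  corr <- suppressWarnings(baseline_aspls(spectral_container(y, axis)))
  expect_gt(min(corr$intensities), -3 * noise_sd - 0.02)
  expect_lt(abs(max(corr$intensities) - 5) / 5, 0.1)
})

test_that("normalization modes honour their contracts", {
  x <- rand_container(2, seed = 40)
  g <- normalize_spectra(x, "minmax_global")
  expect_equal(min(g$intensities), 0)
  expect_equal(max(g$intensities), 1)
  one <- normalize_spectra(spectral_container(c(2, 4, 6), 1:3), "minmax_pixel")
  expect_equal(one$intensities, c(0, 0.5, 1))
  pos <- spectral_container(abs(flatten_container(x)$spectra) + 1, x$axis)
  a <- normalize_spectra(pos, "auc_pixel")
  for (r in seq_len(nrow(a$intensities))) {
    expect_equal(pracma::trapz(a$axis, a$intensities[r, ]), 1,
      tolerance = 1e-12
    )
  }
  expect_error(
    normalize_spectra(spectral_container(rep(1, 5), 1:5), "minmax_global"),
    "degenerate"
  )
  flat <- spectral_container(rbind(c(1, 2, 3), c(4, 4, 4)), 1:3)
  expect_error(normalize_spectra(flat, "minmax_pixel"), "pixel 2")
  neg <- spectral_container(rbind(c(1, 2, 3), c(-4, -4, -4)), 1:3)
  expect_error(normalize_spectra(neg, "auc_pixel"), "pixel 2")
})

test_that("background subtraction is exact and refuses mismatched axes", {
  x <- rand_container(2, seed = 41)
  bg <- rnorm(n_bands(x))
  signal <- x$intensities
  contaminated <- sweep(signal, 3, -bg)
  sc <- spectral_container(contaminated, x$axis)
  rec <- subtract_background(sc, spectral_container(bg, x$axis))
  expect_equal(rec$intensities, signal, tolerance = 1e-12)
  zero <- subtract_background(x, rep(0, n_bands(x)))
  expect_identical(zero$intensities, x$intensities)
  spec <- rand_container(0, seed = 42)
  self <- subtract_background(spec, spec)
  expect_equal(self$intensities, rep(0, n_bands(spec)))
  other_axis <- spectral_container(bg, x$axis + 1)
  expect_error(subtract_background(x, other_axis), "axis")
})

test_that("per-spectrum operations commute with flatten/unflatten", {
  x <- rand_container(3, b = 40, seed = 43)
  x <- spectral_container(abs(x$intensities) + 0.5, x$axis)
  f <- flatten_container(x)
  stack <- spectral_container(f$spectra, x$axis)
  ops <- list(
    function(c) denoise_savgol(c, 2L, 5L),
    function(c) denoise_gaussian(c, 1),
    function(c) normalize_spectra(c, "auc_pixel"),
    function(c) baseline_asls(c, lambda = 1e4)
  )
  for (op in ops) {
    whole <- flatten_container(op(x))$spectra
    rows <- op(stack)$intensities
    expect_equal(whole, rows, tolerance = 1e-12)
  }
})

test_that("operations never mutate their input", {
  x <- rand_container(1, seed = 44)
  snapshot <- x$intensities
  invisible(denoise_gaussian(x, 1))
  invisible(crop_spectra(x, x$axis[3], x$axis[10]))
  invisible(normalize_spectra(x, "minmax_global"))
  expect_identical(x$intensities, snapshot)
})
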