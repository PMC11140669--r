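test_that("a single Gaussian band evaluates to its closed form", {
  cfg <- scene_config(
    k = 2, n_peaks = 1, peak_width = c(5, 5),
    peak_amplitude = c(1, 1), normalize_area = FALSE, min_sad = 0.01,
    axis_range = c(900, 1100), peak_range = c(950, 1050),
    n_bands = 201, seed = 80
  )
  em <- gen_endmembers(cfg)
  axis <- em$axis
  for (j in 1:2) {
    pk <- em$peaks[[j]]
    if (pk$shape != "gaussian") next
    expected <- exp(-(axis - pk$center)^2 / (2 * 25))
    expect_equal(em$spectra[j, ], expected, tolerance = 1e-12)
    expect_equal(axis[which.max(em$spectra[j, ])], pk$center, tolerance = 1)
    # band grid is 1 cm^-1, so the sampled maximum can sit up to half a band
    # off-centre: exp(-0.5^2 / (2 * 25)) = 0.995
    expect_gte(max(em$spectra[j, ]), exp(-0.25 / 50))
    expect_lte(max(em$spectra[j, ]), 1)
  }
})

test_that("endmember generation is seeded, separated, and rejects zero peaks", {
  cfg <- scene_config(seed = 81)
  a <- gen_endmembers(cfg)
  b <- gen_endmembers(cfg)
  expect_identical(a$spectra, b$spectra)
  sads <- combn(cfg$k, 2, function(ij) sad(a$spectra[ij[1], ], a$spectra[ij[2], ]))
  expect_gte(min(sads), cfg$min_sad)
  expect_error(scene_config(n_peaks = 0), "n_peaks")
})

test_that("unit-area endmembers integrate to one", {
  cfg <- scene_config(seed = 82)
  em <- gen_endmembers(cfg)
  for (j in seq_len(cfg$k)) {
    expect_equal(pracma::trapz(em$axis, em$spectra[j, ]), 1, tolerance = 1e-12)
  }
})

test_that("Dirichlet abundances are simplex-valued with planted pure pixels", {
  ab <- gen_abundances(c(10, 10), 4, concentration = 0.5, seed = 83)
  a <- flatten_rowmajor(ab$abundances, c(10, 10))
  expect_true(all(a >= 0))
  expect_equal(rowSums(a), rep(1, 100), tolerance = 1e-12)
  expect_length(ab$pure_indices, 4L)
  for (k in 1:4) {
    expect_equal(a[ab$pure_indices[k], ], as.numeric(k == 1:4))
  }
  # exactly K planted pure pixels
  expect_equal(sum(apply(a, 1, max) == 1), 4L)
})

test_that("a tiny concentration concentrates mass near the vertices", {
  ab <- gen_abundances(10000L, 3, concentration = 0.01, seed = 84,
                       pure_pixels = FALSE)
  frac <- mean(apply(ab$abundances, 1, max) > 0.95)
  expect_gt(frac, 0.9)
})

test_that("the noiseless limit reproduces the exact mixing model", {
  cfg <- scene_config(
    spatial_shape = c(6, 6), noise_sigma = 0, spike_rate = 0,
    baseline_amplitude = 0, seed = 85
  )
  sc <- gen_scene(cfg)
  a <- flatten_rowmajor(sc$truth$abundances, c(6, 6))
  expected <- a %*% sc$truth$endmembers
  got <- flatten_container(sc$container)$spectra
  expect_equal(got, expected, tolerance = 1e-12)
  expect_false(any(sc$truth$spike_mask))
})

test_that("scene generation is fully reproducible from its seed", {
  cfg <- scene_config(spatial_shape = c(5, 5), seed = 86)
  s1 <- gen_scene(cfg)
  s2 <- gen_scene(cfg)
  expect_identical(s1$container$intensities, s2$container$intensities)
  expect_identical(s1$truth$abundances, s2$truth$abundances)
  expect_identical(s1$truth$spike_mask, s2$truth$spike_mask)
})

test_that("spike counts follow the configured Bernoulli rate", {
  cfg <- scene_config(
    spatial_shape = c(40, 40), n_bands = 1000L, spike_rate = 0.001,
    noise_sigma = 0, baseline_amplitude = 0, seed = 87
  )
  sc <- gen_scene(cfg)
  n_values <- 1600 * 1000
  count <- sum(sc$truth$spike_mask)
  expected <- n_values * 0.001
  tol <- 4 * sqrt(n_values * 0.001 * 0.999)
  expect_gt(count, expected - tol)
  expect_lt(count, expected + tol)
  # spikes sit where the mask says, on top of the clean signal
  expect_true(all(
    sc$container$intensities[sc$truth$spike_mask] >
      sc$truth$clean[sc$truth$spike_mask] - 1e-12
  ))
})

test_that("uniform profiling stacks have the documented shape and law", {
  u <- gen_uniform_spectra(1000, seed = 88)
  expect_equal(dim(u$intensities), c(1000L, 1500L))
  expect_true(all(u$intensities >= 0 & u$intensities < 1))
  expect_equal(mean(u$intensities), 0.5, tolerance = 0.01)
  expect_identical(gen_uniform_spectra(50, 64L, seed = 89)$intensities,
                   gen_uniform_spectra(50, 64L, seed = 89)$intensities)
})
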