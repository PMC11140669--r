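test_that("PCA projection is exact on low-rank data and centres the mean", {
  set.seed(60)
  basis <- matrix(rnorm(2 * 30), 2, 30)
  coefs <- matrix(rnorm(25 * 2), 25, 2)
  x <- coefs %*% basis # rank-2 data in a 30-dim space
  pr <- pca_project(x, 2)
  recon <- pr$scores %*% t(pr$rotation)
  recon <- sweep(recon, 2, pr$center, `+`)
  expect_equal(recon, x, tolerance = 1e-10)
  expect_equal(as.numeric(pca_transform(pr, pr$center)), c(0, 0),
    tolerance = 1e-12
  )
  expect_error(pca_project(x, 5), "rank")
})

test_that("one-component PCA separates symmetric clusters by sign", {
  # two clusters at +-mu: the leading eigenvector of the 2x2 covariance is
  # the cluster axis, so scores separate the clusters by sign
  mu <- c(3, 1)
  set.seed(61)
  a <- sweep(matrix(rnorm(40, sd = 0.05), 20, 2), 2, mu, `+`)
  b <- sweep(matrix(rnorm(40, sd = 0.05), 20, 2), 2, mu, `-`)
  pr <- pca_project(rbind(a, b), 1)
  signs <- sign(pr$scores[, 1])
  expect_true(all(signs[1:20] == signs[1]))
  expect_true(all(signs[21:40] == -signs[1]))
})

test_that("N-FINDR finds the exact maximum-volume triple (brute force oracle)", {
  set.seed(62)
  b <- 40
  verts <- matrix(rnorm(3 * b), 3, b)
  w <- matrix(rgamma(30 * 3, 1), 30, 3)
  w <- w / rowSums(w)
  w <- 0.2 + 0.6 * w # strictly interior mixtures
  w <- w / rowSums(w)
  x <- rbind(verts, w %*% verts)
  em <- nfindr(x, 3, n_restarts = 10L, seed = 1)
  expect_setequal(em$indices, 1:3)
  # independent oracle: triangle areas over all C(33,3) triples in the same
  # projection
  scores <- pca_project(x, 2)$scores
  combos <- combn(nrow(x), 3)
  areas <- apply(combos, 2, function(idx) triangle_area(scores[idx, ]))
  expect_equal(em$volume, max(areas), tolerance = 1e-12)
})

test_that("N-FINDR handles N = K and duplicated data", {
  set.seed(63)
  verts <- matrix(rnorm(3 * 12), 3, 12)
  em <- nfindr(verts, 3, seed = 2)
  expect_setequal(em$indices, 1:3)
  mix <- rbind(verts, matrix(rgamma(60, 1), 20, 3) |>
                 (\(m) (m / rowSums(m)) %*% verts)())
  e1 <- nfindr(mix, 3, seed = 3)
  e2 <- nfindr(rbind(mix, mix), 3, seed = 3)
  expect_equal(e2$spectra[order(e2$spectra[, 1]), ],
               e1$spectra[order(e1$spectra[, 1]), ], tolerance = 1e-12)
  expect_error(nfindr(verts, 5), "exceeds")
  expect_error(nfindr(matrix(1:12, 4, 3) * 0, 2, seed = 1), "degenerate")
})

test_that("FCLS recovers vertices and known mixtures", {
  set.seed(64)
  e <- matrix(abs(rnorm(3 * 50)) + 0.1, 3, 50)
  for (k in 1:3) {
    a <- fcls(matrix(e[k, ], 1), e)
    expect_equal(as.numeric(a), as.numeric(k == 1:3), tolerance = 1e-6)
  }
  y <- 0.3 * e[1, ] + 0.7 * e[2, ]
  a <- fcls(matrix(y, 1), e)
  expect_equal(as.numeric(a), c(0.3, 0.7, 0), tolerance = 1e-6)
  # grid-search oracle over the simplex at resolution 1e-3
  g <- seq(0, 1, by = 1e-3)
  grid <- expand.grid(a1 = g, a2 = g)
  grid <- grid[grid$a1 + grid$a2 <= 1, ]
  res <- as.matrix(grid) %*% e[1:2, ] +
    outer(1 - grid$a1 - grid$a2, e[3, ])
  sse <- rowSums(sweep(res, 2, y)^2)
  best <- grid[which.min(sse), ]
  expect_equal(as.numeric(a[1:2]), as.numeric(best), tolerance = 1e-3)
})

test_that("FCLS equals unconstrained least squares when that is feasible", {
  set.seed(65)
  e <- matrix(abs(rnorm(4 * 80)) + 0.05, 4, 80)
  a_true <- c(0.4, 0.3, 0.2, 0.1)
  y <- as.numeric(a_true %*% e)
  a <- fcls(matrix(y, 1), e)
  expect_equal(as.numeric(a), a_true, tolerance = 1e-8)
  # optimality sanity: residual no worse than any vertex assignment
  r_fcls <- sqrt(sum((as.numeric(a %*% e) - y)^2))
  for (k in 1:4) {
    expect_lte(r_fcls, sqrt(sum((e[k, ] - y)^2)) + 1e-12)
  }
})

test_that("FCLS output always satisfies the abundance constraints", {
  set.seed(66)
  e <- matrix(abs(rnorm(4 * 60)), 4, 60)
  x <- matrix(abs(rnorm(25 * 60)), 25, 60)
  a <- fcls(x, e)
  expect_true(all(a >= 0))
  expect_equal(rowSums(a), rep(1, 25), tolerance = 1e-12)
})

test_that("pixel permutations permute abundances and keep the endmember set", {
  sc <- gen_scene(scene_config(
    spatial_shape = 36L, k = 3, n_bands = 120,
    noise_sigma = 0, spike_rate = 0, baseline_amplitude = 0, seed = 67
  ))
  x <- flatten_container(sc$container)$spectra
  perm <- sample(nrow(x))
  e1 <- nfindr(x, 3, seed = 5)
  e2 <- nfindr(x[perm, ], 3, seed = 5)
  expect_equal(e2$spectra[order(e2$spectra[, 1]), ],
               e1$spectra[order(e1$spectra[, 1]), ], tolerance = 1e-12)
  a1 <- fcls(x, e1)
  a2 <- fcls(x[perm, ], e1)
  expect_equal(a2, a1[perm, ], tolerance = 1e-12)
})

test_that("noiseless scenes unmix to near machine precision", {
  sc <- gen_scene(scene_config(
    spatial_shape = c(20, 20), k = 4, n_bands = 200,
    noise_sigma = 0, spike_rate = 0, baseline_amplitude = 0, seed = 68
  ))
  res <- unmix_scene(sc$container, 4, seed = 7)
  m <- match_endmembers(res$endmembers, sc$truth$endmembers)
  expect_lt(max(m$sad), 1e-6)
  est <- flatten_rowmajor(res$abundances, c(20, 20))[, m$order]
  truth <- flatten_rowmajor(sc$truth$abundances, c(20, 20))
  expect_lt(max(abs(est - truth)), 1e-4)
})

test_that("unmixing is deterministic given a seed and K=5 maps sum to one", {
  sc <- gen_scene(scene_config(
    spatial_shape = c(8, 8), k = 5, n_bands = 150,
    noise_sigma = 0.02, seed = 69
  ))
  r1 <- unmix_scene(sc$container, 5, seed = 11)
  r2 <- unmix_scene(sc$container, 5, seed = 11)
  expect_identical(r1$endmembers$indices, r2$endmembers$indices)
  expect_identical(r1$abundances, r2$abundances)
  sums <- apply(r1$abundances, c(1, 2), sum)
  expect_equal(as.numeric(sums), rep(1, 64), tolerance = 1e-12)
  expect_true(all(r1$abundances >= 0))
  expect_equal(dim(r1$abundances), c(8L, 8L, 5L))
})
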