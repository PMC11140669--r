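# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

# a random container of the requested spatial rank
rand_container <- function(n_spatial, b = 24L, seed = 1L) {
  set.seed(seed)
  axis <- seq(700, by = 2, length.out = b)
  dims <- switch(as.character(n_spatial),
    "0" = NULL, "1" = c(5L, b), "2" = c(4L, 5L, b), "3" = c(3L, 4L, 5L, b)
  )
  if (is.null(dims)) {
    spectral_container(stats::rnorm(b), axis)
  } else {
    spectral_container(array(stats::rnorm(prod(dims)), dims), axis)
  }
}

# multi-peak spectrum with broad bands, optionally noisy
peaky_spectrum <- function(axis, centers = c(800, 1008, 1450),
                           widths = c(30, 20, 40), heights = c(1, 2, 1.5),
                           noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- rep(0, length(axis))
  for (j in seq_along(centers)) {
    y <- y + heights[j] * exp(-(axis - centers[j])^2 / (2 * widths[j]^2))
  }
  if (noise_sd > 0) y <- y + stats::rnorm(length(axis), sd = noise_sd)
  y
}

# flatten a c(spatial, K) array to N x K in row-major spatial order,
# independent re-implementation used to compare against package output
flatten_rowmajor <- function(arr, spatial) {
  if (length(spatial) <= 1L) {
    return(if (is.matrix(arr)) arr else matrix(arr, nrow = 1L))
  }
  k <- dim(arr)[length(dim(arr))]
  n <- prod(spatial)
  out <- matrix(0, n, k)
  grid <- expand.grid(rev(lapply(spatial, seq_len)))[, rev(seq_along(spatial)), drop = FALSE]
  for (r in seq_len(n)) {
    idx <- c(as.integer(grid[r, ]), list(quote(expr = )))
    out[r, ] <- do.call(`[`, c(list(arr), as.list(grid[r, ]), list(quote(expr = ))))
  }
  out
}

# triangle area in the plane: independent simplex-volume oracle for K = 3
triangle_area <- function(p) {
  abs((p[2, 1] - p[1, 1]) * (p[3, 2] - p[1, 2]) -
        (p[3, 1] - p[1, 1]) * (p[2, 2] - p[1, 2])) / 2
}
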