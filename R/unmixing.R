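# Hyperspectral unmixing under the linear mixing model: N-FINDR endmember
# extraction (maximum-simplex-volume search in a PCA projection) and fully
# constrained least-squares (FCLS) abundance estimation.

# evaluate `code` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Mean-centred PCA projection
#'
#' Projects the rows of `x` onto the top `dims` principal directions after
#' mean centring; the returned record maps any further row of the same
#' spectral space into the projection.
#'
#' @param x N x B numeric matrix (rows are spectra).
#' @param dims Number of components, `1 <= dims <= min(N, B)`.
#' @return List with `scores` (N x dims), `center` (length-B mean spectrum)
#'   and `rotation` (B x dims orthonormal loadings).
#' @export
pca_project <- function(x, dims) {
  x <- as.matrix(x)
  dims <- as.integer(dims)
  if (dims < 1L) stop("dims must be >= 1", call. = FALSE)
  if (dims > min(dim(x))) {
    stop(sprintf("dims (%d) exceeds min(N, B) = %d", dims, min(dim(x))),
      call. = FALSE
    )
  }
  ctr <- colMeans(x)
  xc <- sweep(x, 2L, ctr)
  sv <- svd(xc)
  tol <- max(dim(xc)) * .Machine$double.eps * sv$d[1L]
  rank <- sum(sv$d > tol)
  if (rank < dims) {
    stop(sprintf("data rank (%d) below requested dims (%d)", rank, dims),
      call. = FALSE
    )
  }
  rotation <- sv$v[, seq_len(dims), drop = FALSE]
  list(
    scores = xc %*% rotation,
    center = ctr,
    rotation = rotation
  )
}

#' Project rows into an existing PCA space
#' @param record A projection record from [pca_project()].
#' @param x Matrix (or vector) of rows in the original spectral space.
#' @return Matrix of scores.
#' @export
pca_transform <- function(record, x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  sweep(x, 2L, record$center) %*% record$rotation
}

# simplex volume of the k points (rows of `pts`, each of length k-1):
# |det([1; pts'])| / (k-1)!
.simplex_volume <- function(pts) {
  k <- nrow(pts)
  abs(det(rbind(rep(1, k), t(pts)))) / factorial(k - 1L)
}

#' N-FINDR endmember extraction
#'
#' Seeks the K observed pixels whose simplex has maximum volume in the
#' (K-1)-dimensional PCA projection of the data. From a random K-subset
#' (seeded), full passes over endmember slots and all pixels accept any swap
#' that strictly increases the simplex volume, until a pass makes no
#' replacement; the largest-volume solution over `n_restarts` restarts wins.
#' Correct recovery relies on the pure-pixel assumption: each endmember must
#' appear unmixed in at least one pixel.
#'
#' @param x N x B data matrix (rows are spectra).
#' @param k Number of endmembers, `2 <= k <= N`.
#' @param n_restarts Number of random restarts (default 10; the search is
#'   initialization-dependent).
#' @param seed Optional integer seed making the search deterministic.
#' @return An `endmember_set`: list with `spectra` (K x B rows of `x`),
#'   `indices` (their row indices), `volume` (achieved projected-space
#'   simplex volume) and `projection` (the PCA record).
#' @export
nfindr <- function(x, k, n_restarts = 10L, seed = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop(sprintf("k (%d) exceeds number of pixels (%d)", k, n),
    call. = FALSE
  )
  proj <- tryCatch(
    pca_project(x, k - 1L),
    error = function(e) {
      stop(sprintf("degenerate geometry: %s", conditionMessage(e)),
        call. = FALSE
      )
    }
  )
  scores <- proj$scores

  run_once <- function() {
    idx <- sample.int(n, k)
    vol <- .simplex_volume(scores[idx, , drop = FALSE])
    repeat {
      improved <- FALSE
      for (j in seq_len(k)) {
        cur <- idx
        for (i in seq_len(n)) {
          if (i %in% idx) next
          cur[j] <- i
          v <- .simplex_volume(scores[cur, , drop = FALSE])
          if (v > vol) { # strict: ties keep the incumbent, for determinism
            vol <- v
            idx <- cur
            improved <- TRUE
          } else {
            cur[j] <- idx[j]
          }
        }
      }
      if (!improved) break
    }
    list(idx = idx, vol = vol)
  }

  best <- .with_seed(seed, {
    b <- NULL
    for (r in seq_len(n_restarts)) {
      res <- run_once()
      if (is.null(b) || res$vol > b$vol) b <- res
    }
    b
  })
  if (best$vol <= 0) {
    stop("degenerate geometry: all candidate simplices have zero volume",
      call. = FALSE
    )
  }
  structure(
    list(
      spectra = x[best$idx, , drop = FALSE],
      indices = best$idx,
      volume = best$vol,
      projection = proj
    ),
    class = "endmember_set"
  )
}

#' @export
print.endmember_set <- function(x, ...) {
  cat(sprintf(
    "<endmember_set: K=%d, B=%d, simplex volume %.6g>\n",
    nrow(x$spectra), ncol(x$spectra), x$volume
  ))
  invisible(x)
}

# Lawson-Hanson active-set nonnegative least squares:
# argmin ||a x - b|| s.t. x >= 0. Robust on boundary-active solutions of the
# heavily weighted sum-to-one augmentation used by FCLS.
.nnls <- function(a, b, max_iter = 10L * ncol(a)) {
  k <- ncol(a)
  x <- rep(0, k)
  passive <- rep(FALSE, k)
  w <- as.numeric(crossprod(a, b))
  tol <- 10 * .Machine$double.eps * max(abs(w), 1) * k
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- rep(0, k)
      s[passive] <- qr.solve(a[, passive, drop = FALSE], b)
      if (all(s[passive] > 0)) {
        x <- s
        break
      }
      neg <- passive & s <= 0
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- as.numeric(crossprod(a, b - a %*% x))
  }
  x
}

#' Fully constrained least-squares (FCLS) abundance estimation
#'
#' Per pixel `y`, solves `argmin || t(E) a - y ||^2` subject to `a >= 0` and
#' `sum(a) = 1`. The sum-to-one constraint is imposed by augmenting the
#' nonnegative least-squares system with the weighted row
#' `gamma * rep(1, K) ~ gamma`, `gamma = 1000 * max column norm of t(E)`,
#' followed by exact renormalization to unit sum.
#'
#' @param x N x B data matrix (rows are pixel spectra).
#' @param endmembers An `endmember_set` from [nfindr()] or a K x B matrix of
#'   linearly independent endmember spectra, `K <= B`.
#' @return N x K abundance matrix: all entries nonnegative, every row summing
#'   to exactly 1.
#' @export
fcls <- function(x, endmembers) {
  x <- as.matrix(x)
  e <- if (inherits(endmembers, "endmember_set")) endmembers$spectra else
    as.matrix(endmembers)
  k <- nrow(e)
  if (k > ncol(e)) stop("more endmembers than bands", call. = FALSE)
  if (ncol(x) != ncol(e)) {
    stop("data and endmembers disagree on band count", call. = FALSE)
  }
  sv <- svd(e, nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1L] / sv[length(sv)] > 1e10) {
    warning("endmember matrix is poorly conditioned; abundances may be unstable",
      call. = FALSE
    )
  }
  et <- t(e) # B x K design
  gamma <- 1e3 * max(sqrt(colSums(et^2)))
  a_mat <- rbind(et, rep(gamma, k))
  n <- nrow(x)
  out <- matrix(0, n, k)
  for (i in seq_len(n)) {
    a <- tryCatch(
      .nnls(a_mat, c(x[i, ], gamma)),
      error = function(err) {
        stop(sprintf("FCLS failed at pixel %d: %s", i, conditionMessage(err)),
          call. = FALSE
        )
      }
    )
    a[a < 0 & a > -1e-9] <- 0
    s <- sum(a)
    if (s <= 0) {
      stop(sprintf("FCLS produced an all-zero abundance at pixel %d", i),
        call. = FALSE
      )
    }
    out[i, ] <- a / s
  }
  out
}

#' Unmix a spectral scene
#'
#' Flattens the container, extracts `k` endmembers with [nfindr()], estimates
#' per-pixel abundances with [fcls()] and reshapes them to the spatial grid.
#' Deterministic given `seed`.
#'
#' @param x A `spectral_container`.
#' @param k Number of endmembers.
#' @param n_restarts,seed Passed to [nfindr()].
#' @return List with `endmembers` (an `endmember_set`) and `abundances` (an
#'   array of shape `c(spatial, k)`; an N x K matrix for stacks, a length-K
#'   vector for a single spectrum).
#' @export
unmix_scene <- function(x, k, n_restarts = 10L, seed = NULL) {
  .assert_container(x)
  f <- flatten_container(x)
  em <- nfindr(f$spectra, k, n_restarts = n_restarts, seed = seed)
  ab <- fcls(f$spectra, em)
  sp <- spatial_shape(x)
  if (length(sp) == 0L) {
    ab_out <- ab[1L, ]
  } else if (length(sp) == 1L) {
    ab_out <- ab
  } else {
    ref <- x
    flat <- .new_container(ab, seq_len(k), "spectra_stack")
    ab_out <- .reshape_like(flat, ref)$intensities
  }
  list(endmembers = em, abundances = ab_out)
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L))
  }))
}

#' Match estimated endmembers to reference endmembers
#'
#' Finds the assignment of estimated to reference endmembers minimising the
#' total spectral angle distance, by exhaustive search over permutations for
#' `K <= 8` and greedily otherwise.
#'
#' @param estimated K x B matrix or `endmember_set`.
#' @param reference K x B matrix of reference (e.g. ground-truth) spectra.
#' @return List with `order` (index into the estimated rows so that
#'   `estimated[order, ]` aligns with `reference`) and `sad` (per-pair
#'   spectral angle distances after matching).
#' @export
match_endmembers <- function(estimated, reference) {
  e <- if (inherits(estimated, "endmember_set")) estimated$spectra else
    as.matrix(estimated)
  r <- as.matrix(reference)
  if (!all(dim(e) == dim(r))) stop("shape mismatch", call. = FALSE)
  k <- nrow(e)
  cost <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) cost[i, j] <- sad(e[i, ], r[j, ])
  }
  if (k <= 8L) {
    perms <- .permutations(k)
    totals <- apply(perms, 1L, function(p) sum(cost[cbind(p, seq_len(k))]))
    p <- perms[which.min(totals), ]
  } else {
    p <- integer(k)
    free <- seq_len(k)
    for (j in seq_len(k)) {
      i <- free[which.min(cost[free, j])]
      p[j] <- i
      free <- setdiff(free, i)
    }
  }
  list(order = p, sad = cost[cbind(p, seq_len(k))])
}
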