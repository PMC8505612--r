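# internal helpers

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one base seed (kept below 2^31).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Shift an array along one axis by an integer number of voxels with
# nearest-edge replication (used for separable convolution).
shiftArray <- function(a, by, axis) {
  n <- dim(a)[axis]
  idx <- pmin(pmax(seq_len(n) + by, 1L), n)
  switch(axis,
    a[idx, , , drop = FALSE],
    a[, idx, , drop = FALSE],
    a[, , idx, drop = FALSE]
  )
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels per axis),
# edge-replicated, kernel truncated at 3 sigma.
gaussSmooth3d <- function(a, sigmaVox) {
  if (length(sigmaVox) == 1L) sigmaVox <- rep(sigmaVox, 3L)
  for (axis in 1:3) {
    s <- sigmaVox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- exp(-((-r:r)^2) / (2 * s^2))
    w <- w / sum(w)
    out <- array(0, dim(a))
    for (k in seq_along(w))
      out <- out + w[k] * shiftArray(a, k - r - 1L, axis)
    a <- out
  }
  a
}

# Correlated Gaussian acquisition noise: white noise smoothed with a
# Gaussian kernel (corrLenVox = SD in voxels, emulating the scanner PSF)
# and renormalised to the requested SD. corrLenVox = 0 gives white noise.
correlatedNoise <- function(d, sigma, corrLenVox) {
  n <- array(stats::rnorm(prod(d)), d)
  if (corrLenVox > 0) {
    n <- gaussSmooth3d(n, corrLenVox)
    n <- n / stats::sd(n)
  }
  n * sigma
}

# Sliding-window box sum over a 3D array with windows clipped at the array
# boundary; returns an array of the same shape.
boxSum3d <- function(a, window) {
  r <- (window - 1L) %/% 2L
  for (axis in 1:3) {
    n <- dim(a)[axis]
    cs <- switch(axis,
      apply(a, c(2, 3), cumsum),
      aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3)),
      aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1))
    )
    # window sum over [i-r, i+r] clipped to [1, n]
    hi <- pmin(seq_len(n) + r, n)
    lo <- pmax(seq_len(n) - r, 1L) - 1L
    take <- function(x, idx, ax) switch(ax,
      x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
      x[, , idx, drop = FALSE])
    upper <- take(cs, hi, axis)
    zero <- lo == 0L
    lower <- take(cs, pmax(lo, 1L), axis)
    if (any(zero)) {
      zidx <- which(zero)
      if (axis == 1) lower[zidx, , ] <- 0
      else if (axis == 2) lower[, zidx, ] <- 0
      else lower[, , zidx] <- 0
    }
    a <- upper - lower
  }
  a
}
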