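# Fixture builders and independent reference (oracle) implementations used
# across the test files. All fixtures are generated in code under fixed
# seeds; nothing is read from disk.

# small random image + ellipsoidal mask on an n^3 grid
randomLesion <- function(n = 12, seed = 1, sd = 50, maskKind = c("box", "ellipsoid")) {
  maskKind <- match.arg(maskKind)
  set.seed(seed)
  d <- rep(n, 3)
  img <- ImageVolume(array(rnorm(prod(d), sd = sd), d))
  m <- array(0, d)
  if (maskKind == "box") {
    lo <- max(2, round(n / 4)); hi <- n - lo + 1
    m[lo:hi, lo:hi, lo:hi] <- 1
  } else {
    c0 <- (n + 1) / 2
    r <- sqrt(outer(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`),
                    (seq_len(n) - c0)^2, `+`))
    m[r <= n / 2 - 1.5] <- 1
  }
  list(image = img, mask = ImageVolume(m))
}

# smooth random map pair defined on a mask (NA outside), normalized jointly
smoothMapPair <- function(n = 16, seed = 1, noise = 0.15) {
  set.seed(seed)
  d <- rep(n, 3)
  base <- habitatlab:::gaussSmooth3d(array(rnorm(prod(d)), d), 1.5)
  pert <- base + noise * habitatlab:::gaussSmooth3d(array(rnorm(prod(d)), d), 1)
  c0 <- (n + 1) / 2
  r <- sqrt(outer(outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`),
                  (seq_len(n) - c0)^2, `+`))
  m <- r <= n / 2 - 1.5
  a <- array(NA_real_, d); a[m] <- base[m]
  b <- array(NA_real_, d); b[m] <- pert[m]
  nrm <- normalizePair(a, b, m)
  list(ref = nrm$a, eval = nrm$b, mask = m)
}

# independent naive voxel-wise extraction: fresh GLCM per voxel via the R
# reference path, no caching
naiveFeatureMaps <- function(image, mask, params) {
  disc <- discretizeVolume(image, mask, params@binWidth)
  m <- maskArray(mask)
  d <- dim(m)
  R <- params@kernelRadius
  idx <- which(m, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(idx), 23,
                dimnames = list(NULL, glcmFeatureNames()))
  for (r in seq_len(nrow(idx))) {
    v <- idx[r, ]
    kern <- array(FALSE, d)
    lo <- pmax(v - R, 1); hi <- pmin(v + R, d)
    kern[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    stack <- glcmFromRegion(disc$gray, kern, disc$ng,
                            distance = params@distance,
                            mask = if (params@maskedKernel) m else NULL)
    out[r, ] <- glcmFeatures(stack)
  }
  out
}

# exhaustive brute-force gamma oracle: full trilinearly upsampled lattice,
# no search cap, vectorized over sample positions
bruteForceGamma <- function(refMap, evalMap, mask, dtaMm, dfPercent,
                            factor = 3, spacing = 1) {
  d <- dim(refMap)
  fmax <- max(refMap[mask], na.rm = TRUE)
  deltaF <- dfPercent / 100 * fmax
  up <- (d - 1) * factor + 1
  # upsampled lattice coordinates (0-based voxel units of the coarse grid)
  ax <- (seq_len(up[1]) - 1) / factor
  ay <- (seq_len(up[2]) - 1) / factor
  az <- (seq_len(up[3]) - 1) / factor
  # independent trilinear interpolation over the full lattice; a sample is
  # NA when any corner carrying positive weight is NA (zero-weight corners
  # do not contribute, so exact-lattice points reduce to one corner)
  grid <- expand.grid(x = ax, y = ay, z = az)
  ix <- floor(grid$x); iy <- floor(grid$y); iz <- floor(grid$z)
  tx <- grid$x - ix; ty <- grid$y - iy; tz <- grid$z - iz
  acc <- rep(0, nrow(grid)); bad <- rep(FALSE, nrow(grid))
  for (cz in 0:1) for (cy in 0:1) for (cx in 0:1) {
    wx <- if (cx) tx else 1 - tx
    wy <- if (cy) ty else 1 - ty
    wz <- if (cz) tz else 1 - tz
    w <- wx * wy * wz
    use <- w > 0
    if (!any(use)) next
    vals <- evalMap[cbind(pmin(ix[use] + cx + 1, d[1]),
                          pmin(iy[use] + cy + 1, d[2]),
                          pmin(iz[use] + cz + 1, d[3]))]
    bad[use] <- bad[use] | is.na(vals)
    vals[is.na(vals)] <- 0
    acc[use] <- acc[use] + w[use] * vals
  }
  evalU <- ifelse(bad, NA_real_, acc)
  keep <- !is.na(evalU)
  ux <- grid$x[keep] * spacing
  uy <- grid$y[keep] * spacing
  uz <- grid$z[keep] * spacing
  ev <- evalU[keep]
  out <- array(NA_real_, d)
  vox <- which(mask & !is.na(refMap), arr.ind = TRUE)
  for (r in seq_len(nrow(vox))) {
    v <- (vox[r, ] - 1) * spacing
    g2 <- ((ux - v[1])^2 + (uy - v[2])^2 + (uz - v[3])^2) / dtaMm^2 +
      (ev - refMap[vox[r, 1], vox[r, 2], vox[r, 3]])^2 / deltaF^2
    out[vox[r, 1], vox[r, 2], vox[r, 3]] <- sqrt(min(g2))
  }
  out
}

# direct per-window SSIM reference (population moments, clipped windows)
referenceSSIM <- function(mapA, mapB, mask, window = 7, k1 = 0.01,
                          k2 = 0.03, L = 1) {
  d <- dim(mapA)
  r <- (window - 1) %/% 2
  fin <- is.finite(mapA) & is.finite(mapB)
  c1 <- (k1 * L)^2; c2 <- (k2 * L)^2
  vox <- which(mask & fin, arr.ind = TRUE)
  vals <- numeric(nrow(vox))
  for (i in seq_len(nrow(vox))) {
    v <- vox[i, ]
    lo <- pmax(v - r, 1); hi <- pmin(v + r, d)
    wa <- mapA[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    wb <- mapB[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    ok <- is.finite(wa) & is.finite(wb)
    wa <- wa[ok]; wb <- wb[ok]
    n <- length(wa)
    mua <- mean(wa); mub <- mean(wb)
    va <- mean((wa - mua)^2); vb <- mean((wb - mub)^2)
    cab <- mean((wa - mua) * (wb - mub))
    vals[i] <- ((2 * mua * mub + c1) * (2 * cab + c2)) /
      ((mua^2 + mub^2 + c1) * (va + vb + c2))
  }
  mean(vals)
}

# adjusted Rand index between two integer label vectors
adjustedRandIndex <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_ <- si * sj / n
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
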