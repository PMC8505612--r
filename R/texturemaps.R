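#' Names of the supported GLCM features
#'
#' The 23 gray-level co-occurrence matrix features computed by this package
#' (the maximal correlation coefficient is not supported). Order is fixed
#' and alphabetical.
#'
#' @return Character vector of length 23.
#' @export
glcmFeatureNames <- function() {
  c("Autocorrelation", "ClusterProminence", "ClusterShade",
    "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
    "DifferenceEntropy", "DifferenceVariance", "Id", "Idm", "Idmn", "Idn",
    "Imc1", "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
    "JointEntropy", "MaximumProbability", "SumAverage", "SumEntropy",
    "SumSquares")
}

#' The nine repeatable-and-reproducible GLCM features
#'
#' The entropy/energy-family subset selected as both repeatable (test-retest)
#' and reproducible (across extraction parameters) for robust habitat
#' computation.
#'
#' @return Character vector of length 9.
#' @export
robustFeatureNames <- function() {
  c("JointEnergy", "JointEntropy", "SumEntropy", "MaximumProbability",
    "DifferenceEntropy", "Imc1", "Imc2", "Idn", "Idmn")
}

#' The 13 unique 3D co-occurrence directions
#'
#' One offset per unordered 26-neighbourhood direction pair; with symmetric
#' pair counting these cover all 26 neighbours.
#'
#' @return Integer 13 x 3 matrix of (dx, dy, dz) offsets.
#' @export
glcmDirections <- function() {
  m <- rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
    c(0, 1, 1), c(0, 1, -1),
    c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(-1, 1, 1)
  )
  storage.mode(m) <- "integer"
  m
}

#' Discretize an image with a fixed bin width
#'
#' Bin index `g(x) = floor((x - min_mask) / B) + 1`, anchored at the minimum
#' intensity over the in-mask voxels and applied to the whole padded crop;
#' `ng` is the maximum bin over the mask. Out-of-mask voxels are clamped
#' into `[1, ng]` so a single global gray-level table serves every kernel.
#'
#' @param image An [ImageVolume-class] (preprocessed crop).
#' @param mask Binary lesion mask on the same grid.
#' @param binWidthHu Bin width B in HU (> 0).
#' @return A list with `gray` (3D integer array of bin indices) and `ng`.
#' @examples
#' img <- ImageVolume(array(c(0, 11.9, 12, 25, rep(0, 4)), c(2, 2, 2)))
#' msk <- ImageVolume(array(1, c(2, 2, 2)))
#' discretizeVolume(img, msk, 12)$ng   # 3
#' @export
discretizeVolume <- function(image, mask, binWidthHu) {
  if (binWidthHu <= 0) stop("binWidthHu must be > 0")
  checkSameGrid(image, mask)
  m <- maskArray(mask)
  v <- voxelData(image)
  minMask <- min(v[m])
  gray <- floor((v - minMask) / binWidthHu) + 1
  ng <- as.integer(max(gray[m]))
  gray <- pmin(pmax(gray, 1), ng)
  storage.mode(gray) <- "integer"
  list(gray = array(gray, dim(v)), ng = ng)
}

#' Build per-direction GLCMs from a voxel region
#'
#' Counts symmetric co-occurrences (each ordered pair counted in both
#' orders) between voxels that are both inside `region`, for each direction
#' offset at distance `distance`. Per-direction matrices are retained so
#' features can be averaged over directions.
#'
#' @param gray 3D integer array of bin indices (from [discretizeVolume()]).
#' @param region Logical 3D array: the voxel set to draw pairs from (a
#'   kernel footprint, or the whole mask for VOI-wise features).
#' @param ng Number of gray levels.
#' @param distance Offset distance \eqn{\delta} in voxels (default 1).
#' @param mask Optional logical array; when given, both pair endpoints must
#'   additionally lie inside it (masked-kernel mode).
#' @param directions Integer matrix of offsets (default [glcmDirections()]).
#' @return A `glcmStack`: list with `p` (ng x ng x nDirections array of
#'   joint probabilities, each slice summing to 1 where pairs exist),
#'   `npairs` (unordered pair count per direction) and `ng`.
#' @export
glcmFromRegion <- function(gray, region, ng, distance = 1L, mask = NULL,
                           directions = glcmDirections()) {
  if (!any(region)) stop("region is empty")
  d <- dim(gray)
  nd <- nrow(directions)
  p <- array(0, c(ng, ng, nd))
  npairs <- numeric(nd)
  for (k in seq_len(nd)) {
    off <- directions[k, ] * distance
    xs <- seq.int(max(1L, 1L - off[1]), min(d[1], d[1] - off[1]))
    ys <- seq.int(max(1L, 1L - off[2]), min(d[2], d[2] - off[2]))
    zs <- seq.int(max(1L, 1L - off[3]), min(d[3], d[3] - off[3]))
    if (!length(xs) || !length(ys) || !length(zs)) next
    ok <- region[xs, ys, zs, drop = FALSE] &
      region[xs + off[1], ys + off[2], zs + off[3], drop = FALSE]
    if (!is.null(mask))
      ok <- ok & mask[xs, ys, zs, drop = FALSE] &
        mask[xs + off[1], ys + off[2], zs + off[3], drop = FALSE]
    if (!any(ok)) next
    ga <- gray[xs, ys, zs, drop = FALSE][ok]
    gb <- gray[xs + off[1], ys + off[2], zs + off[3], drop = FALSE][ok]
    tab <- tabulate(ga + (gb - 1L) * ng, nbins = ng * ng)
    m <- matrix(tab, ng, ng)
    m <- m + t(m)
    npairs[k] <- length(ga)
    p[, , k] <- m / sum(m)
  }
  structure(list(p = p, npairs = npairs, ng = ng), class = "glcmStack")
}

#' Compute the 23 GLCM features from a co-occurrence matrix
#'
#' Reference implementation of the feature formulas using the standard
#' marginals \eqn{p_x, p_y, p_{x+y}, p_{x-y}} and the entropies HX, HY,
#' HXY, HXY1, HXY2, with \eqn{\epsilon = 2.2 \times 10^{-16}} inside base-2
#' logarithms. Given a `glcmStack`, features are computed per direction and
#' averaged over the directions that contain at least one pair (all-zero if
#' none do).
#'
#' Degenerate single-level matrices (ng = 1) follow the documented
#' conventions: entropy-family features 0, Imc1 0, Imc2 0, correlation 1,
#' maximum probability 1, joint energy 1.
#'
#' @param glcm A square joint-probability matrix, or a `glcmStack` from
#'   [glcmFromRegion()].
#' @return Named numeric vector over [glcmFeatureNames()].
#' @export
glcmFeatures <- function(glcm) {
  if (inherits(glcm, "glcmStack")) {
    use <- which(glcm$npairs > 0)
    if (!length(use)) {
      out <- rep(0, 23)
      names(out) <- glcmFeatureNames()
      return(out)
    }
    acc <- rep(0, 23)
    for (k in use) acc <- acc + glcmFeaturesFromMatrix(glcm$p[, , k])
    out <- acc / length(use)
    names(out) <- glcmFeatureNames()
    return(out)
  }
  glcmFeaturesFromMatrix(glcm)
}

# single-matrix feature computation (the formula transcription)
glcmFeaturesFromMatrix <- function(p) {
  eps <- 2.2e-16
  p <- as.matrix(p)
  ng <- nrow(p)
  stopifnot(ncol(p) == ng)
  s <- sum(p)
  if (abs(s - 1) > 1e-9) stop("GLCM must sum to 1")
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(i * p)
  muy <- sum(j * p)
  sx2 <- sum((i - mux)^2 * p)
  sy2 <- sum((j - muy)^2 * p)
  psum <- vapply(2:(2 * ng), function(k) sum(p[i + j == k]), numeric(1))
  pdiff <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  hx <- -sum(px[px > 0] * log2(px[px > 0] + eps))
  hy <- -sum(py[py > 0] * log2(py[py > 0] + eps))
  hxy <- -sum(p[p > 0] * log2(p[p > 0] + eps))
  pp <- outer(px, py)
  hxy1 <- -sum(p[p > 0] * log2(pp[p > 0] + eps))
  hxy2 <- -sum(pp[pp > 0] * log2(pp[pp > 0] + eps))
  diffAvg <- sum((0:(ng - 1)) * pdiff)
  kd <- 0:(ng - 1)
  ks <- 2:(2 * ng)
  out <- c(
    Autocorrelation = sum(i * j * p),
    ClusterProminence = sum((i + j - mux - muy)^4 * p),
    ClusterShade = sum((i + j - mux - muy)^3 * p),
    ClusterTendency = sum((i + j - mux - muy)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = if (sx2 * sy2 > eps)
      (sum(i * j * p) - mux * muy) / sqrt(sx2 * sy2) else 1,
    DifferenceAverage = diffAvg,
    DifferenceEntropy = -sum(pdiff[pdiff > 0] *
                               log2(pdiff[pdiff > 0] + eps)),
    DifferenceVariance = sum((kd - diffAvg)^2 * pdiff),
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = if (ng > 1)
      sum(pdiff[-1] / (seq_len(ng - 1))^2) else 0,
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    SumAverage = sum(ks * psum),
    SumEntropy = -sum(psum[psum > 0] * log2(psum[psum > 0] + eps)),
    SumSquares = sx2
  )
  out[glcmFeatureNames()]
}

#' Compute voxel-wise GLCM feature maps
#'
#' For every in-mask voxel, a symmetric GLCM is built over the cubic kernel
#' of edge `2R + 1` centred at that voxel (clipped to the padded crop; by
#' default the kernel draws on all crop voxels, see
#' [extractionParams()]`$maskedKernel`), the features are evaluated per
#' direction and averaged over the 13 directions, and the value is written
#' at the voxel. Deterministic; the discretization is global (one bin table
#' for the whole lesion).
#'
#' @param image Preprocessed (isotropic, cropped) [ImageVolume-class].
#' @param mask Binary lesion mask on the same grid.
#' @param params An [ExtractionParams-class].
#' @param sourceId Provenance tag stored in the result.
#' @return A [FeatureMapSet-class]; each map is finite on the mask and `NA`
#'   elsewhere.
#' @export
computeFeatureMaps <- function(image, mask, params = extractionParams(),
                               sourceId = "") {
  checkSameGrid(image, mask)
  disc <- discretizeVolume(image, mask, params@binWidth)
  m <- maskArray(mask)
  d <- dim(m)
  vals <- cpp_feature_maps(as.integer(disc$gray), as.logical(m), d,
                           disc$ng, glcmDirections(), params@kernelRadius,
                           params@distance, params@maskedKernel)
  colnames(vals) <- glcmFeatureNames()
  idx <- which(m)
  maps <- lapply(params@featureList, function(f) {
    a <- array(NA_real_, d)
    a[idx] <- vals[, f]
    a
  })
  names(maps) <- params@featureList
  new("FeatureMapSet", maps = maps, params = params,
      sourceId = as.character(sourceId), spacing = spacingMm(image))
}

#' Compute VOI-wise (single-value) GLCM features
#'
#' One GLCM over all in-mask voxels (pairs with both endpoints inside the
#' mask), features computed per direction and averaged, yielding one scalar
#' per feature for the whole lesion.
#'
#' @inheritParams computeFeatureMaps
#' @return Named numeric vector over `params@featureList`.
#' @export
voiFeatures <- function(image, mask, params = extractionParams()) {
  checkSameGrid(image, mask)
  disc <- discretizeVolume(image, mask, params@binWidth)
  m <- maskArray(mask)
  stack <- glcmFromRegion(disc$gray, m, disc$ng, distance = params@distance)
  glcmFeatures(stack)[params@featureList]
}

#' Jointly normalize a pair of feature maps to the unit interval
#'
#' Applies one affine min--max rescaling, computed over the union of the
#' in-mask values of both maps, to both maps, so paired test/retest maps
#' stay on a common scale. A constant joint range sets both maps to 0.
#'
#' @param mapA,mapB 3D arrays (finite on the mask, `NA` elsewhere).
#' @param mask Optional logical array or binary [ImageVolume-class]
#'   restricting the voxels considered; defaults to the finite voxels.
#' @return List with rescaled `a` and `b` and the original `range`.
#' @export
normalizePair <- function(mapA, mapB, mask = NULL) {
  sel <- if (is.null(mask)) is.finite(mapA) & is.finite(mapB)
         else if (is(mask, "ImageVolume")) maskArray(mask)
         else mask
  vals <- c(mapA[sel], mapB[sel])
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no finite in-mask values to normalize")
  rng <- range(vals)
  if (diff(rng) == 0) {
    mapA[sel] <- 0
    mapB[sel] <- 0
  } else {
    mapA <- (mapA - rng[1]) / diff(rng)
    mapB <- (mapB - rng[1]) / diff(rng)
  }
  list(a = mapA, b = mapB, range = rng)
}

#' Jointly normalize two feature-map sets feature by feature
#'
#' @param setA,setB [FeatureMapSet-class] objects sharing feature names.
#' @param mask Binary mask ([ImageVolume-class] or logical array).
#' @return List of two normalized `FeatureMapSet`s (`a`, `b`).
#' @export
normalizePairSets <- function(setA, setB, mask) {
  common <- intersect(mapNames(setA), mapNames(setB))
  if (!setequal(mapNames(setA), mapNames(setB)))
    stop("feature-map sets must share feature names")
  outA <- setA@maps
  outB <- setB@maps
  for (f in common) {
    nrm <- normalizePair(outA[[f]], outB[[f]], mask)
    outA[[f]] <- nrm$a
    outB[[f]] <- nrm$b
  }
  list(a = initialize(setA, maps = outA), b = initialize(setB, maps = outB))
}
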