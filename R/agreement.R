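#' Concordance correlation coefficient
#'
#' Lin's concordance between paired measurements, using population
#' (divide-by-n) moments:
#' \deqn{CCC = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)}
#' Perfect concordance requires both correlation 1 and an identity line
#' through the origin. Conventions: both inputs constant and equal gives 1;
#' a single constant input otherwise gives 0.
#'
#' @param x,y Paired numeric vectors of equal length (>= 2 pairs); `NA`
#'   pairs are dropped.
#' @return CCC in `[-1, 1]`.
#' @examples
#' ccc(c(0, 1, 2), c(1, 2, 3))   # 4/7
#' @export
ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) stop("need at least 2 finite pairs")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den == 0) return(1)          # both constant and equal
  2 * cxy / den
}

#' Pearson correlation of paired maps
#'
#' Standard Pearson correlation with the convention that a constant input
#' yields 0 (no linear covariation measurable).
#'
#' @inheritParams ccc
#' @return PCORR in `[-1, 1]`.
#' @export
pcorr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("need at least 2 finite pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}

#' Mean structural similarity between two 3D maps
#'
#' Mean over in-mask voxels of the local SSIM computed in a cubic uniform
#' window (edge `window`, clipped at the crop boundary), with the standard
#' constants \eqn{C_1 = (k_1 L)^2}, \eqn{C_2 = (k_2 L)^2}. Maps are
#' expected normalized to `[0, 1]` so the dynamic range L is 1. Voxels
#' where either map is `NA` are excluded from every window.
#'
#' @param mapA,mapB 3D arrays on a common grid (`NA` outside the mask).
#' @param mask Logical array or binary [ImageVolume-class] over which the
#'   local SSIM is averaged.
#' @param window Cubic window edge in voxels (odd, default 7).
#' @param k1,k2 Stability constants (0.01, 0.03).
#' @param L Dynamic range (default 1).
#' @return Mean SSIM in `[-1, 1]`; 1 iff the maps agree on the mask.
#' @export
ssim3d <- function(mapA, mapB, mask, window = 7L, k1 = 0.01, k2 = 0.03,
                   L = 1) {
  m <- if (is(mask, "ImageVolume")) maskArray(mask) else mask
  fin <- is.finite(mapA) & is.finite(mapB)
  a <- ifelse(fin, mapA, 0)
  b <- ifelse(fin, mapB, 0)
  w <- array(as.numeric(fin), dim(a))
  n <- boxSum3d(w, window)
  sa <- boxSum3d(a, window)
  sb <- boxSum3d(b, window)
  saa <- boxSum3d(a * a, window)
  sbb <- boxSum3d(b * b, window)
  sab <- boxSum3d(a * b, window)
  mua <- sa / n
  mub <- sb / n
  va <- saa / n - mua^2
  vb <- sbb / n - mub^2
  cab <- sab / n - mua * mub
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  ssim <- ((2 * mua * mub + c1) * (2 * cab + c2)) /
    ((mua^2 + mub^2 + c1) * (va + vb + c2))
  mean(ssim[m & fin])
}

#' Gamma-index map between a reference and an evaluated feature map
#'
#' For each in-mask reference voxel v, the gamma index is the minimum over
#' nearby sample positions u of
#' \deqn{\sqrt{\|u - v\|^2 / DTA^2 + (F_{eval}(u) - F_{ref}(v))^2 / \Delta F^2}}
#' with \eqn{\Delta F} the feature-difference criterion as a percentage of
#' the reference map's in-mask maximum `F_max`. The evaluated map is
#' sampled on a trilinearly upsampled sub-voxel lattice; a voxel whose
#' search region contains no valid sample is returned as `NA` (invalid).
#'
#' @param refMap,evalMap 3D arrays on a common grid, jointly normalized
#'   (`NA` outside the mask).
#' @param mask Logical array or binary [ImageVolume-class].
#' @param crit A [gammaCriterion()].
#' @param spacingMm Voxel spacing in mm (length 1 or 3).
#' @return 3D array of gamma values (`NA` outside the mask and at invalid
#'   voxels).
#' @export
gammaMap <- function(refMap, evalMap, mask, crit = gammaCriterion(),
                     spacingMm = 1) {
  m <- if (is(mask, "ImageVolume")) maskArray(mask) else mask
  stopifnot(identical(dim(refMap), dim(evalMap)),
            identical(dim(refMap), dim(m)))
  if (length(spacingMm) == 1L) spacingMm <- rep(spacingMm, 3L)
  fmax <- if (is.na(crit@fMax)) {
    rv <- refMap[m]
    max(rv[is.finite(rv)])
  } else crit@fMax
  if (!is.finite(fmax) || fmax <= 0)
    stop("F_max of the reference map is not positive; gamma criterion undefined")
  deltaF <- crit@dfPercent / 100 * fmax
  out <- cpp_gamma_map(as.numeric(refMap), as.numeric(evalMap),
                       as.logical(m), dim(refMap), spacingMm, crit@dtaMm,
                       deltaF, crit@searchCapMm, crit@upsampleFactor)
  array(out, dim(refMap))
}

#' Gamma passing rate
#'
#' Percentage of valid in-mask voxels with gamma index < 1.
#'
#' @param gammaVol Output of [gammaMap()].
#' @param mask Logical array or binary [ImageVolume-class].
#' @return Passing rate in percent (0--100); invalid voxels are excluded
#'   from the denominator.
#' @export
gammaPassingRate <- function(gammaVol, mask) {
  m <- if (is(mask, "ImageVolume")) maskArray(mask) else mask
  g <- gammaVol[m]
  g <- g[is.finite(g)]
  if (!length(g)) stop("no valid gamma voxels in the mask")
  100 * mean(g < 1)
}

#' Dice similarity coefficient for one label
#'
#' \eqn{DSC_k = 2 |A_k \cap B_k| / (|A_k| + |B_k|)} over in-mask voxels.
#'
#' @param labelsA,labelsB Integer 3D arrays or [HabitatMap-class] objects.
#' @param mask Logical array or binary [ImageVolume-class].
#' @param label The label value to score.
#' @return DSC in `[0, 1]`; `NaN` when the label is absent from both maps.
#' @export
dsc <- function(labelsA, labelsB, mask, label) {
  la <- if (is(labelsA, "HabitatMap")) habitatLabels(labelsA) else labelsA
  lb <- if (is(labelsB, "HabitatMap")) habitatLabels(labelsB) else labelsB
  m <- if (is(mask, "ImageVolume")) maskArray(mask) else mask
  a <- la[m] == label
  b <- lb[m] == label
  if (!any(a) && !any(b)) return(NaN)
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Lesion-level mean Dice over habitat labels
#'
#' Unweighted mean of the per-label DSC over the labels present in at least
#' one of the two maps (a label absent from both is excluded). With
#' `match = "best"`, labels of `labelsB` are first permuted to maximize the
#' total overlap (useful for externally produced label maps whose cluster
#' identities do not correspond by construction).
#'
#' @inheritParams dsc
#' @param k Number of labels (defaults to the maximum label present).
#' @param match `"none"` (labels correspond already) or `"best"`
#'   (exhaustive permutation matching, k <= 8).
#' @return Mean DSC in `[0, 1]`.
#' @export
meanDsc <- function(labelsA, labelsB, mask, k = NULL, match = c("none", "best")) {
  match <- match.arg(match)
  la <- if (is(labelsA, "HabitatMap")) habitatLabels(labelsA) else labelsA
  lb <- if (is(labelsB, "HabitatMap")) habitatLabels(labelsB) else labelsB
  m <- if (is(mask, "ImageVolume")) maskArray(mask) else mask
  if (is.null(k)) k <- max(la[m], lb[m])
  if (match == "best") {
    if (k > 8) stop("permutation matching supports k <= 8")
    perms <- permutations(k)
    best <- -Inf
    bestLb <- lb
    for (pi in seq_len(nrow(perms))) {
      relab <- array(0L, dim(lb))
      sel <- m & lb > 0
      relab[sel] <- perms[pi, lb[sel]]
      ov <- sum(la[m] == relab[m] & la[m] > 0)
      if (ov > best) {
        best <- ov
        bestLb <- relab
      }
    }
    lb <- bestLb
  }
  vals <- vapply(seq_len(k), function(lab) dsc(la, lb, m, lab), numeric(1))
  mean(vals[!is.nan(vals)])
}

# all permutations of 1..k as a matrix (k! x k)
permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Rank features by repeatability and select the repeatable set
#'
#' Computes per-feature medians across lesions and classifies features as
#' repeatable by fixed thresholds: median CCC > `cccThreshold` and/or
#' median gamma passing rate > `gammaThreshold`. Ordering is by decreasing
#' median with alphabetical tie-break.
#'
#' @param table A tidy agreement table (data frame) with columns `feature`,
#'   `lesion`, `metric`, `value`; metrics `"ccc"` and `"gamma_pass"` are
#'   used when present.
#' @param cccThreshold Median-CCC threshold (default 0.9).
#' @param gammaThreshold Median gamma passing-rate threshold in percent
#'   (default 95).
#' @return A list with `ranking` (tibble: feature, medianCCC, medianGamma,
#'   ordered), `repeatableByCCC` and `repeatableByGamma` (character
#'   vectors).
#' @export
rankFeatures <- function(table, cccThreshold = 0.9, gammaThreshold = 95) {
  empty <- list(
    ranking = tibble::tibble(feature = character(), medianCCC = numeric(),
                             medianGamma = numeric()),
    repeatableByCCC = character(),
    repeatableByGamma = character())
  if (!nrow(table)) return(empty)
  med <- function(metricName) {
    rows <- table[table$metric == metricName, , drop = FALSE]
    if (!nrow(rows)) return(numeric())
    tapply(rows$value, rows$feature, stats::median)
  }
  mc <- med("ccc")
  mg <- med("gamma_pass")
  feats <- sort(unique(table$feature))
  ranking <- tibble::tibble(
    feature = feats,
    medianCCC = as.numeric(mc[feats]),
    medianGamma = as.numeric(mg[feats])
  )
  keyCol <- if (all(is.na(ranking$medianCCC))) "medianGamma" else "medianCCC"
  key <- ranking[[keyCol]]
  ord <- order(-ifelse(is.na(key), -Inf, key), ranking$feature)
  ranking <- ranking[ord, ]
  list(
    ranking = ranking,
    repeatableByCCC = sort(ranking$feature[!is.na(ranking$medianCCC) &
                                             ranking$medianCCC > cccThreshold]),
    repeatableByGamma = sort(ranking$feature[!is.na(ranking$medianGamma) &
                                               ranking$medianGamma > gammaThreshold])
  )
}

#' Agreement of paired feature maps
#'
#' Computes the requested metrics between two feature-map sets on a common
#' mask, after joint per-feature normalization to `[0, 1]`.
#'
#' @param setTest,setRetest [FeatureMapSet-class] objects sharing features.
#' @param mask Binary mask.
#' @param lesionId Identifier written into the table.
#' @param metrics Subset of `c("ccc", "pcorr", "ssim", "gamma_pass")`.
#' @param crit [gammaCriterion()] for the gamma metrics.
#' @return Tidy tibble: feature, lesion, B, R, metric, value.
#' @export
agreementTable <- function(setTest, setRetest, mask, lesionId = "lesion",
                           metrics = c("ccc", "pcorr", "ssim", "gamma_pass"),
                           crit = gammaCriterion()) {
  m <- maskArray(mask)
  nrm <- normalizePairSets(setTest, setRetest, mask)
  sp <- setTest@spacing
  rows <- list()
  for (f in mapNames(setTest)) {
    a <- featureMap(nrm$a, f)
    b <- featureMap(nrm$b, f)
    vals <- c()
    if ("ccc" %in% metrics) vals["ccc"] <- ccc(a[m], b[m])
    if ("pcorr" %in% metrics) vals["pcorr"] <- pcorr(a[m], b[m])
    if ("ssim" %in% metrics) vals["ssim"] <- ssim3d(a, b, m)
    if ("gamma_pass" %in% metrics) {
      fmaxA <- suppressWarnings(max(a[m], na.rm = TRUE))
      vals["gamma_pass"] <- if (is.finite(fmaxA) && fmaxA > 0)
        gammaPassingRate(gammaMap(a, b, m, crit, sp), m) else NA_real_
    }
    rows[[f]] <- tibble::tibble(
      feature = f, lesion = lesionId,
      B = setTest@params@binWidth, R = setTest@params@kernelRadius,
      metric = names(vals), value = as.numeric(vals))
  }
  do.call(rbind, rows)
}

#' Reproducibility of features across extraction parameters
#'
#' For every (B, R) combination in the grid, extracts test and retest
#' feature maps, jointly normalizes them, and computes the per-feature CCC,
#' per lesion. Per-combination and pooled per-feature medians/IQRs are
#' available through [agreementSummary()].
#'
#' @param lesions List of lesions; each element a list with `test` and
#'   `retest` ([ImageVolume-class], preprocessed crops), `mask`, and
#'   optionally `id`.
#' @param binWidths,kernelRadii Numeric grids of B (HU) and R (voxels).
#' @param features Feature names to extract.
#' @param maskedKernel Passed to [extractionParams()].
#' @return Tidy tibble: feature, lesion, B, R, metric (`"ccc"`), value.
#' @export
reproducibilityGrid <- function(lesions, binWidths = c(12, 25),
                                kernelRadii = c(1, 3, 5),
                                features = glcmFeatureNames(),
                                maskedKernel = FALSE) {
  rows <- list()
  for (li in seq_along(lesions)) {
    les <- lesions[[li]]
    id <- if (!is.null(les$id)) les$id else paste0("lesion", li)
    for (B in binWidths) for (R in kernelRadii) {
      params <- extractionParams(binWidth = B, kernelRadius = R,
                                 maskedKernel = maskedKernel,
                                 featureList = features)
      st <- computeFeatureMaps(les$test, les$mask, params, paste0(id, "_test"))
      sr <- computeFeatureMaps(les$retest, les$mask, params,
                               paste0(id, "_retest"))
      rows[[length(rows) + 1L]] <-
        agreementTable(st, sr, les$mask, id, metrics = "ccc")
    }
  }
  do.call(rbind, rows)
}

#' Summarize an agreement table
#'
#' Per-feature medians and IQRs, per (B, R) combination and pooled across
#' all combinations and lesions.
#'
#' @param table Output of [reproducibilityGrid()] or [agreementTable()].
#' @param metric Metric to summarize (default `"ccc"`).
#' @return List with `perCombo` and `pooled` tibbles.
#' @export
agreementSummary <- function(table, metric = "ccc") {
  tab <- table[table$metric == metric, , drop = FALSE]
  splitKey <- interaction(tab$feature, tab$B, tab$R, drop = TRUE)
  perCombo <- do.call(rbind, lapply(split(tab, splitKey), function(g) {
    tibble::tibble(feature = g$feature[1], B = g$B[1], R = g$R[1],
                   median = stats::median(g$value),
                   iqr = stats::IQR(g$value), n = nrow(g))
  }))
  pooled <- do.call(rbind, lapply(split(tab, tab$feature), function(g) {
    tibble::tibble(feature = g$feature[1],
                   median = stats::median(g$value),
                   iqr = stats::IQR(g$value), n = nrow(g))
  }))
  pooled <- pooled[order(-pooled$median, pooled$feature), ]
  rownames(perCombo) <- rownames(pooled) <- NULL
  list(perCombo = perCombo, pooled = pooled)
}
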