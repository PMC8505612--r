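#' Configuration for imaging-habitat computation
#'
#' Habitats are computed by PCA on the voxel-by-feature matrix followed by
#' K-means clustering of the leading principal-component scores.
#'
#' @param k Cluster count (>= 2; 3 and 5 are the usual choices).
#' @param nComponents Principal components retained (default 5).
#' @param featureSelection `"all"`, `"robust"` (the nine
#'   [robustFeatureNames()]), or an explicit character vector.
#' @param kmeansSeed Seed for the K-means starts.
#' @param nInit Number of random K-means starts (default 10).
#' @param maxIter Maximum K-means iterations (default 300).
#' @param fitMode `"pooled"` (PCA and K-means fitted on the row-stacked
#'   test+retest matrices, so cluster identities correspond by
#'   construction) or `"fit-on-test"` (model fitted on test rows, retest
#'   rows projected and assigned to the nearest centroid).
#' @return A `habitatConfig` list.
#' @export
habitatConfig <- function(k = 3L, nComponents = 5L,
                          featureSelection = "robust", kmeansSeed = 1L,
                          nInit = 10L, maxIter = 300L,
                          fitMode = c("pooled", "fit-on-test")) {
  fitMode <- match.arg(fitMode)
  if (k < 2) stop("k must be >= 2")
  if (nComponents < 1) stop("nComponents must be >= 1")
  structure(list(k = as.integer(k), nComponents = as.integer(nComponents),
                 featureSelection = featureSelection,
                 kmeansSeed = as.integer(kmeansSeed),
                 nInit = as.integer(nInit), maxIter = as.integer(maxIter),
                 fitMode = fitMode),
            class = "habitatConfig")
}

# resolve a feature selection keyword to concrete names
resolveSelection <- function(selection, available) {
  sel <- if (identical(selection, "all")) available
         else if (identical(selection, "robust")) robustFeatureNames()
         else selection
  missing <- setdiff(sel, available)
  if (length(missing))
    stop("requested feature(s) not available: ",
         paste(missing, collapse = ", "))
  sel
}

#' Build paired voxel-by-feature matrices from two feature-map sets
#'
#' Rows are the in-mask voxels in fixed raster (column-major) order,
#' columns the selected features; values are pair-normalized to `[0, 1]`
#' (one affine map per feature shared by both scans).
#'
#' @param setTest,setRetest [FeatureMapSet-class] pair sharing features and
#'   mask.
#' @param mask Binary mask.
#' @param selection `"all"`, `"robust"`, or explicit feature names.
#' @return List with matrices `test` and `retest` (voxels x features).
#' @export
buildFeatureMatrix <- function(setTest, setRetest, mask,
                               selection = "robust") {
  m <- maskArray(mask)
  sel <- resolveSelection(selection, intersect(mapNames(setTest),
                                               mapNames(setRetest)))
  n <- sum(m)
  mt <- matrix(NA_real_, n, length(sel), dimnames = list(NULL, sel))
  mr <- mt
  for (f in sel) {
    nrm <- normalizePair(featureMap(setTest, f), featureMap(setRetest, f), m)
    mt[, f] <- nrm$a[m]
    mr[, f] <- nrm$b[m]
  }
  list(test = mt, retest = mr)
}

#' Compute test and retest imaging habitats
#'
#' PCA (columns centred on the pooled mean, no scaling or whitening) is
#' fitted according to `cfg$fitMode`, the first `nComponents` score columns
#' are clustered with seeded K-means, and the labels are mapped back onto
#' the mask. In pooled mode the two scans are clustered jointly, so habitat
#' identities correspond between test and retest by construction.
#'
#' @param matTest,matRetest Voxel-by-feature matrices from
#'   [buildFeatureMatrix()].
#' @param mask Binary mask whose in-mask voxels (raster order) correspond
#'   to the matrix rows.
#' @param cfg A [habitatConfig()].
#' @return List with `test` and `retest` ([HabitatMap-class]) and
#'   `varianceExplained` (per retained component, fractions of total).
#' @export
computeHabitats <- function(matTest, matRetest, mask, cfg = habitatConfig()) {
  stopifnot(identical(colnames(matTest), colnames(matRetest)))
  m <- maskArray(mask)
  n <- nrow(matTest)
  if (sum(m) != n || nrow(matRetest) != n)
    stop("matrix rows must match the in-mask voxel count")
  if (n < cfg$k) stop("fewer voxels than clusters")
  nc <- min(cfg$nComponents, ncol(matTest))

  if (cfg$fitMode == "pooled") {
    pooled <- rbind(matTest, matRetest)
    pca <- stats::prcomp(pooled, center = TRUE, scale. = FALSE)
    scores <- pca$x[, seq_len(nc), drop = FALSE]
    km <- withSeed(cfg$kmeansSeed,
                   stats::kmeans(scores, centers = cfg$k,
                                 nstart = cfg$nInit,
                                 iter.max = cfg$maxIter,
                                 algorithm = "MacQueen"))
    labTest <- km$cluster[seq_len(n)]
    labRetest <- km$cluster[n + seq_len(n)]
  } else {
    pca <- stats::prcomp(matTest, center = TRUE, scale. = FALSE)
    scoresT <- pca$x[, seq_len(nc), drop = FALSE]
    km <- withSeed(cfg$kmeansSeed,
                   stats::kmeans(scoresT, centers = cfg$k,
                                 nstart = cfg$nInit,
                                 iter.max = cfg$maxIter,
                                 algorithm = "MacQueen"))
    labTest <- km$cluster
    scoresR <- scale(matRetest, center = pca$center, scale = FALSE) %*%
      pca$rotation[, seq_len(nc), drop = FALSE]
    d2 <- outer(rowSums(scoresR^2), rowSums(km$centers^2), `+`) -
      2 * scoresR %*% t(km$centers)
    labRetest <- max.col(-d2)
  }
  varExp <- (pca$sdev^2 / sum(pca$sdev^2))[seq_len(nc)]

  toMap <- function(lab) {
    a <- array(0L, dim(m))
    a[m] <- as.integer(lab)
    HabitatMap(a, cfg$k, provenance = list(
      features = colnames(matTest), varianceExplained = varExp,
      seed = cfg$kmeansSeed, fitMode = cfg$fitMode))
  }
  list(test = toMap(labTest), retest = toMap(labRetest),
       varianceExplained = varExp)
}

#' Test--retest robustness of imaging habitats for one lesion
#'
#' Full chain: voxel-wise feature extraction on both scans, joint
#' normalization, feature-matrix construction, habitat computation, and the
#' lesion-level mean Dice between the test and retest habitat maps.
#' Deterministic given the seeds.
#'
#' @param testImage,retestImage Preprocessed [ImageVolume-class] crops on a
#'   common grid.
#' @param mask Binary lesion mask.
#' @param params [ExtractionParams-class] for the feature maps.
#' @param cfg A [habitatConfig()].
#' @return List with `meanDsc`, the two [HabitatMap-class] objects, and
#'   `varianceExplained`.
#' @export
habitatRobustness <- function(testImage, retestImage, mask,
                              params = extractionParams(),
                              cfg = habitatConfig()) {
  st <- computeFeatureMaps(testImage, mask, params, "test")
  sr <- computeFeatureMaps(retestImage, mask, params, "retest")
  mats <- buildFeatureMatrix(st, sr, mask, cfg$featureSelection)
  hab <- computeHabitats(mats$test, mats$retest, mask, cfg)
  list(meanDsc = meanDsc(hab$test, hab$retest, mask, k = cfg$k),
       test = hab$test, retest = hab$retest,
       varianceExplained = hab$varianceExplained)
}
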