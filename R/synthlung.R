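#' Specification of a synthetic heterogeneous lung-lesion phantom
#'
#' Describes a CT-like phantom: an ellipsoidal lesion containing `kTrue`
#' spatially contiguous subregions (concentric ellipsoidal shells) with
#' distinct mean intensity and texture correlation length, embedded in a
#' low-intensity lung-like background. Phantoms emulate the test scan of a
#' test--retest pair of a heterogeneous lung lesion.
#'
#' @param gridShape Integer length-3, voxels per axis (all >= 16).
#' @param spacingMm Isotropic voxel size in mm.
#' @param lesionSemiaxesMm Ellipsoid semi-axes in mm (length 3).
#' @param kTrue Number of ground-truth subregions (>= 1).
#' @param regionMeansHu Mean intensity per subregion, length `kTrue` (HU).
#' @param regionTextureHu SD of the correlated texture field per subregion
#'   (HU); 0 gives a flat region.
#' @param regionCorrLenMm Texture correlation length per subregion (mm),
#'   realised as the SD of the Gaussian smoothing kernel applied to white
#'   noise.
#' @param backgroundHu Constant background level (HU).
#' @param psfMm Scanner point-spread function (Gaussian SD, mm) applied to
#'   the composed noiseless object, producing physical partial-volume
#'   mixing at the lesion boundary; 0 disables it.
#' @param noiseSigmaHu Additive acquisition-noise SD (HU, >= 0).
#' @param noiseCorrLenMm Spatial correlation length of the acquisition
#'   noise (Gaussian SD in mm), emulating the scanner point-spread
#'   function; 0 gives white noise.
#' @param seed RNG seed; identical spec and seed reproduce the phantom
#'   bit-for-bit.
#' @return A `phantomSpec` list.
#' @examples
#' spec <- phantomSpec(kTrue = 3, seed = 7)
#' ph <- generatePhantom(spec)
#' ph$image
#' @export
phantomSpec <- function(gridShape = c(44L, 44L, 44L), spacingMm = 1,
                        lesionSemiaxesMm = c(10, 9, 8), kTrue = 3L,
                        regionMeansHu = seq(-60, 70, length.out = kTrue),
                        regionTextureHu = seq(10, 90, length.out = kTrue),
                        regionCorrLenMm = seq(1.5, 3.5, length.out = kTrue),
                        backgroundHu = -800, psfMm = 0.6,
                        noiseSigmaHu = 20,
                        noiseCorrLenMm = 0.8, seed = 1L) {
  spec <- list(gridShape = as.integer(gridShape),
               spacingMm = as.numeric(spacingMm),
               lesionSemiaxesMm = as.numeric(lesionSemiaxesMm),
               kTrue = as.integer(kTrue),
               regionMeansHu = as.numeric(regionMeansHu),
               regionTextureHu = as.numeric(regionTextureHu),
               regionCorrLenMm = as.numeric(regionCorrLenMm),
               backgroundHu = as.numeric(backgroundHu),
               psfMm = as.numeric(psfMm),
               noiseSigmaHu = as.numeric(noiseSigmaHu),
               noiseCorrLenMm = as.numeric(noiseCorrLenMm),
               seed = as.integer(seed))
  stopifnot(length(spec$gridShape) == 3L, length(spec$lesionSemiaxesMm) == 3L)
  if (any(spec$gridShape < 16L))
    stop("gridShape must be >= 16 voxels on every axis")
  if (spec$kTrue < 1L) stop("kTrue must be >= 1")
  if (length(spec$regionMeansHu) != spec$kTrue ||
      length(spec$regionCorrLenMm) != spec$kTrue ||
      length(spec$regionTextureHu) != spec$kTrue)
    stop("regionMeansHu, regionTextureHu and regionCorrLenMm must each have length kTrue")
  if (spec$noiseSigmaHu < 0) stop("noiseSigmaHu must be >= 0")
  if (spec$noiseCorrLenMm < 0) stop("noiseCorrLenMm must be >= 0")
  if (spec$psfMm < 0) stop("psfMm must be >= 0")
  ext <- (spec$gridShape - 1) / 2 * spec$spacingMm
  over <- which(spec$lesionSemiaxesMm > ext)
  if (length(over))
    stop("lesion semi-axis exceeds the grid on axis ",
         paste(c("x", "y", "z")[over], collapse = ", "))
  class(spec) <- "phantomSpec"
  spec
}

#' Specification of the rigid motion between test and retest acquisitions
#'
#' Models the small patient repositioning between two acquisitions of the
#' same lesion: a per-axis translation, a rotation about the through-slice
#' (z) axis, and independent retest acquisition noise.
#'
#' @param shiftMm Per-axis translation in mm.
#' @param angleDeg Rotation about the z axis in degrees (|angle| <= 15).
#' @param extraNoiseSigmaHu SD of the independent retest noise (HU, >= 0).
#' @param noiseCorrLenMm Correlation length of the retest noise (mm), as in
#'   [phantomSpec()].
#' @return A `rigidMotionSpec` list.
#' @export
rigidMotionSpec <- function(shiftMm = c(0.4, -0.3, 0.3), angleDeg = 3,
                            extraNoiseSigmaHu = 20, noiseCorrLenMm = 0.8) {
  if (abs(angleDeg) > 15) stop("|angleDeg| must be <= 15")
  if (extraNoiseSigmaHu < 0) stop("extraNoiseSigmaHu must be >= 0")
  structure(list(shiftMm = as.numeric(shiftMm),
                 angleDeg = as.numeric(angleDeg),
                 extraNoiseSigmaHu = as.numeric(extraNoiseSigmaHu),
                 noiseCorrLenMm = as.numeric(noiseCorrLenMm)),
            class = "rigidMotionSpec")
}

#' Generate a synthetic lesion phantom with known ground-truth habitats
#'
#' Builds the test image of a synthetic test--retest pair: an ellipsoidal
#' lesion partitioned into `kTrue` concentric ellipsoidal shells, each with
#' its own mean intensity and correlated Gaussian texture (white noise
#' smoothed with a Gaussian kernel of SD `corrLen / spacing` voxels, then
#' variance-renormalised), plus acquisition noise everywhere (spatially
#' correlated over `noiseCorrLenMm`, emulating the scanner PSF). The
#' noiseless object is itself imaged through the PSF (`psfMm`), so lesion
#' boundary voxels show the partial-volume mixing every real acquisition
#' has.
#'
#' @param spec A [phantomSpec()].
#' @return A list with `image` ([ImageVolume-class]), `mask` (binary
#'   [ImageVolume-class]) and `truth` ([HabitatMap-class] of the ground-truth
#'   subregion labels).
#' @export
generatePhantom <- function(spec) {
  stopifnot(inherits(spec, "phantomSpec"))
  d <- spec$gridShape
  sp <- spec$spacingMm
  centre <- (d + 1) / 2
  ax <- (seq_len(d[1]) - centre[1]) * sp / spec$lesionSemiaxesMm[1]
  ay <- (seq_len(d[2]) - centre[2]) * sp / spec$lesionSemiaxesMm[2]
  az <- (seq_len(d[3]) - centre[3]) * sp / spec$lesionSemiaxesMm[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  r <- sqrt(r2)
  mask <- r <= 1
  if (!any(mask)) stop("lesion mask is empty on this grid")
  # concentric equal-thickness shells in normalised radius; centre voxel -> 1
  truth <- array(0L, d)
  truth[mask] <- pmin(spec$kTrue, floor(r[mask] * spec$kTrue) + 1L)

  img <- withSeed(spec$seed, {
    img <- array(spec$backgroundHu, d)
    img[mask] <- spec$regionMeansHu[truth[mask]]
    for (k in seq_len(spec$kTrue)) {
      amp <- spec$regionTextureHu[k]
      if (amp <= 0) next
      field <- gaussSmooth3d(array(stats::rnorm(prod(d)), d),
                             spec$regionCorrLenMm[k] / sp)
      field <- field / stats::sd(field)
      sel <- mask & truth == k
      img[sel] <- img[sel] + amp * field[sel]
    }
    if (spec$psfMm > 0)
      img <- gaussSmooth3d(img, spec$psfMm / sp)
    if (spec$noiseSigmaHu > 0)
      img <- img + correlatedNoise(d, spec$noiseSigmaHu,
                                   spec$noiseCorrLenMm / sp)
    img
  })
  list(
    image = ImageVolume(img, spacing = sp, meta = list(phantomSeed = spec$seed)),
    mask = ImageVolume(array(as.numeric(mask), d), spacing = sp),
    truth = HabitatMap(truth, spec$kTrue,
                       provenance = list(kind = "ground truth"))
  )
}

#' Generate the retest acquisition of a phantom
#'
#' Resamples the test image through a small rigid transform (order-3
#' B-spline interpolation) and adds independent acquisition noise, emulating
#' a second scan a few minutes after the first. The applied world transform
#' and its inverse are recorded in the result's metadata so downstream
#' comparison can use a perfectly aligned pair ([alignRetest()] with zero
#' residual), a realistically registered pair (small residual), or the raw
#' misaligned pair, by configuration.
#'
#' @param image The test [ImageVolume-class].
#' @param motion A [rigidMotionSpec()].
#' @param seed RNG seed for the independent retest noise.
#' @param mask Optional lesion mask; if supplied, an error is raised when
#'   the transform pushes the lesion outside the grid.
#' @return An [ImageVolume-class] with `meta$motion` (shift, angle) and
#'   `meta$transform` / `meta$inverseTransform` (4x4 world-mm matrices).
#' @export
generateRetest <- function(image, motion, seed = 1L, mask = NULL) {
  stopifnot(inherits(motion, "rigidMotionSpec"))
  if (!is.null(mask)) {
    m <- maskArray(mask)
    idx <- which(m, arr.ind = TRUE)
    d <- dim(m)
    sp <- spacingMm(image)
    centre <- (d + 1) / 2
    R <- rotationZ(motion$angleDeg)
    moved <- t(R %*% t((idx - rep(centre, each = nrow(idx))) *
                         rep(sp, each = nrow(idx))))
    moved <- moved + rep(motion$shiftMm, each = nrow(idx))
    movedVox <- moved / rep(sp, each = nrow(idx)) +
      rep(centre, each = nrow(idx))
    if (any(movedVox < 1) || any(movedVox > rep(d, each = nrow(idx))))
      stop("rigid motion pushes the lesion outside the grid")
  }
  identityMotion <- all(motion$shiftMm == 0) && motion$angleDeg == 0
  out <- if (identityMotion) image
         else resampleRigid(image, motion$shiftMm, motion$angleDeg, order = 3L)
  if (motion$extraNoiseSigmaHu > 0) {
    v <- voxelData(out)
    v <- v + withSeed(seed, correlatedNoise(
      dim(voxelData(out)), motion$extraNoiseSigmaHu,
      motion$noiseCorrLenMm / mean(spacingMm(out))))
    out <- ImageVolume(array(v, dim(voxelData(out))), spacing = spacingMm(out),
                       origin = originMm(out), meta = metaInfo(out))
  }
  M <- rigidWorldMatrix(image, motion$shiftMm, motion$angleDeg)
  meta <- metaInfo(out)
  meta$motion <- list(shiftMm = motion$shiftMm, angleDeg = motion$angleDeg,
                      extraNoiseSigmaHu = motion$extraNoiseSigmaHu,
                      seed = seed)
  meta$transform <- M
  meta$inverseTransform <- solve(M)
  initialize(out, meta = meta)
}

#' Align a retest image back onto the test grid
#'
#' Applies the inverse of the rigid transform recorded by
#' [generateRetest()], emulating the rigid registration step applied to real
#' test--retest pairs. The result is voxel-wise comparable to the test image
#' up to interpolation residuals and the independent retest noise.
#'
#' @param retest Output of [generateRetest()].
#' @param order Interpolation order (default 3).
#' @param residualShiftMm,residualAngleDeg Small residual misalignment left
#'   after "registration" (default zero: a perfectly aligned pair). Real
#'   rigid registration aligns to within a fraction of a voxel; supplying a
#'   residual of that order emulates it.
#' @return An [ImageVolume-class] on the test grid.
#' @export
alignRetest <- function(retest, order = 3L, residualShiftMm = c(0, 0, 0),
                        residualAngleDeg = 0) {
  mot <- metaInfo(retest)$motion
  if (is.null(mot))
    stop("retest image carries no recorded motion; nothing to align")
  shift <- -mot$shiftMm + residualShiftMm
  angle <- -mot$angleDeg + residualAngleDeg
  if (all(shift == 0) && angle == 0) return(retest)
  aligned <- resampleRigid(retest, shift, angle, order = order)
  meta <- metaInfo(aligned)
  meta$aligned <- TRUE
  initialize(aligned, meta = meta)
}

#' Write a phantom (image, mask, truth) as NRRD plus a JSON sidecar
#'
#' @param phantom Output of [generatePhantom()].
#' @param dir Output directory (created if needed).
#' @param id Basename prefix for the three volumes.
#' @param spec The [phantomSpec()] used (stored in the sidecar).
#' @param transform Optional 4x4 world transform to record.
#' @return The sidecar path, invisibly.
#' @export
writePhantom <- function(phantom, dir, id, spec = NULL, transform = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeNRRD(phantom$image, file.path(dir, paste0(id, "_image.nrrd")))
  writeNRRD(phantom$mask, file.path(dir, paste0(id, "_mask.nrrd")),
            type = "uint8")
  truthVol <- ImageVolume(array(as.numeric(habitatLabels(phantom$truth)),
                                dim(habitatLabels(phantom$truth))),
                          spacing = spacingMm(phantom$image))
  writeNRRD(truthVol, file.path(dir, paste0(id, "_truth.nrrd")),
            type = "uint8")
  sidecar <- list(id = id)
  if (!is.null(spec)) sidecar$spec <- unclass(spec)
  if (!is.null(transform))
    sidecar$transform <- as.vector(t(transform))  # row-major 4x4
  path <- file.path(dir, paste0(id, ".json"))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
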