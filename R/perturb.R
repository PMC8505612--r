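#' Perturbation recipe for synthetic-retest generation
#'
#' A synthetic retest is produced from a test image by an ordered chain of
#' perturbations: noise addition (`"N"`), sub-voxel translation (`"T"`) and
#' axial rotation (`"R"`). Defaults use a single low-magnitude perturbation
#' of each kind.
#'
#' @param chain Ordered character vector over `c("N", "T", "R")`.
#' @param eta Per-axis translation as a fraction of the (isotropic) voxel
#'   spacing; each component in `[0, 1)`.
#' @param thetaDeg Axial (about-z) rotation angle in degrees.
#' @param sigmaHu Noise SD in HU, or `NULL` to estimate it from the image
#'   via [estimateNoiseSigma()].
#' @param seed RNG seed for the noise draw.
#' @return A `perturbationSpec` list.
#' @export
perturbationSpec <- function(chain = c("N", "T", "R"),
                             eta = c(0.25, 0.25, 0.25), thetaDeg = 5,
                             sigmaHu = NULL, seed = 1L) {
  stopifnot(all(chain %in% c("N", "T", "R")))
  if (any(eta < 0) || any(eta >= 1))
    stop("eta components must lie in [0, 1)")
  if (!is.finite(thetaDeg)) stop("thetaDeg must be finite")
  structure(list(chain = chain, eta = as.numeric(eta),
                 thetaDeg = as.numeric(thetaDeg),
                 sigmaHu = if (is.null(sigmaHu)) NULL else as.numeric(sigmaHu),
                 seed = as.integer(seed)),
            class = "perturbationSpec")
}

#' Estimate the image noise standard deviation
#'
#' Robust noise estimate from the finest-scale wavelet detail coefficients:
#' a single-level separable 3D Haar transform is applied and the estimate is
#' `median(|d|) / 0.6745` over the diagonal (HHH) detail band, which is
#' insensitive to smooth image structure.
#'
#' @param image An [ImageVolume-class] (typically the cropped volume).
#' @param mask Optional binary mask; if given, only 2x2x2 blocks fully
#'   inside the mask contribute.
#' @return Non-negative noise SD in HU; 0 for a constant image.
#' @export
estimateNoiseSigma <- function(image, mask = NULL) {
  v <- voxelData(image)
  d <- dim(v) - dim(v) %% 2L
  if (any(d < 2L)) stop("volume too small for noise estimation")
  v <- v[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  if (prod(d) < 100) stop("need at least 100 voxels to estimate noise")
  e <- function(n) seq(1L, n, by = 2L)
  o <- function(n) seq(2L, n, by = 2L)
  blk <- function(a, i, j, k) a[i(d[1]), j(d[2]), k(d[3]), drop = FALSE]
  # HHH band of an orthonormal Haar step: alternating-sign sum / sqrt(8)
  hhh <- (blk(v, e, e, e) - blk(v, o, e, e) - blk(v, e, o, e) +
            blk(v, o, o, e) - blk(v, e, e, o) + blk(v, o, e, o) +
            blk(v, e, o, o) - blk(v, o, o, o)) / sqrt(8)
  if (!is.null(mask)) {
    m <- maskArray(mask)[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]),
                         drop = FALSE]
    inblk <- (blk(m, e, e, e) & blk(m, o, e, e) & blk(m, e, o, e) &
                blk(m, o, o, e) & blk(m, e, e, o) & blk(m, o, e, o) &
                blk(m, e, o, o) & blk(m, o, o, o))
    hhh <- hhh[inblk]
    if (length(hhh) < 10) stop("too few in-mask blocks for noise estimation")
  }
  stats::median(abs(hhh)) / 0.6745
}

#' Add seeded Gaussian noise to an image
#'
#' @param image An [ImageVolume-class].
#' @param sigmaHu Noise SD in HU (>= 0).
#' @param seed RNG seed.
#' @return The noisy [ImageVolume-class]; identical to the input when
#'   `sigmaHu = 0`.
#' @export
addNoise <- function(image, sigmaHu, seed = 1L) {
  if (sigmaHu < 0) stop("sigmaHu must be >= 0")
  if (sigmaHu == 0) return(image)
  v <- voxelData(image)
  v <- v + withSeed(seed, stats::rnorm(length(v), sd = sigmaHu))
  ImageVolume(array(v, dim(voxelData(image))), spacing = spacingMm(image),
              origin = originMm(image), meta = metaInfo(image))
}

#' Translate an image by a fraction of the voxel spacing
#'
#' Shifts the image content by `eta * spacing` along each axis using order-3
#' B-spline interpolation; the grid (and any mask) is unchanged. `eta = 1`
#' is permitted (an integer one-voxel shift, useful for validation).
#'
#' @param image An [ImageVolume-class].
#' @param eta Per-axis shift fraction (length 1 or 3).
#' @return The translated [ImageVolume-class].
#' @export
translateImage <- function(image, eta) {
  if (length(eta) == 1L) eta <- rep(eta, 3L)
  if (all(eta == 0)) return(image)
  resampleRigid(image, shiftMm = eta * spacingMm(image), thetaDeg = 0,
                order = 3L)
}

#' Rotate an image in the axial plane
#'
#' Rotates the image content by `thetaDeg` about the z axis through the
#' volume centre, order-3 B-spline interpolation; grid unchanged.
#'
#' @param image An [ImageVolume-class].
#' @param thetaDeg Rotation angle in degrees.
#' @return The rotated [ImageVolume-class].
#' @export
rotateAxial <- function(image, thetaDeg) {
  if (thetaDeg == 0) return(image)
  resampleRigid(image, shiftMm = c(0, 0, 0), thetaDeg = thetaDeg, order = 3L)
}

#' Create a synthetic retest image by perturbing a test image
#'
#' Applies the perturbation chain in order (default noise, translation,
#' rotation). The noise SD is taken from the spec or, when absent,
#' estimated from the image with [estimateNoiseSigma()]. The mask is *not*
#' perturbed: test-vs-perturbed comparisons use the original contour at the
#' original voxel indices.
#'
#' @param image Test [ImageVolume-class] (preprocessed crop).
#' @param mask Binary lesion mask (used only for noise estimation).
#' @param spec A [perturbationSpec()].
#' @return The perturbed [ImageVolume-class].
#' @export
makeSyntheticRetest <- function(image, mask, spec = perturbationSpec()) {
  stopifnot(inherits(spec, "perturbationSpec"))
  out <- image
  for (step in spec$chain) {
    out <- switch(step,
      N = {
        sigma <- if (is.null(spec$sigmaHu)) estimateNoiseSigma(image)
                 else spec$sigmaHu
        addNoise(out, sigma, seed = spec$seed)
      },
      T = translateImage(out, spec$eta),
      R = rotateAxial(out, spec$thetaDeg)
    )
  }
  out
}
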