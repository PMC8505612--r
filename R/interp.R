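# Affine resampling wrappers around the compiled B-spline interpolator.
# Transforms are expressed in world mm; the grid (shape, spacing, origin) is
# always preserved, so these operate in-place on the voxel lattice.

# Rotation about the z axis by theta degrees (world coordinates).
rotationZ <- function(thetaDeg) {
  th <- thetaDeg * pi / 180
  matrix(c(cos(th), sin(th), 0,
           -sin(th), cos(th), 0,
           0, 0, 1), 3, 3)
}

# Resample `image` through the rigid motion that rotates the content by
# thetaDeg about the z axis through the grid centre and then shifts it by
# shiftMm. order: 0 nearest, 1 trilinear, 3 cubic B-spline. The output voxel
# at index o samples the input at R^-1 (o - c - t) + c (index units).
resampleRigid <- function(image, shiftMm = c(0, 0, 0), thetaDeg = 0,
                          order = 3L) {
  v <- voxelData(image)
  d <- dim(v)
  sp <- spacingMm(image)
  centre <- (d - 1) / 2
  Rinv <- rotationZ(-thetaDeg)
  tVox <- shiftMm / sp
  # input index = Rinv %*% (o - centre - tVox) + centre
  b <- as.numeric(centre - Rinv %*% (centre + tVox))
  out <- cpp_resample_affine(as.numeric(v), d, Rinv, b, d, as.integer(order))
  ImageVolume(array(out, d), spacing = sp, origin = originMm(image),
              meta = metaInfo(image))
}

# 4x4 homogeneous world-coordinate matrix for the same motion (row-major
# convention when serialised): x' = R (x - c_w) + c_w + t.
rigidWorldMatrix <- function(image, shiftMm, thetaDeg) {
  d <- dim(voxelData(image))
  cw <- originMm(image) + (d - 1) / 2 * spacingMm(image)
  R <- rotationZ(thetaDeg)
  t <- as.numeric(cw - R %*% cw + shiftMm)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t
  M
}
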