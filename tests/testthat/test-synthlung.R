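test_that("noise-free single-region phantom is constant inside the lesion", {
  spec <- phantomSpec(kTrue = 1, regionMeansHu = -50,
                      regionTextureHu = 0, regionCorrLenMm = 2,
                      noiseSigmaHu = 0, psfMm = 0, seed = 1)
  ph <- generatePhantom(spec)
  m <- maskArray(ph$mask)
  expect_true(all(voxelData(ph$image)[m] == -50))
  expect_true(all(voxelData(ph$image)[!m] == -800))
})

test_that("shell means match the requested region means within sampling error", {
  # texture off so the Monte-Carlo error is noise/sqrt(n); >= 1000 voxels
  # per region needs a large lesion (inner shell holds ~1/27 of the volume)
  spec <- phantomSpec(gridShape = c(64, 64, 64),
                      lesionSemiaxesMm = c(21, 20, 19), kTrue = 3,
                      regionMeansHu = c(-50, 20, 80),
                      regionTextureHu = c(0, 0, 0),
                      regionCorrLenMm = c(2, 2, 2),
                      noiseSigmaHu = 20, psfMm = 0, seed = 11)
  ph <- generatePhantom(spec)
  tr <- habitatLabels(ph$truth)
  v <- voxelData(ph$image)
  for (k in 1:3) {
    n <- sum(tr == k)
    expect_gte(n, 1000)
    expect_lt(abs(mean(v[tr == k]) - spec$regionMeansHu[k]), 3)
  }
  expect_true(mean(v[tr == 1]) < mean(v[tr == 2]))
  expect_true(mean(v[tr == 2]) < mean(v[tr == 3]))
})

test_that("phantom generation is deterministic and seed-sensitive", {
  spec <- phantomSpec(seed = 5)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(voxelData(a$image), voxelData(b$image))
  spec2 <- phantomSpec(seed = 6)
  c <- generatePhantom(spec2)
  expect_false(isTRUE(all.equal(voxelData(a$image), voxelData(c$image))))
  # mask is deterministic geometry, independent of the seed
  expect_identical(voxelData(a$mask), voxelData(c$mask))
})

test_that("truth labels tile the mask exactly", {
  ph <- generatePhantom(phantomSpec(seed = 2))
  m <- maskArray(ph$mask)
  tr <- habitatLabels(ph$truth)
  expect_true(all(tr[m] %in% 1:3))
  expect_true(all(tr[!m] == 0L))
})

test_that("oversized lesions are rejected naming the axis", {
  expect_error(phantomSpec(gridShape = c(20, 44, 44),
                           lesionSemiaxesMm = c(15, 9, 8)),
               "axis x")
  expect_error(phantomSpec(kTrue = 2, regionMeansHu = c(-50, 0, 50)),
               "length kTrue")
  expect_error(phantomSpec(noiseSigmaHu = -1), "noiseSigmaHu")
})

test_that("texture correlation length is monotone in the requested parameter", {
  lag1 <- function(corrLen) {
    spec <- phantomSpec(kTrue = 1, regionMeansHu = 0,
                        regionTextureHu = 40, regionCorrLenMm = corrLen,
                        noiseSigmaHu = 0, psfMm = 0, seed = 9)
    ph <- generatePhantom(spec)
    m <- maskArray(ph$mask)
    v <- voxelData(ph$image)
    sel <- m[-dim(m)[1], , ] & m[-1, , ]
    a <- v[-dim(m)[1], , ][sel]
    b <- v[-1, , ][sel]
    stats::cor(a, b)
  }
  acs <- vapply(c(1, 2, 4), lag1, numeric(1))
  expect_true(all(diff(acs) > 0))
})

test_that("identity retest returns the input exactly", {
  ph <- generatePhantom(phantomSpec(seed = 3))
  mo <- rigidMotionSpec(shiftMm = c(0, 0, 0), angleDeg = 0,
                        extraNoiseSigmaHu = 0)
  rt <- generateRetest(ph$image, mo, seed = 1)
  expect_identical(voxelData(rt), voxelData(ph$image))
})

test_that("integer-voxel retest shift equals an index roll in the interior", {
  ph <- generatePhantom(phantomSpec(noiseSigmaHu = 0, seed = 3))
  mo <- rigidMotionSpec(shiftMm = c(1, 0, 0), angleDeg = 0,
                        extraNoiseSigmaHu = 0)
  rt <- generateRetest(ph$image, mo, seed = 1)
  d <- dim(voxelData(ph$image))
  i <- 8:(d[1] - 7)
  expect_lt(max(abs(voxelData(rt)[i, i, i] -
                      voxelData(ph$image)[i - 1, i, i])), 1e-8)
})

test_that("retest noise SD matches the motion spec", {
  ph <- generatePhantom(phantomSpec(seed = 3))
  mo <- rigidMotionSpec(shiftMm = c(0, 0, 0), angleDeg = 0,
                        extraNoiseSigmaHu = 10)
  rt <- generateRetest(ph$image, mo, seed = 4)
  dif <- voxelData(rt) - voxelData(ph$image)
  expect_gt(length(dif), 1e4)
  expect_lt(abs(stats::sd(dif) - 10) / 10, 0.05)
})

test_that("motion pushing the lesion outside the grid errors", {
  ph <- generatePhantom(phantomSpec(seed = 3))
  mo <- rigidMotionSpec(shiftMm = c(14, 0, 0), angleDeg = 0,
                        extraNoiseSigmaHu = 0)
  expect_error(generateRetest(ph$image, mo, seed = 1, mask = ph$mask),
               "outside the grid")
  expect_error(rigidMotionSpec(angleDeg = 20), "angleDeg")
})

test_that("retest records the transform and alignment undoes the motion", {
  ph <- generatePhantom(phantomSpec(noiseSigmaHu = 0, seed = 8))
  mo <- rigidMotionSpec(shiftMm = c(0.5, -0.4, 0.3), angleDeg = 3,
                        extraNoiseSigmaHu = 0)
  rt <- generateRetest(ph$image, mo, seed = 1, mask = ph$mask)
  meta <- metaInfo(rt)
  expect_equal(dim(meta$transform), c(4, 4))
  expect_equal(meta$transform %*% meta$inverseTransform, diag(4),
               tolerance = 1e-12)
  al <- alignRetest(rt)
  m <- maskArray(ph$mask)
  err <- (voxelData(al) - voxelData(ph$image))[m]
  rng <- diff(range(voxelData(ph$image)[m]))
  expect_lt(sqrt(mean(err^2)) / rng, 0.05)
})

test_that("phantom round-trips through NRRD with sidecar", {
  ph <- generatePhantom(phantomSpec(seed = 2))
  dir <- withr::local_tempdir()
  writePhantom(ph, dir, "p01", spec = phantomSpec(seed = 2),
               transform = diag(4))
  img <- readNRRD(file.path(dir, "p01_image.nrrd"))
  expect_identical(voxelData(img), voxelData(ph$image))
  side <- jsonlite::read_json(file.path(dir, "p01.json"))
  expect_equal(side$spec$seed, 2)
  expect_equal(length(side$transform), 16)
})
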