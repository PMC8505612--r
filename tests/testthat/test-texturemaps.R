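test_that("fixed-bin discretization follows the floor rule", {
  vals <- c(0, 11.9, 12, 25, 3, 3, 3, 3)
  img <- ImageVolume(array(vals, c(2, 2, 2)))
  msk <- ImageVolume(array(1, c(2, 2, 2)))
  disc <- discretizeVolume(img, msk, 12)
  expect_equal(disc$gray[1:4], c(1L, 1L, 2L, 3L))
  expect_equal(disc$ng, 3L)
  # constant lesion collapses to one bin
  disc1 <- discretizeVolume(ImageVolume(array(9, c(2, 2, 2))), msk, 12)
  expect_equal(disc1$ng, 1L)
  expect_true(all(disc1$gray == 1L))
  # coarser bins never increase ng
  les <- randomLesion(8, seed = 20)
  expect_lte(discretizeVolume(les$image, les$mask, 24)$ng,
             discretizeVolume(les$image, les$mask, 12)$ng)
  expect_error(discretizeVolume(les$image, les$mask, 0), "binWidthHu")
})

test_that("GLCM counts on the 2x2 patch match hand enumeration", {
  gray <- array(c(1L, 1L, 1L, 2L), c(2, 2, 1))
  region <- array(TRUE, c(2, 2, 1))
  stack <- glcmFromRegion(gray, region, ng = 2,
                          directions = matrix(c(0L, 1L, 0L), 1))
  expect_equal(stack$npairs, 2)
  expect_equal(stack$p[, , 1],
               matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
})

test_that("constant regions give a single-entry GLCM in every direction", {
  gray <- array(1L, c(4, 4, 4))
  stack <- glcmFromRegion(gray, array(TRUE, c(4, 4, 4)), ng = 1)
  expect_true(all(stack$npairs > 0))
  expect_true(all(stack$p == 1))
})

test_that("vectorized GLCM accumulation equals brute-force enumeration", {
  set.seed(21)
  for (rep in 1:3) {
    d <- c(5, 5, 5)
    gray <- array(sample(1:4, prod(d), replace = TRUE), d)
    region <- array(runif(prod(d)) > 0.3, d)
    region[3, 3, 3] <- TRUE
    dirs <- glcmDirections()
    stack <- glcmFromRegion(gray, region, ng = 4)
    for (k in seq_len(nrow(dirs))) {
      counts <- matrix(0, 4, 4)
      np <- 0
      for (x in 1:5) for (y in 1:5) for (z in 1:5) {
        t <- c(x, y, z) + dirs[k, ]
        if (any(t < 1) || any(t > 5)) next
        if (!region[x, y, z] || !region[t[1], t[2], t[3]]) next
        a <- gray[x, y, z]; b <- gray[t[1], t[2], t[3]]
        counts[a, b] <- counts[a, b] + 1
        counts[b, a] <- counts[b, a] + 1
        np <- np + 1
      }
      expect_equal(stack$npairs[k], np)
      if (np > 0)
        expect_equal(stack$p[, , k], counts / sum(counts))
    }
  }
})

test_that("hand-worked 2x2 GLCM yields the documented feature values", {
  p <- matrix(c(0.5, 0.25, 0.25, 0), 2, 2)
  f <- glcmFeatures(p)
  expect_equal(unname(f["JointEnergy"]), 0.375)
  expect_equal(unname(f["JointEntropy"]), 1.5, tolerance = 1e-9)
  expect_equal(unname(f["MaximumProbability"]), 0.5)
  expect_equal(unname(f["SumEntropy"]), 1.0, tolerance = 1e-9)
  expect_equal(unname(f["DifferenceEntropy"]), 1.0, tolerance = 1e-9)
  expect_equal(unname(f["Idn"]), 5 / 6, tolerance = 1e-9)
  expect_equal(unname(f["Idmn"]), 0.9, tolerance = 1e-9)
  # information measures via HX = HY ~ 0.8113, HXY1 = HXY2 ~ 1.6226
  expect_equal(unname(f["Imc1"]), -0.1511, tolerance = 1e-3)
  expect_equal(unname(f["Imc2"]), 0.4662, tolerance = 1e-3)
})

test_that("single-level GLCM follows the degenerate conventions", {
  f <- glcmFeatures(matrix(1, 1, 1))
  expect_equal(unname(f["JointEnergy"]), 1)
  expect_equal(unname(f["JointEntropy"]), 0, tolerance = 1e-12)
  expect_equal(unname(f["MaximumProbability"]), 1)
  expect_equal(unname(f["Imc1"]), 0)
  expect_equal(unname(f["Imc2"]), 0)
  expect_equal(unname(f["SumEntropy"]), 0, tolerance = 1e-12)
})

test_that("constant images give degenerate feature maps on the mask", {
  d <- c(8, 8, 8)
  img <- ImageVolume(array(3, d))
  msk <- randomLesion(8, seed = 22)$mask
  fms <- computeFeatureMaps(img, msk, extractionParams())
  m <- maskArray(msk)
  expect_true(all(featureMap(fms, "JointEnergy")[m] == 1))
  expect_true(all(abs(featureMap(fms, "JointEntropy")[m]) < 1e-12))
  expect_true(all(is.na(featureMap(fms, "JointEnergy")[!m])))
})

test_that("optimized extractor equals naive per-voxel re-extraction", {
  for (seed in c(23, 24)) {
    les <- randomLesion(12, seed = seed)
    for (masked in c(FALSE, TRUE)) {
      params <- extractionParams(binWidth = 12, kernelRadius = 1,
                                 maskedKernel = masked)
      fms <- computeFeatureMaps(les$image, les$mask, params)
      ref <- naiveFeatureMaps(les$image, les$mask, params)
      m <- maskArray(les$mask)
      for (f in glcmFeatureNames())
        expect_lt(max(abs(featureMap(fms, f)[m] - ref[, f])), 1e-10)
    }
  }
})

test_that("feature maps are equivariant to integer image shifts", {
  les <- randomLesion(12, seed = 25)
  params <- extractionParams(binWidth = 12, kernelRadius = 1)
  d <- dim(voxelData(les$image))
  v <- voxelData(les$image)
  m0 <- voxelData(les$mask)
  shImg <- ImageVolume(v[c(d[1], 1:(d[1] - 1)), , ])
  shMsk <- ImageVolume(m0[c(d[1], 1:(d[1] - 1)), , ])
  a <- computeFeatureMaps(les$image, les$mask, params)
  b <- computeFeatureMaps(shImg, shMsk, params)
  i <- 4:9
  for (f in c("JointEntropy", "Contrast", "Idn"))
    expect_equal(featureMap(b, f)[i + 1, i, i],
                 featureMap(a, f)[i, i, i], tolerance = 1e-12)
})

test_that("feature maps are invariant to a global intensity shift", {
  les <- randomLesion(10, seed = 26)
  params <- extractionParams(binWidth = 12, kernelRadius = 1)
  a <- computeFeatureMaps(les$image, les$mask, params)
  shifted <- ImageVolume(voxelData(les$image) + 100)
  b <- computeFeatureMaps(shifted, les$mask, params)
  m <- maskArray(les$mask)
  for (f in c("JointEntropy", "JointEnergy", "Contrast"))
    expect_equal(featureMap(a, f)[m], featureMap(b, f)[m])
})

test_that("VOI-wise features match the mask-wide GLCM oracle", {
  les <- randomLesion(8, seed = 27)
  params <- extractionParams(binWidth = 12)
  got <- voiFeatures(les$image, les$mask, params)
  disc <- discretizeVolume(les$image, les$mask, 12)
  m <- maskArray(les$mask)
  ref <- glcmFeatures(glcmFromRegion(disc$gray, m, disc$ng))
  expect_equal(got, ref[names(got)], tolerance = 1e-12)
  # constant lesion
  cst <- voiFeatures(ImageVolume(array(2, dim(m))), les$mask, params)
  expect_equal(unname(cst["JointEnergy"]), 1)
})

test_that("VOI features coincide with the map value on a kernel-sized mask", {
  set.seed(28)
  d <- c(9, 9, 9)
  img <- ImageVolume(array(rnorm(prod(d), sd = 40), d))
  m <- array(0, d); m[4:6, 4:6, 4:6] <- 1
  msk <- ImageVolume(m)
  params <- extractionParams(binWidth = 12, kernelRadius = 1,
                             maskedKernel = TRUE)
  fms <- computeFeatureMaps(img, msk, params)
  voi <- voiFeatures(img, msk, params)
  for (f in glcmFeatureNames())
    expect_equal(featureMap(fms, f)[5, 5, 5], unname(voi[f]),
                 tolerance = 1e-12)
})

test_that("GLCM invariants hold on random matrices", {
  set.seed(29)
  for (rep in 1:5) {
    ng <- sample(2:6, 1)
    raw <- matrix(rexp(ng * ng), ng)
    p <- raw + t(raw)
    p <- p / sum(p)
    f <- glcmFeatures(p)
    expect_gt(unname(f["JointEnergy"]), 0)
    expect_lte(unname(f["JointEnergy"]), 1)
    expect_gte(unname(f["JointEntropy"]), 0)
    expect_gt(unname(f["MaximumProbability"]), 0)
    expect_gt(unname(f["Idn"]), 0); expect_lte(unname(f["Idn"]), 1)
    expect_gt(unname(f["Idmn"]), 0); expect_lte(unname(f["Idmn"]), 1)
    expect_gte(unname(f["Imc2"]), 0); expect_lt(unname(f["Imc2"]), 1)
    # marginal identities
    expect_equal(rowSums(p), colSums(p))
    i <- matrix(seq_len(ng), ng, ng); j <- t(i)
    psum <- vapply(2:(2 * ng), function(k) sum(p[i + j == k]), numeric(1))
    pdiff <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]),
                    numeric(1))
    expect_equal(sum(psum), 1)
    expect_equal(sum(pdiff), 1)
  }
})

test_that("pair normalization follows the joint affine map", {
  a <- array(NA_real_, c(2, 2, 1)); b <- a
  a[1:2] <- c(0, 2); b[1:2] <- c(1, 4)
  sel <- !is.na(a)
  nrm <- normalizePair(a, b, sel)
  expect_equal(nrm$a[sel], c(0, 0.5))
  expect_equal(nrm$b[sel], c(0.25, 1))
  # degenerate joint range collapses both to zero
  cst <- normalizePair(array(3, c(2, 2, 1)), array(3, c(2, 2, 1)))
  expect_true(all(cst$a == 0) && all(cst$b == 0))
})

test_that("normalization preserves CCC and |PCORR|", {
  set.seed(30)
  x <- rnorm(500); y <- 0.8 * x + rnorm(500, sd = 0.4) + 0.5
  a <- array(x, c(5, 10, 10)); b <- array(y, c(5, 10, 10))
  nrm <- normalizePair(a, b, array(TRUE, dim(a)))
  expect_equal(ccc(nrm$a, nrm$b), ccc(x, y), tolerance = 1e-12)
  expect_equal(abs(pcorr(nrm$a, nrm$b)), abs(pcorr(x, y)),
               tolerance = 1e-12)
})

test_that("direction-averaged features are stable under 90-degree rotation", {
  set.seed(31)
  d <- c(14, 14, 14)
  f0 <- habitatlab:::gaussSmooth3d(array(rnorm(prod(d)), d), 1.2)
  img <- ImageVolume(f0 / stats::sd(f0) * 60)
  msk <- ImageVolume(array(1, d))
  rotImg <- ImageVolume(aperm(voxelData(img), c(2, 1, 3))[d[2]:1, , ])
  params <- extractionParams(binWidth = 12, kernelRadius = 1)
  a <- voiFeatures(img, msk, params)
  b <- voiFeatures(rotImg, msk, params)
  for (f in c("JointEntropy", "JointEnergy", "Contrast", "Idn"))
    expect_lt(abs(a[f] - b[f]) / max(abs(a[f]), 1e-12), 0.02)
})
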