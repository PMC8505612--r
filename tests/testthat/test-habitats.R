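# build a small FeatureMapSet pair from a phantom for habitat tests
habitatFixture <- function(seed = 60, retestEqualsTest = FALSE) {
  spec <- phantomSpec(gridShape = c(28L, 28L, 28L),
                      lesionSemiaxesMm = c(8, 7, 6), seed = seed)
  ph <- generatePhantom(spec)
  retest <- if (retestEqualsTest) ph$image else
    alignRetest(generateRetest(ph$image, rigidMotionSpec(), seed = seed + 1,
                               mask = ph$mask))
  crop <- cropToLesion(ph$image, ph$mask, 5)
  cropR <- cropToLesion(retest, ph$mask, 5)$image
  params <- extractionParams(binWidth = 12, kernelRadius = 1)
  list(test = computeFeatureMaps(crop$image, crop$mask, params, "t"),
       retest = computeFeatureMaps(cropR, crop$mask, params, "r"),
       mask = crop$mask, testImage = crop$image, retestImage = cropR)
}

test_that("feature matrices have the right shape, names and range", {
  fx <- habitatFixture()
  mats <- buildFeatureMatrix(fx$test, fx$retest, fx$mask, "robust")
  n <- sum(maskArray(fx$mask))
  expect_equal(dim(mats$test), c(n, 9))
  expect_equal(colnames(mats$test), robustFeatureNames())
  matsAll <- buildFeatureMatrix(fx$test, fx$retest, fx$mask, "all")
  expect_equal(ncol(matsAll$test), 23)
  expect_gte(min(mats$test, mats$retest), 0)
  expect_lte(max(mats$test, mats$retest), 1)
  expect_error(buildFeatureMatrix(fx$test, fx$retest, fx$mask, "NoSuch"),
               "NoSuch")
})

test_that("identical inputs give identical habitats with Dice 1", {
  fx <- habitatFixture(retestEqualsTest = TRUE)
  mats <- buildFeatureMatrix(fx$test, fx$retest, fx$mask, "robust")
  expect_identical(mats$test, mats$retest)
  for (k in c(3L, 5L)) {
    hab <- computeHabitats(mats$test, mats$retest, fx$mask,
                           habitatConfig(k = k))
    expect_identical(habitatLabels(hab$test), habitatLabels(hab$retest))
    expect_equal(meanDsc(hab$test, hab$retest, fx$mask, k = k), 1)
  }
})

test_that("well-separated blobs in feature space are recovered", {
  set.seed(61)
  d <- c(10, 10, 9)
  m <- array(TRUE, d)
  n <- prod(d)
  truth <- rep(1:3, length.out = n)
  centres <- matrix(c(0, 0, 0, 10, 0, 0, 0, 10, 0), 3, byrow = TRUE)
  mk <- function() {
    x <- centres[truth, ] + matrix(rnorm(3 * n, sd = 0.05), n, 3)
    colnames(x) <- c("f1", "f2", "f3")
    x
  }
  hab <- computeHabitats(mk(), mk(), ImageVolume(array(1, d)),
                         habitatConfig(k = 3, nComponents = 3,
                                       featureSelection = "all"))
  lab <- habitatLabels(hab$test)[m]
  expect_gt(adjustedRandIndex(lab, truth), 0.99)
})

test_that("habitats are invariant to feature column order", {
  fx <- habitatFixture()
  mats <- buildFeatureMatrix(fx$test, fx$retest, fx$mask, "robust")
  perm <- sample(ncol(mats$test))
  hab1 <- computeHabitats(mats$test, mats$retest, fx$mask, habitatConfig())
  hab2 <- computeHabitats(mats$test[, perm], mats$retest[, perm], fx$mask,
                          habitatConfig())
  expect_equal(meanDsc(hab1$test, hab2$test, fx$mask, k = 3,
                       match = "best"), 1)
})

test_that("variance explained is non-increasing and bounded", {
  fx <- habitatFixture()
  mats <- buildFeatureMatrix(fx$test, fx$retest, fx$mask, "all")
  hab <- computeHabitats(mats$test, mats$retest, fx$mask,
                         habitatConfig(featureSelection = "all"))
  ve <- hab$varianceExplained
  expect_length(ve, 5)
  expect_true(all(diff(ve) <= 1e-12))
  expect_lte(sum(ve), 1 + 1e-12)
})

test_that("degenerate configurations are rejected", {
  expect_error(habitatConfig(k = 1), "k must be")
  d <- c(2, 1, 1)
  mats <- matrix(rnorm(4), 2, 2)
  expect_error(computeHabitats(mats, mats, ImageVolume(array(1, d)),
                               habitatConfig(k = 3)), "fewer voxels")
})

test_that("full-chain robustness returns Dice 1 for a perfect retest", {
  fx <- habitatFixture(retestEqualsTest = TRUE)
  out <- habitatRobustness(fx$testImage, fx$retestImage, fx$mask,
                           extractionParams(binWidth = 12, kernelRadius = 1),
                           habitatConfig(k = 3))
  expect_equal(out$meanDsc, 1)
  # labels partition the mask
  lab <- habitatLabels(out$test)
  m <- maskArray(fx$mask)
  expect_true(all(lab[m] %in% 1:3))
  expect_true(all(lab[!m] == 0L))
})

test_that("habitat computation is deterministic given the seed", {
  fx <- habitatFixture()
  mats <- buildFeatureMatrix(fx$test, fx$retest, fx$mask, "robust")
  h1 <- computeHabitats(mats$test, mats$retest, fx$mask,
                        habitatConfig(kmeansSeed = 7))
  h2 <- computeHabitats(mats$test, mats$retest, fx$mask,
                        habitatConfig(kmeansSeed = 7))
  expect_identical(habitatLabels(h1$test), habitatLabels(h2$test))
})
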