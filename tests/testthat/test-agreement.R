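test_that("ccc matches closed-form and boundary conventions", {
  x <- c(0, 1, 2)
  expect_equal(ccc(x, x + 1), 4 / 7)
  expect_equal(ccc(x, x), 1)
  z <- c(-1, 0, 1)
  expect_equal(ccc(z, -z), -1)
  expect_equal(ccc(c(2, 2, 2), c(2, 2, 2)), 1)   # constant and equal
  expect_equal(ccc(c(2, 2, 2), c(1, 2, 3)), 0)   # one side constant
  expect_error(ccc(1:3, 1:4), "equal length")
})

test_that("pcorr is affine-invariant with a constant-input convention", {
  x <- c(0, 1, 2)
  expect_equal(pcorr(x, 2 * x + 3), 1)
  expect_equal(pcorr(x, x + 1), 1)    # while CCC is 4/7
  expect_equal(pcorr(c(1, 1, 1), x), 0)
  set.seed(40)
  expect_lt(abs(pcorr(rnorm(1e4), rnorm(1e4))), 0.05)
})

test_that("concordance never exceeds the magnitude of correlation", {
  set.seed(41)
  for (rep in 1:20) {
    x <- rnorm(50)
    y <- runif(1, -2, 2) * x + rnorm(50, sd = runif(1, 0.1, 2)) +
      runif(1, -1, 1)
    expect_lte(ccc(x, y), abs(pcorr(x, y)) + 1e-12)
  }
  # equality when means and variances match exactly
  x <- rnorm(100)
  y <- sample(x)
  expect_equal(ccc(x, y), pcorr(x, y), tolerance = 1e-12)
})

test_that("ssim equals 1 on identical maps and degrades monotonically", {
  mp <- smoothMapPair(12, seed = 42)
  expect_equal(ssim3d(mp$ref, mp$ref, mp$mask), 1, tolerance = 1e-12)
  flipped <- 1 - mp$ref
  expect_lt(ssim3d(mp$ref, flipped, mp$mask),
            ssim3d(mp$ref, mp$ref, mp$mask))
})

test_that("ssim matches the direct per-window reference", {
  mp <- smoothMapPair(16, seed = 43)
  got <- ssim3d(mp$ref, mp$eval, mp$mask)
  ref <- referenceSSIM(mp$ref, mp$eval, mp$mask)
  expect_equal(got, ref, tolerance = 1e-8)
})

test_that("gamma is zero with full passing on identical maps", {
  mp <- smoothMapPair(12, seed = 44)
  g <- gammaMap(mp$ref, mp$ref, mp$mask, gammaCriterion(), 1)
  expect_equal(max(g[mp$mask], na.rm = TRUE), 0)
  expect_equal(gammaPassingRate(g, mp$mask), 100)
})

test_that("uniform offset on flat maps isolates the difference term", {
  d <- c(10, 10, 10)
  m <- array(TRUE, d)
  flat <- array(1, d)
  g <- gammaMap(flat, flat + 0.005, m, gammaCriterion(2, 1, fMax = 1), 1)
  expect_equal(range(g[m]), c(0.5, 0.5))
})

test_that("gamma search equals the exhaustive brute-force oracle", {
  for (seed in c(45, 46, 47)) {
    mp <- smoothMapPair(10, seed = seed, noise = 0.3)
    crit <- gammaCriterion(dtaMm = 2, dfPercent = 10,
                           searchCapMm = 20, upsampleFactor = 3)
    got <- gammaMap(mp$ref, mp$eval, mp$mask, crit, 1)
    ref <- bruteForceGamma(mp$ref, mp$eval, mp$mask, 2, 10, factor = 3)
    sel <- mp$mask & !is.na(got)
    expect_gt(sum(sel), 50)
    expect_lt(max(abs(got[sel] - ref[sel])), 1e-6)
  }
})

test_that("gamma errors when the reference maximum is not positive", {
  d <- c(6, 6, 6)
  m <- array(TRUE, d)
  expect_error(gammaMap(array(0, d), array(0, d), m, gammaCriterion(), 1),
               "F_max")
})

test_that("passing rate counts and is monotone in the criterion", {
  d <- c(10, 10, 10)
  m <- array(TRUE, d)
  g <- array(2, d)
  g[1:500] <- 0.5
  expect_equal(gammaPassingRate(g, m), 50)
  # tightening the feature criterion never increases the rate
  mp <- smoothMapPair(10, seed = 48, noise = 0.4)
  loose <- gammaPassingRate(
    gammaMap(mp$ref, mp$eval, mp$mask, gammaCriterion(2, 5), 1), mp$mask)
  tight <- gammaPassingRate(
    gammaMap(mp$ref, mp$eval, mp$mask, gammaCriterion(2, 1), 1), mp$mask)
  expect_lte(tight, loose)
})

test_that("dice follows set arithmetic", {
  d <- c(4, 4, 1)
  m <- array(TRUE, d)
  a <- array(0L, d); b <- array(0L, d)
  a[1:4] <- 1L; b[3:6] <- 1L
  expect_equal(dsc(a, b, m, 1), 0.5)
  expect_equal(dsc(a, a, m, 1), 1)
  c2 <- array(0L, d); c2[7:8] <- 1L
  expect_equal(dsc(a, c2, m, 1), 0)
  expect_true(is.nan(dsc(a, b, m, 3)))
})

test_that("mean dice excludes absent labels and supports matching", {
  d <- c(4, 4, 2)
  m <- array(TRUE, d)
  a <- array(1L, d); a[1:16] <- 2L
  # a consistent relabelling is recovered by best matching
  b <- array(2L, d); b[1:16] <- 1L
  expect_equal(meanDsc(a, b, m, k = 2, match = "best"), 1)
  expect_lt(meanDsc(a, b, m, k = 2, match = "none"), 1)
  # label 3 absent from both is excluded, not zero-counted
  expect_equal(meanDsc(a, a, m, k = 3), 1)
})

test_that("feature ranking applies the threshold semantics exactly", {
  tab <- tibble::tibble(
    feature = "JointEnergy",
    lesion = c("a", "b", "c"),
    metric = "ccc",
    value = c(0.85, 0.95, 0.92))
  rk <- rankFeatures(tab)
  expect_equal(rk$ranking$medianCCC, 0.92)
  expect_equal(rk$repeatableByCCC, "JointEnergy")
  # 0.9 exactly is NOT above the threshold
  tab$value <- c(0.9, 0.9, 0.9)
  expect_equal(rankFeatures(tab)$repeatableByCCC, character(0))
  # gamma threshold: strictly above 95
  tabg <- tibble::tibble(feature = c("A", "B"), lesion = "l1",
                         metric = "gamma_pass", value = c(95, 95.1))
  expect_equal(rankFeatures(tabg)$repeatableByGamma, "B")
  # empty table is fine
  expect_equal(nrow(rankFeatures(tab[0, ])$ranking), 0)
})

test_that("ranking breaks ties alphabetically", {
  tab <- tibble::tibble(
    feature = rep(c("Zeta", "Alpha", "Mid"), each = 2),
    lesion = rep(c("a", "b"), 3),
    metric = "ccc",
    value = c(1, 1, 1, 1, 0.5, 0.5))
  rk <- rankFeatures(tab)
  expect_equal(rk$ranking$feature, c("Alpha", "Zeta", "Mid"))
})

test_that("identical test and retest give CCC 1 at every grid combination", {
  les <- randomLesion(10, seed = 49)
  lesions <- list(list(test = les$image, retest = les$image,
                       mask = les$mask, id = "p1"))
  tab <- reproducibilityGrid(lesions, binWidths = c(12, 25),
                             kernelRadii = 1,
                             features = c("JointEnergy", "JointEntropy"))
  expect_true(all(tab$value == 1))
  expect_equal(nrow(tab), 2 * 2)   # 2 features x 2 combos
})

test_that("the full grid emits one CCC row per feature and combination", {
  les <- randomLesion(8, seed = 50)
  noisy <- addNoise(les$image, 5, seed = 1)
  lesions <- list(list(test = les$image, retest = noisy, mask = les$mask))
  tab <- reproducibilityGrid(lesions, binWidths = c(12, 25),
                             kernelRadii = c(1, 3, 5))
  expect_equal(nrow(tab), 23 * 6)
  smry <- agreementSummary(tab)
  expect_equal(nrow(smry$pooled), 23)
  expect_equal(nrow(smry$perCombo), 23 * 6)
})
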