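test_that("edge indicator is 1 on flat images and dips at a step edge", {
  expect_true(all(edgeIndicator(matrix(42, 30, 30)) == 1))

  edge <- matrix(0, 40, 60); edge[, 31:60] <- 255
  g <- edgeIndicator(edge, sigma = 1.5)
  # row-wise argmin must sit at the edge column +- 1 px
  mins <- apply(g[5:35, ], 1, which.min)
  expect_true(all(abs(mins - 30.5) <= 1))

  set.seed(3)
  g2 <- edgeIndicator(matrix(runif(50 * 50, 0, 255), 50, 50))
  expect_gt(min(g2), 0)
  expect_lte(max(g2), 1)
})

test_that("high-contrast edges trace a rectangle boundary", {
  expect_true(all(highContrastEdges(matrix(0, 40, 40)) == 1))

  m <- matrix(0, 60, 60); m[20:40, 15:45] <- 1
  g <- highContrastEdges(m, sigma = 1.5)
  expect_gt(min(g), 0)
  expect_lte(max(g), 1)
  boundary <- m * 0
  boundary[c(20, 40), 15:45] <- 1; boundary[20:40, c(15, 45)] <- 1
  inner <- matrix(0, 60, 60); inner[26:34, 21:39] <- 1
  expect_lt(mean(g[boundary == 1]), 0.01)
  expect_gt(mean(g[inner == 1]), 0.99)
})

test_that("emphasized edges highlight the meat/fat boundary", {
  ph <- generateSteakPhantom(steakPhantomSpec(seed = 23, noiseSigma = 0))
  g <- emphasizedEdges(phantomImage(ph))
  tr <- groundTruth(ph)
  rim <- (tr$ribeye - as.matrix(EBImage::erode(
    tr$ribeye, EBImage::makeBrush(5, "disc")))) == 1
  interior <- as.matrix(EBImage::erode(
    tr$ribeye, EBImage::makeBrush(9, "disc"))) == 1
  expect_lt(mean(g[rim]), mean(g[interior]))
  expect_gt(mean(g[interior]), 0.99)   # uniform color inside
  expect_gt(min(g), 0)
  expect_lte(max(g), 1)
})

test_that("iterative erosion yields a single component inside the big blob", {
  m <- matrix(0, 120, 200)
  m[30:90, 20:80] <- 1                     # ~3700 px blob
  m[50:57, 150:157] <- 1                   # small separate blob
  seed <- initialRegionByErosion(m, minFrac = 0)
  expect_equal(max(EBImage::bwlabel(seed)), 1)
  expect_true(all(m[seed == 1] == 1))
  expect_true(all(seed[, 100:200] == 0))   # contained in the big blob

  blob <- diskMask(80, 80, 40, 40, 25)
  s2 <- initialRegionByErosion(blob)
  expect_gt(sum(s2), 0)
  expect_true(all(blob[s2 == 1] == 1))

  expect_error(initialRegionByErosion(matrix(0, 20, 20)), "empty")
})

test_that("a contour on a strong closed edge stops within five checks", {
  ring <- diskMask(120, 120, 60, 60, 30)
  g <- highContrastEdges(ring, 1.5)
  r <- evolveStage(initLevelSet(ring), g,
                   drlseParams(alpha = -1.5, maxIterations = 100,
                               checkEvery = 10))
  expect_true(r$converged)
  expect_lte(r$iterations, 50)
  expect_lt(abs(sum(r$phi < 0) - sum(ring)) / sum(ring), 0.05)
})

test_that("with g == 1 the balloon grows the interior at every check", {
  m <- matrix(0, 100, 100); m[45:55, 45:55] <- 1
  g1 <- matrix(1, 100, 100)
  phi <- initLevelSet(m)
  areas <- numeric(3)
  for (k in 1:3) {
    r <- evolveStage(phi, g1, drlseParams(maxIterations = 20,
                                          checkEvery = 21),
                     redistance = FALSE)
    phi <- r$phi
    areas[k] <- sum(phi < 0)
  }
  expect_true(all(diff(c(sum(m), areas)) > 0))
  expect_true(all(is.finite(phi)))
})

test_that("evolved fields satisfy the signed-distance band contract", {
  ring <- diskMask(120, 120, 60, 60, 30)
  r <- evolveStage(initLevelSet(ring), highContrastEdges(ring, 1.5),
                   drlseParams(alpha = -1.5, maxIterations = 60,
                               checkEvery = 10))
  expect_gte(bandGradientFraction(r$phi, band = 5, tol = 0.2), 0.95)
})

test_that("segmentRibeye recovers the phantom rib eye deterministically", {
  ph <- generateSteakPhantom(sampleSteakPhantomSpec(31))
  img <- phantomImage(ph)
  tr <- groundTruth(ph)
  seg <- segmentRibeye(img)
  expect_lte(concordance(ribeyeMask(seg), tr$ribeye), 0.10)
  expect_equal(ribeyeArea(seg), sum(ribeyeMask(seg)))
  expect_true(all(dim(ribeyeMask(seg)) == dim(img)[1:2]))
  expect_gte(min(seg@diagnostics$bandFraction), 0.95)

  seg2 <- segmentRibeye(img)
  expect_identical(ribeyeMask(seg), ribeyeMask(seg2))
})
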