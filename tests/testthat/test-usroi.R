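test_that("the subcutaneous fat band is found by its aspect ratio", {
  ph <- generateUSPhantom(usPhantomSpec(seed = 51))
  fat <- detectSubcutaneousFat(phantomImage(ph))
  tr <- groundTruth(ph)
  expect_gte(sum(fat$mask * tr$fatMask) / sum(tr$fatMask), 0.9)

  # a tall bright bar (ratio < 1) must lose to a horizontal band (ratio > 5)
  img <- matrix(30, 240, 240)
  img[50:60, 20:220] <- 220       # band in the upper third
  img[20:75, 230:236] <- 220      # vertical bar, also upper third
  fat2 <- detectSubcutaneousFat(img)
  expect_gte(sum(fat2$mask[50:60, 20:220]) / sum(fat2$mask), 0.99)

  expect_error(detectSubcutaneousFat(matrix(8, 220, 220)), "degenerate|bright")
})

test_that("the rib template is symmetric with a bright arc over shadow", {
  tpl <- makeRibTemplate(43, 31)
  expect_equal(tpl, tpl[, rev(seq_len(ncol(tpl)))])
  arcRow <- which.max(apply(tpl, 1, max))
  expect_lt(mean(tpl), mean(tpl[arcRow, ]))

  ncc <- matchTemplateNCC(
    rbind(matrix(0.45, 20, 101),
          cbind(matrix(0.45, 31, 29), tpl, matrix(0.45, 31, 29)),
          matrix(0.45, 20, 101)), tpl)
  peak <- which(ncc == max(ncc, na.rm = TRUE), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(20 + 16, 51))
})

test_that("both rib echoes are localized and separated", {
  ph <- generateUSPhantom(usPhantomSpec(seed = 52))
  tr <- groundTruth(ph)
  ribs <- detectRibs(phantomImage(ph))
  det <- ribs[order(ribs[, 1]), ]
  expect_true(all(abs(det[, 1] - sort(tr$ribPositions[, 1])) <= 10))
  expect_gte(abs(diff(ribs[, 1])), ncol(phantomImage(ph)) / 4)

  # speckle-only frame with a single implanted rib: one admissible maximum
  set.seed(99)
  img <- matrix(72, 300, 300)
  tpl <- makeRibTemplate(43, 31)
  block <- img[180:210, 129:171]
  block[tpl > 0.75] <- 235; block[tpl < 0.18] <- 18
  img[180:210, 129:171] <- block
  g <- matrix(rnorm(300 * 300), 300, 300)
  env <- 0.6 + 0.4 * (g^2 / mean(g^2))
  img <- pmax(pmin(round(img * env), 255), 0)
  expect_error(detectRibs(img), "fewer than two")
})

test_that("detectRibs is translation-equivariant within a pixel", {
  base <- usPhantomSpec(seed = 53)
  shifted <- usPhantomSpec(seed = 53, fatRows = base$fatRows + 6,
                           ribX = base$ribX + 9, ribY = base$ribY + 6)
  r1 <- detectRibs(phantomImage(generateUSPhantom(base)))
  r2 <- detectRibs(phantomImage(generateUSPhantom(shifted)))
  r1 <- r1[order(r1[, 1]), ]; r2 <- r2[order(r2[, 1]), ]
  expect_true(all(abs(r2[, 1] - r1[, 1] - 9) <= 1))
  expect_true(all(abs(r2[, 2] - r1[, 2] - 6) <= 1))
})

test_that("the ROI sits between the fat band and the ribs, 80x80, in frame", {
  ph <- generateUSPhantom(usPhantomSpec(seed = 54))
  img <- phantomImage(ph)
  tr <- groundTruth(ph)
  roi <- extractROI(img)
  expect_equal(roi@side, 80)
  rows <- roi@y:(roi@y + 79); cols <- roi@x:(roi@x + 79)
  expect_true(all(rows >= 1 & rows <= nrow(img)))
  expect_true(all(cols >= 1 & cols <= ncol(img)))
  expect_equal(sum(tr$fatMask[rows, cols]), 0)
  expect_equal(sum(tr$ribMask[rows, cols]), 0)
  expect_identical(dim(roiPatch(img, roi)), c(80L, 80L))

  # ribs too shallow: zone below the band is under 80 px -> error
  expect_error(extractROI(phantomImage(generateUSPhantom(
    usPhantomSpec(seed = 55, fatRows = c(60, 75), ribY = 150)))),
    "smaller than 80|manual")
})
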