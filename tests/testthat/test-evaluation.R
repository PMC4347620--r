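test_that("relative area error is the absolute relative difference", {
  expect_equal(relativeAreaError(110, 100), 0.10)
  expect_equal(relativeAreaError(90, 100), 0.10)
  expect_equal(relativeAreaError(2500, 2500), 0)
  expect_equal(relativeAreaError(330, 300), relativeAreaError(33, 30))
  expect_error(relativeAreaError(10, 0), "positive")
})

test_that("concordance is one minus the Jaccard overlap", {
  a <- matrix(0, 10, 10); a[2:5, 2:5] <- 1
  expect_equal(concordance(a, a), 0)
  b <- matrix(0, 10, 10); b[7:9, 7:9] <- 1
  expect_equal(concordance(a, b), 1)
  # two unit squares overlapping half their area: 1 - 0.5/1.5 = 2/3
  s1 <- matrix(0, 10, 20); s1[1:10, 1:10] <- 1
  s2 <- matrix(0, 10, 20); s2[1:10, 6:15] <- 1
  expect_equal(concordance(s1, s2), 2 / 3)
  expect_equal(concordance(s1, s2), concordance(s2, s1))
  expect_error(concordance(matrix(0, 5, 5), matrix(0, 5, 5)), "empty")
  expect_error(concordance(a, matrix(0, 5, 5)), "shape")
})

test_that("regression metrics match the direct formulas", {
  y <- c(1, 3, 5, 7)
  expect_equal(regressionEval(y, y), list(rmse = 0, r2 = 1))
  ev <- regressionEval(y + 2, y)
  expect_equal(ev$rmse, 2)
  expect_equal(ev$r2, 1)
  set.seed(81)
  p <- rnorm(50); t <- rnorm(50)
  ev2 <- regressionEval(p, t)
  expect_equal(ev2$rmse, sqrt(sum((p - t)^2) / 50), tolerance = 1e-12)
  expect_equal(ev2$r2,
               (sum((p - mean(p)) * (t - mean(t))) /
                  sqrt(sum((p - mean(p))^2) * sum((t - mean(t))^2)))^2,
               tolerance = 1e-12)
  expect_error(regressionEval(p, rep(1, 50)), "constant")
})

test_that("the split protocol reproduces the 103/50 partition", {
  sp <- makeSplits(153, repetitions = 1, seed = 4)[[1]]
  expect_length(sp$train, 103)
  expect_length(sp$test, 50)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), 1:153)

  expect_identical(makeSplits(153, repetitions = 3, seed = 9),
                   makeSplits(153, repetitions = 3, seed = 9))

  g <- rep(1:30, each = 4)
  spg <- makeSplits(120, repetitions = 1, seed = 2, groups = g)[[1]]
  expect_length(intersect(unique(g[spg$train]), unique(g[spg$test])), 0)
  expect_length(unique(g[spg$train]), 20)
})

test_that("evaluateProtocol reports one row per repetition, reproducibly", {
  set.seed(82)
  x <- matrix(rnorm(90 * 3), 90, 3)
  y <- x %*% c(1, -1, 0.5) + rnorm(90, 0, 0.1)
  fitF <- function(xx, yy) stats::lm.fit(cbind(1, xx), yy)$coefficients
  predF <- function(m, xx) as.numeric(cbind(1, xx) %*% m)
  tab <- evaluateProtocol(x, as.numeric(y), fitF, predF,
                          repetitions = 10, seed = 5)
  expect_equal(nrow(tab), 10)
  expect_equal(tab$nTrain, rep(60, 10))
  expect_equal(tab$nTest, rep(30, 10))
  expect_true(all(c("rmse", "r2", "baselineRmse",
                    "fracUnder10", "fracUnder15") %in% names(tab)))
  tab2 <- evaluateProtocol(x, as.numeric(y), fitF, predF,
                           repetitions = 10, seed = 5)
  expect_identical(tab, tab2)
  expect_true(all(tab$rmse < tab$baselineRmse))
})
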