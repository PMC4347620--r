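test_that("PCA loadings are orthonormal and ratios match an eigen oracle", {
  set.seed(71)
  x <- matrix(rnorm(200 * 42), 200, 42) %*% diag(runif(42, 0.5, 3))
  pca <- fitPCA(x, k = 10)
  G <- crossprod(pcaLoadings(pca))
  expect_lt(max(abs(G - diag(10))), 1e-8)

  ev <- eigen(stats::cov(scale(x, center = TRUE, scale = FALSE)),
              symmetric = TRUE)$values
  expect_equal(explainedVariance(pca), (ev / sum(ev))[1:10],
               tolerance = 1e-8)
  expect_true(all(diff(explainedVariance(pca)) <= 1e-12))

  # the training mean projects to the origin of component space
  expect_lt(max(abs(applyPCA(pca, colMeans(x)))), 1e-10)
})

test_that("rank-3 data concentrates 99% of variance in 3 components", {
  set.seed(72)
  basis <- qr.Q(qr(matrix(rnorm(42 * 3), 42, 3)))
  scores <- matrix(rnorm(150 * 3, sd = c(4, 2, 1)), 150, 3, byrow = TRUE)
  x <- scores %*% t(basis) + matrix(rnorm(150 * 42, sd = 1e-3), 150, 42)
  pca <- fitPCA(x, k = 10)
  expect_gte(sum(explainedVariance(pca)[1:3]), 0.99)

  # exactly rank-2 input: trailing ratios are zero, with a warning
  y <- matrix(rnorm(60), 60, 1) %*% t(basis[, 1]) +
       matrix(rnorm(60), 60, 1) %*% t(basis[, 2])
  expect_warning(p2 <- fitPCA(y, k = 10), "rank")
  expect_true(all(explainedVariance(p2)[3:10] == 0))
})

test_that("constant labels give a constant predictor with a warning", {
  set.seed(73)
  x <- matrix(rnorm(30 * 42), 30, 42)
  expect_warning(m <- trainIMFModel(x, rep(3, 30)), "constant")
  expect_true(all(abs(predictIMF(m, x) - 3) < 1e-3))
})

test_that("unbounded support vectors sit on the epsilon tube", {
  set.seed(74)
  x <- matrix(rnorm(60 * 42), 60, 42)
  y <- as.numeric(3 + x %*% c(rep(0.3, 5), rep(0, 37)))  # smooth, noise-free
  m <- trainIMFModel(x, y)
  # support vectors with |alpha| < C lie on the tube boundary; the svm
  # fits on internally scaled responses, so the tube width is eps * sd(y)
  unbounded <- m@svm$index[abs(m@svm$coefs) < 1 - 1e-6]
  expect_gt(length(unbounded), 0)
  resid <- abs(predictIMF(m, x[unbounded, , drop = FALSE]) - y[unbounded])
  expect_lte(max(resid), 0.1 * sd(y) + m@tolerance + 0.05)
})

test_that("predictions are deterministic, reloadable, and validated", {
  set.seed(75)
  x <- matrix(rnorm(40 * 42), 40, 42)
  y <- rnorm(40, 4, 1)
  m <- trainIMFModel(x, y)
  p1 <- predictIMF(m, x[1, ])
  expect_identical(p1, predictIMF(m, x[1, ]))
  f <- tempfile(fileext = ".rds")
  saveRDS(m, f)
  expect_identical(predictIMF(readRDS(f), x), predictIMF(m, x))
  unlink(f)
  expect_error(predictIMF(m, rnorm(10)), "42")
})

test_that("the pipeline recovers a latent scalar from synthetic features", {
  # labels = 2 + 0.8 * latent + N(0, 0.3); features carry the latent in a
  # few nonlinear channels plus distractors
  set.seed(76)
  n <- 200
  latent <- runif(n, 0, 10)
  x <- matrix(rnorm(n * 42, sd = 0.3), n, 42)
  x[, 3] <- x[, 3] + latent
  x[, 8] <- x[, 8] + 0.5 * latent
  x[, 17] <- x[, 17] + sqrt(latent) * 2
  x[, 30] <- x[, 30] + latent^1.5 / 5
  y <- 2 + 0.8 * latent + rnorm(n, 0, 0.3)
  tr <- sample(n, 133)
  m <- trainIMFModel(x[tr, ], y[tr])
  ev <- regressionEval(predictIMF(m, x[-tr, ]), y[-tr])
  expect_gte(ev$r2, 0.8)
  expect_lte(ev$rmse, 2 * 0.3)   # twice the injected label noise
  expect_equal(ncol(pcaLoadings(m@pca)), 10)
})
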