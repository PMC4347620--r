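test_that("the descriptor has exactly 42 registered features", {
  expect_length(imfFeatureNames(), 42)
  expect_false(any(duplicated(imfFeatureNames())))
  set.seed(61)
  patch <- matrix(sample(0:255, 6400, replace = TRUE), 80, 80)
  f <- extractUSFeatures(patch)
  expect_length(f, 42)
  expect_identical(names(f), imfFeatureNames())
  expect_true(all(is.finite(f)))
  expect_identical(f, extractUSFeatures(patch))   # deterministic
  expect_error(extractUSFeatures(matrix(0, 40, 40)), "80 x 80")
})

test_that("a constant patch yields the degenerate feature values", {
  f <- extractUSFeatures(matrix(97, 80, 80))
  expect_equal(unname(f["grad_mean"]), 0)
  expect_equal(unname(f["grad_sd"]), 0)
  for (off in c("d01", "d10", "d11", "d1m1")) {
    expect_equal(unname(f[paste0("glcm_", off, "_energy")]), 1)
    expect_equal(unname(f[paste0("glcm_", off, "_contrast")]), 0)
    expect_equal(unname(f[paste0("glcm_", off, "_homogeneity")]), 1)
  }
  expect_true(all(f[paste0("hist_p", c(20, 40, 60, 80))] == 97))
  expect_equal(unname(f["hist_skewness"]), 0)
  expect_equal(unname(f["fourier_var_coeff"]), 0)
  expect_true(all(is.finite(f)))
})

test_that("co-occurrence contrast matches the pair-counting oracle", {
  chk <- 255 * outer(1:80, 1:80, function(r, c) (r + c) %% 2)
  f <- extractUSFeatures(chk)
  for (off in list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))) {
    nm <- paste0("glcm_d", off[1],
                 if (off[2] == -1) "m1" else off[2], "_contrast")
    expect_equal(unname(f[nm]), glcmContrastBrute(chk, off),
                 tolerance = 1e-12)
  }
  # analytic check: horizontal neighbors always differ by 31 levels,
  # diagonal (1,1) neighbors never differ
  expect_equal(unname(f["glcm_d01_contrast"]), 31^2)
  expect_equal(unname(f["glcm_d11_contrast"]), 0)

  set.seed(62)
  rnd <- matrix(sample(0:255, 6400, replace = TRUE), 80, 80)
  fr <- extractUSFeatures(rnd)
  expect_equal(unname(fr["glcm_d10_contrast"]), glcmContrastBrute(rnd, c(1, 0)),
               tolerance = 1e-12)
})

test_that("color features report means and double counts with region size", {
  img <- array(0, c(60, 120, 3))
  img[, , 1] <- 180; img[, , 2] <- 90; img[, , 3] <- 40
  mask1 <- matrix(0, 60, 120); mask1[10:40, 10:40] <- 1
  f1 <- extractColorFeatures(img, mask1)
  expect_equal(unname(f1[c("mean_r", "mean_g", "mean_b")]), c(180, 90, 40))
  expect_identical(f1, extractColorFeatures(img, mask1))

  # textured region duplicated side by side: per-channel counts double
  set.seed(63)
  tex <- matrix(sample(0:255, 31 * 31, replace = TRUE), 31, 31)
  for (ch in 1:3) {
    pl <- matrix(0, 60, 120)
    pl[10:40, 10:40] <- tex
    pl[10:40, 60:90] <- tex
    img[, , ch] <- pl
  }
  maskA <- matrix(0, 60, 120); maskA[10:40, 10:40] <- 1
  maskB <- maskA; maskB[10:40, 60:90] <- 1
  fA <- extractColorFeatures(img, maskA)
  fB <- extractColorFeatures(img, maskB)
  cnt <- paste0("count_above_otsu_", c("r", "g", "b"))
  expect_equal(unname(fB[cnt]), 2 * unname(fA[cnt]))
  expect_equal(unname(fB[c("mean_r", "mean_g", "mean_b")]),
               unname(fA[c("mean_r", "mean_g", "mean_b")]))

  expect_error(extractColorFeatures(img, matrix(0, 60, 120)), "empty")
})
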