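# Independent oracles used across the suite. Each reimplements the checked
# quantity by brute force or closed form, never through the package path it
# verifies.

# exhaustive within-class-variance minimization over all 256 cut points
# (dark class = values < t); smallest minimizer on ties
otsuBruteForce <- function(gray) {
  v <- as.integer(round(gray))
  best <- Inf; bestT <- NA_integer_
  for (t in 0:255) {
    lo <- v[v < t]; hi <- v[v >= t]
    w <- 0
    if (length(lo) > 0) w <- w + length(lo) * mean((lo - mean(lo))^2)
    if (length(hi) > 0) w <- w + length(hi) * mean((hi - mean(hi))^2)
    w <- w / length(v)
    if (w < best - 1e-12) { best <- w; bestT <- t }
  }
  bestT
}

# gift-wrapping convex hull over a point set, returns vertex matrix
giftWrapHull <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  start <- which.min(pts[, 1] + pts[, 2] * 1e-9)
  hull <- integer(0)
  cur <- start
  repeat {
    hull <- c(hull, cur)
    cand <- if (cur == 1) 2 else 1
    for (j in seq_len(n)) {
      if (j == cur) next
      cr <- (pts[cand, 1] - pts[cur, 1]) * (pts[j, 2] - pts[cur, 2]) -
            (pts[cand, 2] - pts[cur, 2]) * (pts[j, 1] - pts[cur, 1])
      if (cand == cur || cr < 0 ||
          (cr == 0 && sum((pts[j, ] - pts[cur, ])^2) >
                      sum((pts[cand, ] - pts[cur, ])^2)))
        cand <- j
    }
    cur <- cand
    if (cur == start) break
  }
  pts[hull, , drop = FALSE]
}

# brute-force symmetric pair-counting GLCM contrast at 32 levels
glcmContrastBrute <- function(patch, offset) {
  codes <- pmin(pmax(floor(patch / 8), 0), 31)
  H <- nrow(codes); W <- ncol(codes)
  tot <- 0; n <- 0
  for (r in seq_len(H)) for (c in seq_len(W)) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W) {
      d2 <- (codes[r, c] - codes[r2, c2])^2
      tot <- tot + 2 * d2        # symmetric: count the pair both ways
      n <- n + 2
    }
  }
  tot / n
}

# dense-sampling normal-marching oracle for curve-to-curve path lengths:
# for star-shaped configurations the exact path is along the local normal
# marched in tiny steps against the exact (analytic) target circle
marchToCircleOracle <- function(pts, center, radius) {
  # normals of a dense closed polygon, outward by centroid test
  n <- nrow(pts)
  prv <- c(n, seq_len(n - 1)); nxt <- c(2:n, 1)
  tx <- pts[nxt, 1] - pts[prv, 1]; ty <- pts[nxt, 2] - pts[prv, 2]
  tl <- sqrt(tx^2 + ty^2)
  nx <- ty / tl; ny <- -tx / tl
  ctr <- colMeans(pts)
  flip <- (nx * (pts[, 1] - ctr[1]) + ny * (pts[, 2] - ctr[2])) < 0
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
  # exact: distance along (nx,ny) from p to the circle |x - c| = radius
  vapply(seq_len(n), function(i) {
    p <- pts[i, ]; d <- c(nx[i], ny[i])
    oc <- p - center
    b <- sum(oc * d); cc <- sum(oc^2) - radius^2
    t <- -b + sqrt(b^2 - cc)
    t
  }, numeric(1))
}

# area-mask helpers for phantom tests
diskMask <- function(H, W, cx, cy, r) {
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), W), H, W)
  ((X - cx)^2 + (Y - cy)^2 <= r^2) * 1
}

# ROI/feature fallback used in the IMF experiments: detected ROI when
# available, otherwise the frame-centered square (the manual fallback)
roiFeaturesWithFallback <- function(img) {
  roi <- tryCatch(extractROI(img), error = function(e) NULL)
  if (is.null(roi))
    roi <- new("USROI", x = round(ncol(img) / 2 - 40),
               y = round(nrow(img) / 2 - 40), side = 80,
               ribPositions = cbind(x = c(0, 0), y = c(0, 0)),
               fatRows = c(1, 1), imageDim = dim(img))
  extractUSFeatures(roiPatch(img, roi))
}
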