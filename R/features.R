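# The 42-dimensional texture descriptor of an ultrasound ROI. The registry
# below is the authoritative feature order; extractUSFeatures() fills it
# exactly. Degenerate conventions (flat patches): sd-normalized statistics
# (GLCM/LBP correlation, skewness, Fourier variance coefficient) are 0 when
# the underlying variance vanishes.

.glcmOffsets <- list(d01 = c(0, 1), d10 = c(1, 0),
                     d11 = c(1, 1), d1m1 = c(1, -1))

#' Names of the 42 ROI texture features, in extraction order
#'
#' Groups: gradient mean/sd at two smoothing scales (4); co-occurrence
#' correlation/homogeneity/contrast/energy at 32 gray levels for offsets
#' (0,1), (1,0), (1,1), (1,-1) (16); gray-level mean, contrast ratio and
#' entropy (3); histogram percentiles 20/40/60/80 and skewness (5); Fourier
#' variance coefficient and five log-power percentiles (6); LBP(8,1)
#' uniform-code co-occurrence statistics (4) and code-histogram statistics
#' (4).
#'
#' @return character vector of length 42.
#' @export
imfFeatureNames <- function() {
  c("grad_mean", "grad_sd", "grad2_mean", "grad2_sd",
    as.vector(vapply(names(.glcmOffsets), function(o)
      paste0("glcm_", o, "_", c("correlation", "homogeneity", "contrast",
                                "energy")), character(4))),
    "gray_mean", "gray_contrast_ratio", "gray_entropy",
    paste0("hist_p", c(20, 40, 60, 80)), "hist_skewness",
    "fourier_var_coeff", paste0("fourier_logpower_p", c(10, 30, 50, 70, 90)),
    paste0("lbp_", c("correlation", "homogeneity", "contrast", "energy")),
    paste0("lbp_hist_", c("mean", "variance", "energy", "entropy")))
}

# symmetric normalized co-occurrence matrix of an integer code image
.cooccurrence <- function(codes, offset, nLevels) {
  H <- nrow(codes); W <- ncol(codes)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1, 1 - dr):min(H, H - dr)
  c1 <- max(1, 1 - dc):min(W, W - dc)
  a <- codes[r1, c1, drop = FALSE]
  b <- codes[r1 + dr, c1 + dc, drop = FALSE]
  m <- matrix(0, nLevels, nLevels)
  tab <- table(factor(a, levels = 0:(nLevels - 1)),
               factor(b, levels = 0:(nLevels - 1)))
  m <- m + tab + t(tab)
  m / sum(m)
}

.glcmStats <- function(p) {
  n <- nrow(p)
  i <- matrix(rep(seq_len(n) - 1, n), n, n)
  j <- t(i)
  pi_ <- rowSums(p)
  mu <- sum((seq_len(n) - 1) * pi_)
  sig2 <- sum(((seq_len(n) - 1) - mu)^2 * pi_)
  corr <- if (sig2 < 1e-12) 0 else (sum(i * j * p) - mu^2) / sig2
  c(correlation = corr,
    homogeneity = sum(p / (1 + (i - j)^2)),
    contrast = sum(p * (i - j)^2),
    energy = sum(p^2))
}

# LBP(8,1) uniform codes on the interior of a patch: codes 0..8 = number of
# ones of a uniform pattern (at most 2 circular transitions), 9 = non-uniform
.lbpCodes <- function(patch) {
  H <- nrow(patch); W <- ncol(patch)
  ctr <- patch[2:(H - 1), 2:(W - 1)]
  offs <- list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1),
               c(1, 0), c(1, -1), c(0, -1), c(-1, -1))
  bits <- lapply(offs, function(o)
    (patch[2:(H - 1) + o[1], 2:(W - 1) + o[2]] >= ctr) * 1L)
  trans <- matrix(0L, H - 2, W - 2)
  ones <- matrix(0L, H - 2, W - 2)
  for (k in seq_along(bits)) {
    nxt <- bits[[if (k == length(bits)) 1 else k + 1]]
    trans <- trans + (bits[[k]] != nxt)
    ones <- ones + bits[[k]]
  }
  code <- ifelse(trans <= 2, ones, 9L)
  matrix(as.integer(code), H - 2, W - 2)
}

.skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 < 1e-12) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

.histEntropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Extract the 42-dimensional texture descriptor from an ROI patch
#'
#' Deterministic; the order matches \code{\link{imfFeatureNames}}. Gradient
#' statistics use central differences (raw, and after Gaussian smoothing at
#' sigma 2); co-occurrence matrices use 32 gray levels, symmetric and
#' normalized; LBP is the 8-neighbor radius-1 uniform variant.
#'
#' @param patch 80 x 80 numeric matrix, values 0-255.
#' @return named numeric vector of length 42.
#' @export
extractUSFeatures <- function(patch) {
  .assertMatrix(patch)
  if (!all(dim(patch) == c(80, 80)))
    stop("patch must be exactly 80 x 80", call. = FALSE)

  out <- numeric(0)
  for (sig in c(0, 2)) {
    s <- if (sig > 0) .gsmooth(patch, sig) else patch
    gm <- sqrt(.gradX(s)^2 + .gradY(s)^2)
    out <- c(out, mean(gm), stats::sd(gm))
  }

  codes32 <- pmin(pmax(floor(patch / 8), 0), 31)
  for (off in .glcmOffsets)
    out <- c(out, .glcmStats(.cooccurrence(codes32, off, 32)))

  p5 <- stats::quantile(patch, 0.05, names = FALSE)
  p95 <- stats::quantile(patch, 0.95, names = FALSE)
  h <- tabulate(as.integer(round(patch)) + 1L, nbins = 256)
  out <- c(out, mean(patch),
           if (p95 + p5 < 1e-12) 0 else (p95 - p5) / (p95 + p5),
           .histEntropy(h / sum(h)))

  out <- c(out, stats::quantile(patch, c(0.2, 0.4, 0.6, 0.8), names = FALSE),
           .skewness(patch))

  pw <- Mod(stats::fft(patch - mean(patch)))^2
  pw <- pw[-1]                       # drop the (zeroed) DC bin
  mp <- mean(pw)
  out <- c(out, if (mp < 1e-12) 0 else stats::sd(pw) / mp,
           stats::quantile(log10(1 + pw), c(0.1, 0.3, 0.5, 0.7, 0.9),
                           names = FALSE))

  lbp <- .lbpCodes(patch)
  out <- c(out, .glcmStats(.cooccurrence(lbp, c(0, 1), 10)))
  ph <- tabulate(as.vector(lbp) + 1L, nbins = 10)
  ph <- ph / sum(ph)
  lv <- 0:9
  m <- sum(lv * ph)
  out <- c(out, m, sum((lv - m)^2 * ph), sum(ph^2), .histEntropy(ph))

  stats::setNames(out, imfFeatureNames())
}

#' Color-image descriptor for the IMF variant
#'
#' For a masked rib eye region of a color image: per-channel intensity
#' means, per-channel counts of pixels above the channel's Otsu threshold
#' (bright marbling flecks), and the magnitudes of the 8 lowest non-DC
#' Fourier coefficients of the masked, zero-padded luminance.
#'
#' @param img H x W x 3 array, values 0-255.
#' @param mask binary region mask.
#' @return named numeric vector of length 14.
#' @export
extractColorFeatures <- function(img, mask) {
  .assertMask(mask)
  if (sum(mask) == 0) stop("region is empty", call. = FALSE)
  idx <- mask == 1
  out <- numeric(0)
  for (ch in 1:3) {
    v <- img[, , ch][idx]
    out <- c(out, mean(v))
  }
  for (ch in 1:3) {
    v <- img[, , ch][idx]
    t <- tryCatch(.otsuContinuous(v), error = function(e) NA_real_)
    out <- c(out, if (is.na(t)) 0 else sum(v >= t))
  }
  lum <- (0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]) * mask
  px <- which(mask == 1, arr.ind = TRUE)
  crop <- lum[min(px[, 1]):max(px[, 1]), min(px[, 2]):max(px[, 2]),
              drop = FALSE]
  n2 <- 2^ceiling(log2(max(dim(crop), 32)))
  padded <- matrix(0, n2, n2)
  padded[seq_len(nrow(crop)), seq_len(ncol(crop))] <- crop
  F <- stats::fft(padded)
  ks <- expand.grid(kr = 0:4, kc = 0:4)
  ks <- ks[!(ks$kr == 0 & ks$kc == 0), ]
  ks <- ks[order(ks$kr^2 + ks$kc^2, ks$kr, ks$kc), ][1:8, ]
  out <- c(out, Mod(F[cbind(ks$kr + 1, ks$kc + 1)]))
  stats::setNames(out, c(paste0("mean_", c("r", "g", "b")),
                         paste0("count_above_otsu_", c("r", "g", "b")),
                         paste0("fourier_mag_", seq_len(8))))
}
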