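#' Detect the subcutaneous fat band in an ultrasound frame
#'
#' Otsu-binarizes the raw frame, labels the bright components, and among
#' those whose centroid lies in the upper third of the image returns the
#' one with the highest width/height ratio -- the thin, long horizontal
#' band characteristic of subcutaneous fat.
#'
#' @param img grayscale matrix, values 0-255.
#' @return list: \code{mask} (binary matrix of the selected component),
#'   \code{rows} c(first, last) row extent, \code{ratio} its aspect ratio.
#' @export
detectSubcutaneousFat <- function(img) {
  .assertMatrix(img)
  t <- otsuThreshold(img)
  lab <- EBImage::bwlabel((img >= t) * 1)
  nlab <- max(lab)
  if (nlab == 0) stop("no bright component found in the frame", call. = FALSE)
  H <- nrow(img)
  best <- NULL; bestRatio <- -Inf
  for (k in seq_len(nlab)) {
    px <- which(lab == k, arr.ind = TRUE)
    if (mean(px[, 1]) > H / 3) next
    ratio <- (diff(range(px[, 2])) + 1) / (diff(range(px[, 1])) + 1)
    if (ratio > bestRatio) { bestRatio <- ratio; best <- k }
  }
  if (is.null(best))
    stop("no candidate component in the upper third of the frame",
         call. = FALSE)
  mask <- (lab == best) * 1
  px <- which(mask == 1, arr.ind = TRUE)
  list(mask = mask, rows = range(px[, 1]), ratio = bestRatio)
}

#' Synthetic rib template
#'
#' A deterministic, column-symmetric raster emulating a generic rib echo:
#' a Gaussian-blurred bright semicircular arc (radius 0.4 x width) over a
#' dark vertical acoustic shadow.
#'
#' @param width,height template size in px (>= 8 each).
#' @return numeric matrix in [0, 1], rows x cols = height x width.
#' @export
makeRibTemplate <- function(width = 43, height = 31) {
  if (width < 8 || height < 8) stop("template must be at least 8 x 8",
                                    call. = FALSE)
  cx <- (width + 1) / 2
  cy <- 0.42 * height
  r <- 0.4 * width
  X <- matrix(rep(seq_len(width), each = height), height, width)
  Y <- matrix(rep(seq_len(height), width), height, width)
  d <- sqrt((X - cx)^2 + ((Y - cy) * 1.6)^2)   # flattened arc
  tpl <- matrix(0.45, height, width)
  tpl[abs(d - r) < 1.6 & Y <= cy + 2] <- 1
  tpl[Y > cy + 1 & abs(X - cx) < 0.55 * r & d > r - 1] <- 0.08
  tpl <- .gsmooth(tpl, 1)
  # enforce exact column symmetry (blur is symmetric, guard roundoff)
  (tpl + tpl[, rev(seq_len(width))]) / 2
}

#' Normalized cross-correlation map
#'
#' Correlation coefficient between the template and every (fully contained)
#' image window, computed with box-filter running sums. Border positions
#' where the template sticks out are NA.
#'
#' @param img grayscale matrix.
#' @param tpl template matrix (smaller than img).
#' @return matrix of NCC values in [-1, 1] (NA at borders), same size as
#'   \code{img}; entry (r, c) corresponds to the template centered there.
#' @export
matchTemplateNCC <- function(img, tpl) {
  .assertMatrix(img); .assertMatrix(tpl)
  th <- nrow(tpl); tw <- ncol(tpl)
  if (th > nrow(img) || tw > ncol(img))
    stop("template larger than image", call. = FALSE)
  nt <- th * tw
  t0 <- tpl - mean(tpl)
  tNorm <- sqrt(sum(t0^2))
  if (tNorm < 1e-12) stop("template is constant", call. = FALSE)
  box <- matrix(1, th, tw)
  s1 <- as.matrix(EBImage::filter2(img, box))
  s2 <- as.matrix(EBImage::filter2(img^2, box))
  # filter2 convolves (flips the kernel), so flip the centered template to
  # get correlation; no mean correction needed since t0 sums to zero
  tFlip <- t0[rev(seq_len(th)), rev(seq_len(tw)), drop = FALSE]
  num <- as.matrix(EBImage::filter2(img, tFlip))
  denom <- sqrt(pmax(s2 - s1^2 / nt, 0)) * tNorm
  out <- ifelse(denom > 1e-9, num / denom, 0)
  # mask borders where the window is not fully contained
  mr <- (th - 1) %/% 2; mc <- (tw - 1) %/% 2
  out[c(seq_len(mr), nrow(out) - seq_len(th - 1 - mr) + 1), ] <- NA
  out[, c(seq_len(mc), ncol(out) - seq_len(tw - 1 - mc) + 1)] <- NA
  out
}

#' Detect the two rib echoes
#'
#' Applies anisotropic diffusion, correlates the frame with the rib
#' template (normalized cross-correlation), suppresses non-maxima in a
#' square window, and returns the two strongest admissible maxima separated
#' horizontally by at least \code{minSeparation}.
#'
#' @param img grayscale matrix, values 0-255.
#' @param template matrix from \code{\link{makeRibTemplate}}.
#' @param minSeparation minimal horizontal distance between the two ribs
#'   (default W/4).
#' @param nmsWindow non-maximum-suppression window side (odd, default 31).
#' @param minCorrelation admissibility threshold on the NCC value
#'   (default 0.5).
#' @param diffusion list of anisotropic-diffusion parameters.
#' @return 2 x 2 matrix with columns (x, y), strongest rib first.
#' @export
detectRibs <- function(img, template = makeRibTemplate(),
                       minSeparation = ncol(img) / 4, nmsWindow = 31,
                       minCorrelation = 0.5,
                       diffusion = list(iterations = 15, K = 30,
                                        step = 0.15)) {
  sm <- anisotropicDiffusion(img, diffusion$iterations, diffusion$K,
                             diffusion$step)
  ncc <- matchTemplateNCC(sm, template)
  ncc[is.na(ncc)] <- -Inf
  half <- (nmsWindow - 1) %/% 2
  # running maximum over the NMS window by repeated 3x3 dilation
  dil <- ncc
  for (i in seq_len(half)) {
    dil <- pmax(dil, .shiftUp(dil), .shiftDown(dil))
    dil <- pmax(dil, .shiftLeft(dil), .shiftRight(dil))
  }
  peaks <- which(is.finite(ncc) & ncc == dil & ncc >= minCorrelation,
                 arr.ind = TRUE)
  if (nrow(peaks) == 0)
    stop("fewer than two admissible correlation maxima", call. = FALSE)
  vals <- ncc[peaks]
  ord <- order(vals, decreasing = TRUE)
  chosen <- integer(0)
  for (i in ord) {
    if (length(chosen) == 2) break
    if (all(abs(peaks[i, 2] - peaks[chosen, 2]) >= minSeparation))
      chosen <- c(chosen, i)
  }
  if (length(chosen) < 2)
    stop("fewer than two admissible correlation maxima", call. = FALSE)
  cbind(x = peaks[chosen, 2], y = peaks[chosen, 1])
}

#' Place the 80 x 80 analysis ROI
#'
#' Detects the subcutaneous fat band and the two ribs, then centers an
#' 80 x 80 square horizontally between the rib x positions and vertically
#' midway between the fat band's lower edge and the mean rib depth. Errors
#' if the available zone cannot contain the square (the caller may then
#' fall back to a manually chosen ROI).
#'
#' @param img grayscale matrix, values 0-255.
#' @param template rib template (default \code{\link{makeRibTemplate}()}).
#' @param ribTopMargin vertical clearance (px) subtracted above the rib
#'   centers when sizing the zone (default half the template height).
#' @param ... passed to \code{\link{detectRibs}}.
#' @return a \linkS4class{USROI}.
#' @export
extractROI <- function(img, template = makeRibTemplate(),
                       ribTopMargin = nrow(template) / 2, ...) {
  fat <- detectSubcutaneousFat(img)
  ribs <- detectRibs(img, template, ...)
  side <- 80
  top <- fat$rows[2] + 1
  bottom <- mean(ribs[, 2]) - ribTopMargin
  if (bottom - top + 1 < side)
    stop("zone between fat band and ribs is smaller than 80 x 80 ",
         "(height ", round(bottom - top + 1), " px); manual ROI required",
         call. = FALSE)
  xc <- mean(ribs[, 1])
  yc <- (top + bottom) / 2
  x0 <- round(xc - side / 2); y0 <- round(yc - side / 2)
  x0 <- min(max(1, x0), ncol(img) - side + 1)
  y0 <- min(max(top, y0), nrow(img) - side + 1)
  new("USROI", x = x0, y = y0, side = side,
      ribPositions = ribs, fatRows = fat$rows,
      imageDim = dim(img))
}

#' Crop the ROI patch from a frame
#'
#' @param img grayscale matrix.
#' @param roi a \linkS4class{USROI}.
#' @return 80 x 80 matrix.
#' @export
roiPatch <- function(img, roi) {
  img[roi@y:(roi@y + roi@side - 1), roi@x:(roi@x + roi@side - 1)]
}
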