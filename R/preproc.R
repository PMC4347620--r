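#' Otsu's optimal threshold
#'
#' Finds the cut point t in 0..255 that minimizes the within-class intensity
#' variance of the two classes \code{x < t} (dark) and \code{x >= t}
#' (bright), which is the classic Otsu criterion. Ties are broken by the
#' smallest threshold.
#'
#' @param gray numeric matrix with integer values in 0..255.
#' @return integer threshold t; pixels \code{< t} form the dark class.
#' @export
otsuThreshold <- function(gray) {
  .assertMatrix(gray)
  if (min(gray) < 0 || max(gray) > 255)
    stop("values must lie in [0,255]", call. = FALSE)
  h <- tabulate(as.integer(round(gray)) + 1L, nbins = 256)
  if (sum(h > 0) < 2)
    stop("degenerate input: constant raster of intensity ",
         which(h > 0) - 1L, call. = FALSE)
  n <- sum(h)
  lev <- 0:255
  cw <- cumsum(h)                      # pixels with value <= 0..255
  cs <- cumsum(h * lev)
  css <- cumsum(h * lev^2)
  # candidate cuts t = 0..255; dark class = values <= t - 1
  w1 <- c(0, cw[1:255]); s1 <- c(0, cs[1:255]); ss1 <- c(0, css[1:255])
  w2 <- n - w1
  m1 <- ifelse(w1 > 0, s1 / w1, 0)
  m2 <- ifelse(w2 > 0, (cs[256] - s1) / w2, 0)
  v1 <- ifelse(w1 > 0, ss1 / w1 - m1^2, 0)
  v2 <- ifelse(w2 > 0, (css[256] - ss1) / w2 - m2^2, 0)
  within <- (w1 * v1 + w2 * v2) / n
  as.integer(which.min(within) - 1L)   # which.min takes the first (smallest) tie
}

# Otsu on an arbitrary continuous channel: linearly rescale to 0..255 first.
.otsuContinuous <- function(v) {
  rng <- range(v)
  if (diff(rng) < 1e-9)
    stop("degenerate input: constant raster of intensity ", rng[1],
         call. = FALSE)
  scaled <- (v - rng[1]) / diff(rng) * 255
  t <- otsuThreshold(matrix(scaled, nrow = 1))
  rng[1] + t / 255 * diff(rng)
}

#' Convert an RGB raster to CIE Luv
#'
#' sRGB with the D65 white point (the channel thresholds of the meat
#' detection depend on this choice, so it is fixed and documented).
#'
#' @param img H x W x 3 array, values 0-255.
#' @return list of H x W matrices \code{L}, \code{u}, \code{v}.
#' @export
rgbToLuv <- function(img) {
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3) stop("img must be H x W x 3", call. = FALSE)
  rgb <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
               as.vector(img[, , 3])) / 255
  luv <- grDevices::convertColor(rgb, from = "sRGB", to = "Luv")
  list(L = matrix(luv[, 1], d[1], d[2]),
       u = matrix(luv[, 2], d[1], d[2]),
       v = matrix(luv[, 3], d[1], d[2]))
}

#' Background elimination on a color carcass image
#'
#' Otsu-binarizes the red channel (the steak -- meat, fat and bone -- is
#' bright in red against the near-black background), fills enclosed
#' background gaps and keeps the largest connected foreground component.
#'
#' @param img H x W x 3 array, values 0-255.
#' @return binary steak mask (H x W matrix).
#' @export
removeBackground <- function(img) {
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3) stop("img must be H x W x 3", call. = FALSE)
  red <- img[, , 1]
  t <- otsuThreshold(red)
  fg <- (red >= t) * 1
  if (sum(fg) == 0) stop("no steak found: empty foreground after thresholding",
                         call. = FALSE)
  fg <- .largestComponent(fg)
  fg <- as.matrix(EBImage::fillHull(fg))   # fill all enclosed background gaps
  if (sum(fg) == 0) stop("no steak found after cleanup", call. = FALSE)
  fg
}

#' Meat / non-meat detection inside the steak
#'
#' Binarizes the u and L channels of Luv and the G channel of RGB with Otsu's
#' method, restricted to the steak mask, and combines the three votes.
#' Polarity convention: meat is the darker class in G and in L, and the
#' higher-u class (lean muscle is red, hence strong positive u; fat and bone
#' are bright and nearly achromatic).
#'
#' @param img H x W x 3 array, values 0-255.
#' @param steak binary steak mask from \code{\link{removeBackground}}.
#' A channel only votes if its Otsu split actually separates two
#' populations: the separability eta (between-class over total variance)
#' must exceed \code{minEta}. A steak that is all fat has non-constant but
#' unimodal channels; every channel is then excluded with a warning and the
#' meat mask comes back empty. Channels that are constant inside the steak
#' are likewise excluded; if all three are constant no detection is
#' possible and an error is raised.
#'
#' @param rule voting rule combining the channel votes: \code{"majority"}
#'   (default, at least 2 of 3), \code{"and"}, or \code{"or"}.
#' @param minEta minimal Otsu separability for a channel to vote
#'   (default 0.75; an optimal split of pure Gaussian noise reaches ~0.64,
#'   real meat/fat splits exceed 0.99).
#' @return list with binary matrices \code{meat} and \code{nonmeat}
#'   partitioning the steak mask.
#' @export
detectMeatNonmeat <- function(img, steak, rule = c("majority", "and", "or"),
                              minEta = 0.75) {
  rule <- match.arg(rule)
  .assertMask(steak)
  if (sum(steak) == 0) stop("steak mask is empty", call. = FALSE)
  luv <- rgbToLuv(img)
  idx <- steak == 1
  channels <- list(u = luv$u, L = luv$L, G = img[, , 2])
  darkIsMeat <- c(u = FALSE, L = TRUE, G = TRUE)
  votes <- list()
  nConstant <- 0
  for (nm in names(channels)) {
    v <- channels[[nm]][idx]
    t <- tryCatch(.otsuContinuous(v), error = function(e) NULL)
    if (is.null(t)) {
      nConstant <- nConstant + 1
      warning("channel ", nm, " is constant within the steak mask; excluded")
      next
    }
    lo <- v < t
    w1 <- mean(lo)
    eta <- if (w1 %in% c(0, 1)) 0 else
      w1 * (1 - w1) * (mean(v[lo]) - mean(v[!lo]))^2 /
        (stats::var(v) * (length(v) - 1) / length(v))
    if (eta < minEta) {
      warning("channel ", nm, " separates poorly within the steak mask ",
              sprintf("(eta = %.2f); excluded", eta))
      next
    }
    votes[[nm]] <- if (darkIsMeat[[nm]]) v < t else v >= t
  }
  if (length(votes) == 0) {
    if (nConstant == length(channels))
      stop("all channels degenerate within the steak mask", call. = FALSE)
    warning("no channel separates meat from fat; returning an empty meat ",
            "mask (all-fat steak?)")
    return(list(meat = steak * 0, nonmeat = steak))
  }
  vs <- do.call(cbind, votes)
  meatVote <- switch(rule,
    majority = rowSums(vs) >= ceiling((ncol(vs) + 1) / 2),
    and = rowSums(vs) == ncol(vs),
    or = rowSums(vs) > 0)
  meat <- steak * 0
  meat[idx] <- meatVote * 1
  if (sum(meat) == 0)
    warning("no meat detected within the steak (all-fat steak?)")
  list(meat = meat, nonmeat = steak - meat)
}

#' Perona-Malik anisotropic diffusion
#'
#' Edge-preserving smoothing: iterates the 4-neighbor Perona-Malik update
#' with the exponential conduction function
#' \eqn{c(\nabla I) = \exp(-(|\nabla I|/K)^2)}. Output values never leave
#' the input range and a strong step edge does not move.
#'
#' @param gray numeric matrix.
#' @param iterations number of diffusion steps (default 15).
#' @param K conduction coefficient on the 8-bit intensity scale (default 30);
#'   gradients well above K are preserved, below K are smoothed.
#' @param step time step (default 0.15; must be <= 0.25 for stability of the
#'   4-neighbor discretization).
#' @return smoothed matrix, same shape.
#' @export
anisotropicDiffusion <- function(gray, iterations = 15, K = 30, step = 0.15) {
  .assertMatrix(gray)
  if (iterations < 1) stop("iterations must be >= 1", call. = FALSE)
  if (K <= 0 || step <= 0) stop("K and step must be positive", call. = FALSE)
  if (step > 0.25) stop("step must be <= 0.25 (stability bound)", call. = FALSE)
  u <- gray
  for (i in seq_len(iterations)) {
    dN <- .shiftDown(u) - u
    dS <- .shiftUp(u) - u
    dW <- .shiftRight(u) - u
    dE <- .shiftLeft(u) - u
    u <- u + step * (exp(-(dN / K)^2) * dN + exp(-(dS / K)^2) * dS +
                     exp(-(dW / K)^2) * dW + exp(-(dE / K)^2) * dE)
  }
  u
}
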