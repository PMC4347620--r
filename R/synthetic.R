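# Ground-truthed phantoms standing in for the study's unreleased steer
# database: a bright steak on a near-black background with a large meat
# region (rib eye), white fat seams, satellite muscles and a peripheral
# backfat band; and speckled B-mode frames with a subcutaneous fat band,
# two rib echoes and an inter-rib texture driven by a latent IMF scalar.

# point on a rotated ellipse at parameter gamma (y axis points down)
.ellipsePoint <- function(center, axes, rot, gamma) {
  px <- axes[1] * cos(gamma); py <- axes[2] * sin(gamma)
  cbind(x = center[1] + px * cos(rot) - py * sin(rot),
        y = center[2] + px * sin(rot) + py * cos(rot))
}

# outward unit normal of a rotated ellipse at parameter gamma
.ellipseNormal <- function(axes, rot, gamma) {
  nx <- axes[2] * cos(gamma); ny <- axes[1] * sin(gamma)
  len <- sqrt(nx^2 + ny^2)
  cbind(x = (nx * cos(rot) - ny * sin(rot)) / len,
        y = (nx * sin(rot) + ny * cos(rot)) / len)
}

.ellipseMask <- function(center, axes, rot, H, W) {
  X <- matrix(rep(seq_len(W), each = H), H, W)
  Y <- matrix(rep(seq_len(H), W), H, W)
  dx <- X - center[1]; dy <- Y - center[2]
  u <- dx * cos(rot) + dy * sin(rot)
  v <- -dx * sin(rot) + dy * cos(rot)
  ((u / axes[1])^2 + (v / axes[2])^2 <= 1) * 1
}

#' Specification of a steak phantom
#'
#' Geometry and appearance of a synthetic carcass cross-section: an
#' elliptical steak body, an elliptical rib eye, a thin meat strip lining
#' the body boundary along the backfat arc (so the meat convex hull reaches
#' the inner band edge there), satellite muscle blobs, and a backfat band
#' rendered outside the body with an arc-parameterized thickness function.
#'
#' @param imageSize c(rows, cols), default c(320, 320).
#' @param bodyCenter,bodyAxes,bodyRot steak body ellipse ((x, y), semi-axes
#'   px, rotation rad).
#' @param ribeyeCenter,ribeyeAxes,ribeyeRot rib eye ellipse.
#' @param bandRange ellipse-parameter range (rad) of the backfat arc;
#'   gamma = pi/2 is the image bottom.
#' @param bandThickness either a single thickness (px) or a function of the
#'   arc position s in [0, 1] returning px.
#' @param stripWidth width (px) of the boundary meat strip along the band
#'   arc.
#' @param satellites list of satellite muscle blobs, each
#'   list(center = c(x, y), radius).
#' @param meatColor,fatColor,backgroundColor RGB triples in 0-255.
#' @param noiseSigma per-pixel Gaussian noise sd (default 3).
#' @param seed RNG seed for the rendering noise.
#' @return spec list for \code{\link{generateSteakPhantom}}.
#' @export
steakPhantomSpec <- function(imageSize = c(320, 320),
                             bodyCenter = c(160, 150),
                             bodyAxes = c(132, 104), bodyRot = 0,
                             ribeyeCenter = c(160, 116),
                             ribeyeAxes = c(94, 60), ribeyeRot = 0.25,
                             bandRange = c(0.2 * pi, 0.8 * pi),
                             bandThickness = 20,
                             stripWidth = 9,
                             satellites = list(
                               list(center = c(52, 150), radius = 13),
                               list(center = c(268, 148), radius = 12)),
                             meatColor = c(168, 45, 52),
                             fatColor = c(243, 238, 228),
                             backgroundColor = c(12, 10, 11),
                             noiseSigma = 3, seed = 1) {
  tf <- if (is.function(bandThickness)) bandThickness
        else { th <- bandThickness; function(s) rep(th, length(s)) }
  s <- seq(0, 1, length.out = 11)
  if (any(tf(s) < 0)) stop("band thickness must be non-negative", call. = FALSE)
  if (any(c(meatColor, fatColor, backgroundColor) < 0) ||
      any(c(meatColor, fatColor, backgroundColor) > 255))
    stop("colors must lie in [0,255]", call. = FALSE)
  list(imageSize = imageSize, bodyCenter = bodyCenter, bodyAxes = bodyAxes,
       bodyRot = bodyRot, ribeyeCenter = ribeyeCenter,
       ribeyeAxes = ribeyeAxes, ribeyeRot = ribeyeRot, bandRange = bandRange,
       bandThickness = tf, stripWidth = stripWidth, satellites = satellites,
       meatColor = meatColor, fatColor = fatColor,
       backgroundColor = backgroundColor, noiseSigma = noiseSigma,
       seed = seed)
}

#' Generate a ground-truthed steak phantom
#'
#' Deterministic given the spec (including its seed). The ground truth holds
#' the exact rasterized masks (steak, meat, nonmeat, ribeye, band), the rib
#' eye pixel area, the band thickness samples along the arc, and the true
#' thickness at the 1/2 and 3/4 axis marks computed from the rib eye
#' geometry.
#'
#' @param spec list from \code{\link{steakPhantomSpec}}.
#' @return a \linkS4class{SteakPhantom}.
#' @export
generateSteakPhantom <- function(spec = steakPhantomSpec()) {
  H <- spec$imageSize[1]; W <- spec$imageSize[2]
  body <- .ellipseMask(spec$bodyCenter, spec$bodyAxes, spec$bodyRot, H, W)
  ribeye <- .ellipseMask(spec$ribeyeCenter, spec$ribeyeAxes, spec$ribeyeRot,
                         H, W)
  if (any(ribeye == 1 & body == 0))
    stop("rib eye must lie inside the steak body", call. = FALSE)

  gam <- seq(spec$bandRange[1], spec$bandRange[2], length.out = 400)
  sArc <- (gam - spec$bandRange[1]) / diff(spec$bandRange)
  thick <- spec$bandThickness(sArc)
  bPts <- .ellipsePoint(spec$bodyCenter, spec$bodyAxes, spec$bodyRot, gam)
  bNrm <- .ellipseNormal(spec$bodyAxes, spec$bodyRot, gam)
  outer <- bPts + bNrm * thick
  bandPoly <- rbind(bPts, outer[rev(seq_len(nrow(outer))), ])
  band <- .rasterizePolygon(bandPoly, H, W)
  band <- (band == 1 & body == 0) * 1

  inner <- bPts - bNrm * spec$stripWidth
  stripPoly <- rbind(bPts, inner[rev(seq_len(nrow(inner))), ])
  strip <- .rasterizePolygon(stripPoly, H, W)
  strip <- (strip == 1 & body == 1 & ribeye == 0) * 1

  sat <- matrix(0, H, W)
  for (b in spec$satellites)
    sat <- pmax(sat, .ellipseMask(b$center, c(b$radius, b$radius), 0, H, W))
  sat <- (sat == 1 & body == 1 & ribeye == 0 & strip == 0) * 1

  meat <- pmax(ribeye, pmax(strip, sat))
  steak <- pmax(body, band)
  nonmeat <- (steak == 1 & meat == 0) * 1

  img <- array(0, c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(spec$backgroundColor[ch], H, W)
    plane[nonmeat == 1] <- spec$fatColor[ch]
    plane[meat == 1] <- spec$meatColor[ch]
    img[, , ch] <- plane
  }
  img <- .withSeed(spec$seed, {
    noisy <- img + array(stats::rnorm(H * W * 3, 0, spec$noiseSigma),
                         c(H, W, 3))
    .clamp(round(noisy))
  })

  # true thickness at the 1/2 and 3/4 perpendicular marks, from the exact
  # rib eye geometry (canonical direction: positive x component)
  dir <- c(cos(spec$ribeyeRot), sin(spec$ribeyeRot))
  if (dir[1] < 0) dir <- -dir
  ctr <- spec$ribeyeCenter
  hl <- spec$ribeyeAxes[1]
  perp <- c(-dir[2], dir[1])
  if (perp[2] < 0) perp <- -perp         # band side is downward by design
  markTruth <- vapply(c(0.5, 0.75), function(f) {
    q <- ctr - hl * dir + f * 2 * hl * dir
    # intersect ray q + t*perp with the body boundary: nearest sample point
    tq <- ((bPts[, 1] - q[1]) * perp[1] + (bPts[, 2] - q[2]) * perp[2])
    lat <- abs((bPts[, 1] - q[1]) * (-perp[2]) + (bPts[, 2] - q[2]) * perp[1])
    ok <- tq > 0
    if (!any(ok)) return(NA_real_)
    i <- which(ok)[which.min(lat[ok])]
    thick[i]
  }, numeric(1))

  truth <- list(steak = steak, meat = meat, nonmeat = nonmeat,
                ribeye = ribeye, band = band, areaPx = sum(ribeye),
                bandSamples = data.frame(gamma = gam, s = sArc,
                                         x = bPts[, 1], y = bPts[, 2],
                                         thickness = thick),
                markThickness = c(half = markTruth[1],
                                  threequarter = markTruth[2]))
  new("SteakPhantom", image = img, truth = truth, spec = spec)
}

#' Draw a randomized steak phantom specification
#'
#' Samples rib eye size, position, rotation and (constant) backfat band
#' thickness from ranges representative of the carcass imagery the suite
#' emulates: rib eye semi-axes 78-96 x 48-58 px, rotation within 0.3 rad,
#' small center jitter, band thickness 10-40 px. Deterministic given the
#' seed, which also seeds the rendering noise.
#'
#' @param seed RNG seed.
#' @param bandThickness optional fixed thickness (px) or function of arc
#'   position, overriding the random draw.
#' @return spec list for \code{\link{generateSteakPhantom}}.
#' @export
sampleSteakPhantomSpec <- function(seed, bandThickness = NULL) {
  .withSeed(seed, {
    th <- if (is.null(bandThickness)) stats::runif(1, 10, 40)
          else bandThickness
    steakPhantomSpec(
      ribeyeCenter = c(stats::runif(1, 154, 166), stats::runif(1, 114, 122)),
      ribeyeAxes = c(stats::runif(1, 78, 96), stats::runif(1, 48, 58)),
      ribeyeRot = stats::runif(1, -0.3, 0.3),
      bandThickness = th, seed = seed)
  })
}

#' Specification of an ultrasound phantom
#'
#' @param imageSize c(rows, cols), default c(300, 300); must be at least
#'   200 x 200 so the 80 px ROI plus margins fit.
#' @param fatRows c(first, last) rows of the subcutaneous fat band; its
#'   centroid must lie in the upper third of the frame.
#' @param fatBrightness band intensity before speckle (default 215).
#' @param ribX two rib x positions (default c(75, 225)).
#' @param ribY rib center row (default 195); must be below the fat band.
#' @param ribSize template size c(width, height) of the stamped rib echo.
#' @param muscleLevel,skinLevel base intensities below/above the band.
#' @param speckleWeight multiplicative speckle mixing weight w in [0, 1]:
#'   the envelope is (1 - w) + w * R with R a normalized squared low-pass
#'   Gaussian field (Rayleigh-like), so w = 0 is speckle-free.
#' @param speckleCorr speckle correlation length (blur sigma, px).
#' @param imfScalar latent intramuscular-fat scalar in [0, 10] controlling
#'   the density of bright specks between the ribs.
#' @param seed RNG seed.
#' @return spec list for \code{\link{generateUSPhantom}}.
#' @export
usPhantomSpec <- function(imageSize = c(300, 300), fatRows = c(42, 58),
                          fatBrightness = 215, ribX = c(75, 225),
                          ribY = 195, ribSize = c(43, 31),
                          muscleLevel = 72, skinLevel = 45,
                          speckleWeight = 0.4, speckleCorr = 1.2,
                          imfScalar = 4, seed = 1) {
  if (any(imageSize < 200)) stop("image must be at least 200 x 200",
                                 call. = FALSE)
  if (mean(fatRows) > imageSize[1] / 3)
    stop("fat band must lie in the upper third", call. = FALSE)
  if (ribY <= fatRows[2]) stop("ribs must lie below the fat band",
                               call. = FALSE)
  if (imfScalar < 0) stop("imfScalar must be non-negative", call. = FALSE)
  list(imageSize = imageSize, fatRows = fatRows,
       fatBrightness = fatBrightness, ribX = ribX, ribY = ribY,
       ribSize = ribSize, muscleLevel = muscleLevel, skinLevel = skinLevel,
       speckleWeight = speckleWeight, speckleCorr = speckleCorr,
       imfScalar = imfScalar, seed = seed)
}

#' Draw a randomized ultrasound phantom specification
#'
#' Samples the fat band position and height, rib positions and depth, and
#' the latent IMF scalar from ranges that keep the anatomy valid (band in
#' the upper third, ribs below it, room for the 80 px ROI). Deterministic
#' given the seed.
#'
#' @param seed RNG seed.
#' @param imfScalar optional fixed IMF scalar overriding the random draw.
#' @return spec list for \code{\link{generateUSPhantom}}.
#' @export
sampleUSPhantomSpec <- function(seed, imfScalar = NULL) {
  .withSeed(seed, {
    top <- round(stats::runif(1, 35, 55))
    height <- round(stats::runif(1, 12, 20))
    usPhantomSpec(
      fatRows = c(top, top + height),
      ribX = c(round(stats::runif(1, 62, 88)),
               round(stats::runif(1, 212, 238))),
      ribY = round(stats::runif(1, 190, 215)),
      imfScalar = if (is.null(imfScalar)) stats::runif(1, 0, 8)
                  else imfScalar,
      seed = seed)
  })
}

#' Generate a ground-truthed ultrasound phantom
#'
#' Renders skin/fat-band/muscle base intensities, stamps two rib echoes
#' (bright convex arc over a dark acoustic shadow), sprinkles bright
#' intramuscular-fat specks in the inter-rib zone with density proportional
#' to the latent IMF scalar, and multiplies by a Rayleigh-like speckle
#' envelope. Deterministic given the spec seed.
#'
#' @param spec list from \code{\link{usPhantomSpec}}.
#' @return a \linkS4class{USPhantom}.
#' @export
generateUSPhantom <- function(spec = usPhantomSpec()) {
  H <- spec$imageSize[1]; W <- spec$imageSize[2]
  base <- matrix(spec$muscleLevel, H, W)
  base[seq_len(min(H, spec$fatRows[1] - 1)), ] <- spec$skinLevel
  fat <- matrix(0, H, W)
  fat[spec$fatRows[1]:spec$fatRows[2], ] <- 1
  base[fat == 1] <- spec$fatBrightness

  tpl <- makeRibTemplate(spec$ribSize[1], spec$ribSize[2])
  th <- nrow(tpl); tw <- ncol(tpl)
  ribMask <- matrix(0, H, W)
  for (rx in spec$ribX) {
    r0 <- round(spec$ribY - th / 2); c0 <- round(rx - tw / 2)
    rr <- pmax(1, r0 + 1):pmin(H, r0 + th)
    cc <- pmax(1, c0 + 1):pmin(W, c0 + tw)
    sub <- tpl[rr - r0, cc - c0, drop = FALSE]
    block <- base[rr, cc]
    block[sub > 0.75] <- 235
    block[sub < 0.18] <- 18
    base[rr, cc] <- block
    ribMask[rr, cc] <- pmax(ribMask[rr, cc], (sub > 0.6) * 1)
  }

  zone <- list(rows = c(spec$fatRows[2] + 8,
                        round(spec$ribY - spec$ribSize[2] / 2) - 6),
               cols = c(min(spec$ribX) + round(spec$ribSize[1] / 2) + 4,
                        max(spec$ribX) - round(spec$ribSize[1] / 2) - 4))

  img <- .withSeed(spec$seed, {
    zr <- zone$rows[1]:zone$rows[2]; zc <- zone$cols[1]:zone$cols[2]
    nz <- length(zr) * length(zc)
    p <- 0.002 + 0.0035 * spec$imfScalar
    nSpecks <- round(p * nz)
    if (nSpecks > 0) {
      sr <- sample(zr, nSpecks, replace = TRUE)
      sc <- sample(zc, nSpecks, replace = TRUE)
      base[cbind(sr, sc)] <- 185
      # small cross arms give specks a ~2 px footprint
      base[cbind(pmin(sr + 1, H), sc)] <- pmax(base[cbind(pmin(sr + 1, H), sc)], 160)
      base[cbind(sr, pmin(sc + 1, W))] <- pmax(base[cbind(sr, pmin(sc + 1, W))], 160)
    }
    g <- .gsmooth(matrix(stats::rnorm(H * W), H, W), spec$speckleCorr)
    r <- g^2 / mean(g^2)
    env <- (1 - spec$speckleWeight) + spec$speckleWeight * r
    .clamp(round(base * env))
  })

  truth <- list(fatMask = fat, fatRows = spec$fatRows,
                ribPositions = cbind(x = spec$ribX,
                                     y = rep(spec$ribY, length(spec$ribX))),
                ribMask = ribMask, roiZone = zone,
                imfScalar = spec$imfScalar)
  new("USPhantom", image = img, truth = truth, spec = spec)
}

#' Generate a synthetic IMF regression dataset
#'
#' One latent IMF scalar per animal (uniform on [0, 10]),
#' \code{imagesPerAnimal} ultrasound phantoms per animal sharing that
#' scalar, and one chemical-style label per animal,
#' \code{label = 2 + 0.8 * scalar + N(0, labelNoiseSigma)}, repeated across
#' its images. The per-animal grouping is returned so splits can be made
#' per animal.
#'
#' @param nAnimals number of animals (>= 5; default 69, giving 276 images
#'   at 4 per animal).
#' @param imagesPerAnimal frames per animal (default 4).
#' @param labelNoiseSigma label noise sd in IMF\% units (default 0.3).
#' @param seed RNG seed.
#' @param imageSize frame size passed to the phantom spec.
#' @return list: \code{phantoms} (list of \linkS4class{USPhantom}),
#'   \code{labels} (per image), \code{animal} (factor, per image),
#'   \code{scalars} (per animal), \code{animalLabels} (per animal).
#' @export
generateIMFDataset <- function(nAnimals = 69, imagesPerAnimal = 4,
                               labelNoiseSigma = 0.3, seed = 1,
                               imageSize = c(300, 300)) {
  if (nAnimals < 5) stop("need at least 5 animals", call. = FALSE)
  dat <- .withSeed(seed, {
    scalars <- stats::runif(nAnimals, 0, 10)
    animalLabels <- 2 + 0.8 * scalars +
      stats::rnorm(nAnimals, 0, labelNoiseSigma)
    imgSeeds <- sample.int(2^31 - 1, nAnimals * imagesPerAnimal)
    list(scalars = scalars, animalLabels = animalLabels, imgSeeds = imgSeeds)
  })
  n <- nAnimals * imagesPerAnimal
  phantoms <- vector("list", n)
  animal <- integer(n); labels <- numeric(n)
  k <- 0
  for (a in seq_len(nAnimals)) {
    for (j in seq_len(imagesPerAnimal)) {
      k <- k + 1
      phantoms[[k]] <- generateUSPhantom(
        usPhantomSpec(imageSize = imageSize, imfScalar = dat$scalars[a],
                      seed = dat$imgSeeds[k]))
      animal[k] <- a
      labels[k] <- dat$animalLabels[a]
    }
  }
  list(phantoms = phantoms, labels = labels, animal = factor(animal),
       scalars = dat$scalars, animalLabels = dat$animalLabels)
}
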