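#' Geodesic active contour edge indicator
#'
#' Computes \eqn{g = 1 / (1 + |\nabla (G_\sigma * I)|^2)}: the image is
#' smoothed with a Gaussian of standard deviation \code{sigma} and g decays
#' from 1 (flat regions) toward 0 at strong edges, halting the contour there.
#'
#' @param channel numeric matrix (intensities, typically 0-255).
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return matrix of g values in (0, 1].
#' @export
edgeIndicator <- function(channel, sigma = 1.5) {
  .assertMatrix(channel)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  s <- .gsmooth(channel, sigma)
  1 / (1 + .gradX(s)^2 + .gradY(s)^2)
}

#' High-contrast edge map from the non-meat mask
#'
#' The edge indicator applied to the binary non-meat detection result
#' (scaled 0/255), giving strong, clean stopping edges at meat/fat borders.
#'
#' @param nonmeat binary mask.
#' @param sigma Gaussian standard deviation (px).
#' @return edge indicator matrix in (0, 1].
#' @export
highContrastEdges <- function(nonmeat, sigma = 1.5) {
  .assertMask(nonmeat)
  edgeIndicator(nonmeat * 255, sigma)
}

#' Emphasized edge map from the diffused u channel
#'
#' The edge indicator applied to the u chromaticity channel (Luv) after
#' anisotropic diffusion; it carries softer meat/fat transitions that the
#' binary map misses. The u channel is linearly rescaled to 0-255 before
#' diffusion so gradients are on the 8-bit scale.
#'
#' @param img H x W x 3 array, values 0-255.
#' @param sigma Gaussian standard deviation (px).
#' @param iterations,K,step diffusion parameters, see
#'   \code{\link{anisotropicDiffusion}}.
#' @return edge indicator matrix in (0, 1].
#' @export
emphasizedEdges <- function(img, sigma = 1.5, iterations = 15, K = 30,
                            step = 0.15) {
  u <- rgbToLuv(img)$u
  rng <- range(u)
  u8 <- if (diff(rng) < 1e-9) u * 0 else (u - rng[1]) / diff(rng) * 255
  edgeIndicator(anisotropicDiffusion(u8, iterations, K, step), sigma)
}

#' Initial region by iterative erosion of the meat mask
#'
#' Discards small meat components (below \code{minFrac} of the mask area),
#' then erodes with a 3x3 cross until a single connected component remains.
#' The rib eye is the largest meat region, so the survivor lies inside it
#' and its boundary seeds the curve evolution.
#'
#' @param meat binary meat mask.
#' @param minFrac components smaller than this fraction of the meat area are
#'   removed before eroding (default 0.01).
#' @param minErosions erode at least this many times so the seed is strictly
#'   interior (default 2).
#' @return binary single-component mask.
#' @export
initialRegionByErosion <- function(meat, minFrac = 0.01, minErosions = 2) {
  .assertMask(meat)
  if (sum(meat) == 0) stop("meat mask is empty", call. = FALSE)
  lab <- EBImage::bwlabel(meat)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minFrac * sum(meat))
  m <- (matrix(lab %in% keep, nrow(meat)) & meat == 1) * 1
  kern <- EBImage::makeBrush(3, "diamond")       # 3x3 cross
  iter <- 0
  repeat {
    nc <- .componentCount(m)
    if (nc == 0)
      stop("erosion emptied the meat mask before reaching one component; ",
           "reduce minErosions or check the meat detection", call. = FALSE)
    if (nc == 1 && iter >= minErosions) break
    m2 <- as.matrix(EBImage::erode(m, kern))
    if (sum(m2) == 0 && nc == 1) break           # keep last non-empty survivor
    m <- m2
    iter <- iter + 1
    if (iter > 500) stop("erosion failed to converge", call. = FALSE)
  }
  if (sum(m) == 0) stop("erosion emptied the meat mask", call. = FALSE)
  m
}

#' Parameters of the distance-regularized level-set evolution
#'
#' @param timeStep explicit Euler time step (default 5).
#' @param mu weight of the distance-regularization term; requires
#'   \code{timeStep * mu < 1/4} for stability (default 0.04).
#' @param lambda weight of the geodesic length term (default 5).
#' @param alpha weighted area (balloon) term; negative expands a contour
#'   whose interior has negative phi (default -3).
#' @param epsilon width of the smoothed Dirac delta (default 1.5).
#' @param maxIterations iteration cap (default 400).
#' @param checkEvery interior-area growth is checked every this many
#'   iterations (default 20).
#' @param areaGrowthStop stop when the relative interior-area change between
#'   successive checks falls below this fraction (default 0.005).
#' @return validated parameter list.
#' @export
drlseParams <- function(timeStep = 5, mu = 0.04, lambda = 5, alpha = -3,
                        epsilon = 1.5, maxIterations = 400, checkEvery = 20,
                        areaGrowthStop = 0.005) {
  if (timeStep * mu >= 0.25)
    stop("timeStep * mu must be < 1/4 for stability", call. = FALSE)
  if (maxIterations < 1) stop("maxIterations must be >= 1", call. = FALSE)
  list(timeStep = timeStep, mu = mu, lambda = lambda, alpha = alpha,
       epsilon = epsilon, maxIterations = maxIterations,
       checkEvery = checkEvery, areaGrowthStop = areaGrowthStop)
}

#' Signed-distance initialization of the level-set field
#'
#' phi is the Euclidean distance to the mask boundary, negative inside, so
#' the field starts with |grad phi| = 1 and the distance regularization
#' only has to maintain it.
#'
#' @param mask binary mask of the initial interior region.
#' @return numeric matrix phi.
#' @export
initLevelSet <- function(mask) {
  .assertMask(mask)
  if (sum(mask) == 0) stop("initial region is empty", call. = FALSE)
  dOut <- as.matrix(EBImage::distmap(1 - mask))
  dIn <- as.matrix(EBImage::distmap(mask))
  dOut - dIn + (mask * 2 - 1) * 0.5
}

# one DRLSE update step (double-well potential); phi modified and returned
.drlseStep <- function(phi, g, gx, gy, p) {
  px <- .gradX(phi); py <- .gradY(phi)
  mag <- sqrt(px^2 + py^2)
  eps <- 1e-10
  nx <- px / (mag + eps); ny <- py / (mag + eps)
  curvature <- .gradX(nx) + .gradY(ny)
  # double-well distance regularization: d p(s)/ds / s
  a <- (mag >= 0) & (mag <= 1)
  ps <- a * sin(2 * pi * mag) / (2 * pi) + (!a) * (mag - 1)
  dps <- ifelse(ps != 0, ps, 1) / ifelse(mag != 0, mag, 1)
  distReg <- .gradX(dps * px - px) + .gradY(dps * py - py) +
    (.shiftUp(phi) + .shiftDown(phi) + .shiftLeft(phi) + .shiftRight(phi) -
       4 * phi)
  dirac <- (abs(phi) <= p$epsilon) *
    (1 + cos(pi * phi / p$epsilon)) / (2 * p$epsilon)
  edgeTerm <- dirac * (gx * nx + gy * ny) + dirac * g * curvature
  areaTerm <- dirac * g
  phi + p$timeStep * (p$mu * distReg + p$lambda * edgeTerm +
                        p$alpha * areaTerm)
}

#' One stage of distance-regularized level-set evolution
#'
#' Iterates the DRLSE update (distance regularization + geodesic edge term +
#' weighted area term) until the interior-area change between successive
#' checks falls below \code{areaGrowthStop}, or \code{maxIterations} is
#' reached. The contour interior is \code{phi < 0}.
#'
#' On return the field is re-anchored to an exact signed distance function
#' of its interior (the zero level set is unchanged), so the distance
#' regularity contract holds globally, not only in the narrow band the
#' double-well potential maintains during iteration.
#'
#' @param phi level-set field (matrix), e.g. from \code{\link{initLevelSet}}.
#' @param g edge indicator matrix, same shape.
#' @param params list from \code{\link{drlseParams}}.
#' @param redistance re-anchor phi to a signed distance function on return
#'   (default TRUE).
#' @return list with \code{phi} (evolved field), \code{iterations} run, and
#'   \code{converged} flag (TRUE if the growth-stop rule fired).
#' @export
evolveStage <- function(phi, g, params = drlseParams(), redistance = TRUE) {
  .assertMatrix(phi); .assertMatrix(g)
  if (!all(dim(phi) == dim(g)))
    stop("phi and g must have the same shape", call. = FALSE)
  gx <- .gradX(g); gy <- .gradY(g)
  lastArea <- sum(phi < 0)
  iter <- 0
  converged <- FALSE
  while (iter < params$maxIterations) {
    phi <- .drlseStep(phi, g, gx, gy, params)
    iter <- iter + 1
    if (any(!is.finite(phi)))
      stop("level-set evolution diverged at iteration ", iter, call. = FALSE)
    if (iter %% params$checkEvery == 0) {
      area <- sum(phi < 0)
      if (abs(area - lastArea) <= params$areaGrowthStop * max(lastArea, 1)) {
        converged <- TRUE
        break
      }
      lastArea <- area
    }
  }
  if (redistance) {
    interior <- (phi < 0) * 1
    if (sum(interior) > 0 && sum(interior) < length(interior))
      phi <- initLevelSet(interior)
  }
  list(phi = phi, iterations = iter, converged = converged)
}

#' Segment the rib eye and report its area
#'
#' Full pipeline: background elimination, meat/non-meat detection, edge maps,
#' initial region by iterative erosion, then three evolution stages:
#' \enumerate{
#'   \item fast expansion driven by the high-contrast (binary non-meat) edge
#'     map alone, growth checked every \code{checkEvery1} iterations;
#'   \item slower evolution adding the emphasized (diffused u channel) edge
#'     energy -- the two maps are combined as their pointwise minimum -- with
#'     growth checked every \code{checkEvery2} iterations and the learned
#'     area-growth stop;
#'   \item exactly \code{refineIterations} refinement iterations with no
#'     balloon force.
#' }
#'
#' The stage edge maps are tempered as \code{g^edgeExponent}: a monotone
#' transform that keeps every edge valley in place but lifts its saturated
#' floor (a binary input on the 0/255 scale drives the edge indicator to
#' ~1e-4 across several px, which would stall the front at the valley
#' entrance), so the balloon force carries the contour to the valley
#' center where the geodesic attraction pins it.
#'
#' @param img H x W x 3 array, values 0-255.
#' @param sigma Gaussian standard deviation of the edge indicator (px).
#' @param alpha1,alpha2 balloon weights of stages 1 and 2.
#' @param maxIter1,maxIter2 iteration caps of stages 1 and 2.
#' @param checkEvery1,checkEvery2 growth-check periods of stages 1 and 2.
#' @param areaGrowthStop learned relative growth threshold stopping stage 2
#'   (and stage 1).
#' @param refineIterations stage-3 iteration count (default 10).
#' @param edgeExponent tempering exponent applied to the edge maps
#'   (default 0.3; small enough to lift the saturated valley floor, large
#'   enough that the geodesic attraction still dominates the balloon force
#'   on the valley's far slope).
#' @param diffusion list of anisotropic-diffusion parameters
#'   (\code{iterations}, \code{K}, \code{step}) for the emphasized edges.
#' @return a \linkS4class{RibeyeSegmentation}.
#' @export
segmentRibeye <- function(img, sigma = 1.5, alpha1 = -3, alpha2 = -1.5,
                          maxIter1 = 500, maxIter2 = 300,
                          checkEvery1 = 20, checkEvery2 = 10,
                          areaGrowthStop = 0.005, refineIterations = 10,
                          edgeExponent = 0.3,
                          diffusion = list(iterations = 15, K = 30,
                                           step = 0.15)) {
  steak <- removeBackground(img)
  mn <- detectMeatNonmeat(img, steak)
  gHigh <- highContrastEdges(mn$nonmeat, sigma)^edgeExponent
  gEmph <- emphasizedEdges(img, sigma, diffusion$iterations, diffusion$K,
                           diffusion$step)^edgeExponent
  seed <- initialRegionByErosion(mn$meat)
  phi <- initLevelSet(seed)

  s1 <- evolveStage(phi, gHigh,
                    drlseParams(alpha = alpha1, maxIterations = maxIter1,
                                checkEvery = checkEvery1,
                                areaGrowthStop = areaGrowthStop))
  gBoth <- pmin(gHigh, gEmph)
  s2 <- evolveStage(s1$phi, gBoth,
                    drlseParams(alpha = alpha2, maxIterations = maxIter2,
                                checkEvery = checkEvery2,
                                areaGrowthStop = areaGrowthStop))
  s3 <- evolveStage(s2$phi, gBoth,
                    drlseParams(alpha = 0, maxIterations = refineIterations,
                                checkEvery = refineIterations + 1))

  mask <- .largestComponent((s3$phi < 0) * steak)  # rib eye lies in the steak
  new("RibeyeSegmentation", mask = mask, areaPx = sum(mask),
      stageIterations = c(stage1 = as.integer(s1$iterations),
                          stage2 = as.integer(s2$iterations),
                          stage3 = as.integer(s3$iterations)),
      diagnostics = list(stage1Converged = s1$converged,
                         stage2Converged = s2$converged,
                         sigma = sigma, alpha = c(alpha1, alpha2, 0),
                         areaGrowthStop = areaGrowthStop,
                         seedArea = sum(seed),
                         bandFraction = c(
                           stage1 = bandGradientFraction(s1$phi),
                           stage2 = bandGradientFraction(s2$phi),
                           stage3 = bandGradientFraction(s3$phi)),
                         phi = s3$phi))
}

#' Check the signed-distance band property of a level-set field
#'
#' Fraction of pixels within \code{band} px of the zero level set whose
#' gradient magnitude lies in [1 - tol, 1 + tol]; the distance
#' regularization keeps this near 1.
#'
#' @param phi level-set field.
#' @param band band half-width in px (default 5).
#' @param tol gradient tolerance (default 0.2).
#' @return fraction in [0, 1].
#' @export
bandGradientFraction <- function(phi, band = 5, tol = 0.2) {
  interior <- (phi < 0) * 1
  if (sum(interior) == 0 || sum(interior) == length(phi)) return(NA_real_)
  contour <- .maskBoundary(interior)
  d <- .distanceTo(contour)
  sel <- d <= band
  mag <- sqrt(.gradX(phi)^2 + .gradY(phi)^2)
  mean(mag[sel] >= 1 - tol & mag[sel] <= 1 + tol)
}
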