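# Curves are matrices with columns (x, y) in pixel coordinates (x = col,
# y = row), vertices ordered along the curve, implicitly closed.

# trace the outer contour of the largest component of a mask, as (x, y)
.maskContour <- function(mask) {
  m <- .largestComponent(mask)
  if (sum(m) == 0) stop("mask is empty", call. = FALSE)
  oc <- EBImage::ocontour(m)[[1]]            # 0-based (row, col)
  cbind(x = oc[, 2] + 1, y = oc[, 1] + 1)
}

.polygonPerimeter <- function(pts) {
  nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
  sum(sqrt(rowSums((nxt - pts)^2)))
}

# insert vertices so no closed-polygon edge exceeds maxSpacing
.densifyPolygon <- function(pts, maxSpacing = 0.5) {
  n <- nrow(pts)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    a <- pts[i, ]; b <- pts[if (i == n) 1 else i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / maxSpacing))
    t <- (seq_len(k) - 1) / k
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  res <- do.call(rbind, out)
  colnames(res) <- c("x", "y")
  res
}

# arc-length positions (starting at 0 on vertex 1) of a closed polygon
.arcPositions <- function(pts) {
  seg <- sqrt(rowSums((pts - rbind(pts[nrow(pts), ], pts[-nrow(pts), ]))^2))
  seg[1] <- 0
  cumsum(seg)
}

# uniform arc-length resampling of a closed polygon to n points
.resampleClosed <- function(pts, n) {
  dense <- .densifyPolygon(pts, 0.25)
  arc <- .arcPositions(dense)
  L <- arc[length(arc)] +
    sqrt(sum((dense[1, ] - dense[length(arc), ])^2))
  s <- (seq_len(n) - 1) * L / n
  idx <- findInterval(s, arc)
  out <- dense[idx, , drop = FALSE]
  list(points = out, arc = arc[idx], length = L)
}

#' Initial backfat curve: convex hull of the meat
#'
#' The backfat contains no meat and borders the steak edge, so the convex
#' hull of all meat pixels traces the inner limit of the band.
#'
#' @param meat binary meat mask.
#' @return closed convex polygon, matrix with columns (x, y).
#' @export
buildInitialCurve <- function(meat) {
  .assertMask(meat)
  px <- which(meat == 1, arr.ind = TRUE)
  if (nrow(px) < 3) stop("need at least 3 meat pixels", call. = FALSE)
  pts <- cbind(x = px[, 2], y = px[, 1])
  hull <- grDevices::chull(pts)
  if (length(hull) < 3)
    stop("meat pixels are collinear; no hull polygon exists", call. = FALSE)
  pts[hull, , drop = FALSE]
}

#' Target backfat curve: boundary of steak-plus-hull union
#'
#' The outer limit of the band is the edge of the union of the steak region
#' (from background elimination) and the hull region. Wherever that edge
#' would touch the initial curve, the union is locally dilated so the two
#' curves never intersect.
#'
#' @param steak binary steak mask.
#' @param initial convex polygon from \code{\link{buildInitialCurve}}.
#' @param contactRadius dilation radius (px) applied at contact points
#'   (default 2).
#' @return closed polygon, matrix with columns (x, y).
#' @export
buildTargetCurve <- function(steak, initial, contactRadius = 2) {
  .assertMask(steak)
  H <- nrow(steak); W <- ncol(steak)
  hullMask <- .rasterizeConvexPolygon(initial, H, W)
  u <- ((steak + hullMask) > 0) * 1
  if (.componentCount(u) != 1)
    stop("union of steak and hull region is disconnected", call. = FALSE)
  ub <- .maskBoundary(u)
  dHull <- .distanceTo(.maskBoundary(hullMask))
  contact <- (ub == 1 & dHull <= 1.5) * 1
  if (sum(contact) > 0 && contactRadius > 0) {
    zone <- as.matrix(EBImage::dilate(
      contact, EBImage::makeBrush(2 * 4 + 1, "disc")))
    grown <- as.matrix(EBImage::dilate(
      u, EBImage::makeBrush(2 * contactRadius + 1, "disc")))
    u <- ((u + grown * zone) > 0) * 1
  }
  .maskContour(u)
}

#' Evolve the inner curve along its normals to the target
#'
#' The initial curve is resampled to control points (about one per
#' \code{spacing} px of arc), then each point marches along the local
#' outward normal in increments of \code{step} until it comes within
#' \code{step} of the target curve; the residual distance is added on
#' arrival. Points are created when neighbors drift more than twice the
#' spacing apart (and merged when they bunch below a quarter of it), so the
#' sampling density survives the outward growth. The recorded value per
#' point is its cumulative path length -- the backfat thickness.
#'
#' @param initial closed polygon (x, y), the inner curve.
#' @param target closed polygon (x, y), the outer curve; must not intersect
#'   the initial curve.
#' @param step advance per iteration in px (default 1).
#' @param spacing control-point spacing: one control point is kept per this
#'   many px of dense (1 px) arc, mirroring resampling every 50 points
#'   (default 50).
#' @param maxIterations per-point iteration cap (default 500).
#' @param anchors optional matrix of (x, y) points lying on the initial
#'   curve that must appear among the control points (e.g. the 1/2 and 3/4
#'   axis marks).
#' @param gridDim optional c(rows, cols) of the underlying raster; defaults
#'   to the target bounding box plus a margin.
#' @return list: \code{points} final positions, \code{origins} start
#'   positions on the initial curve, \code{pathLength} per-point thickness
#'   (px), \code{anchorIndex} indices of the anchor points, \code{arcLength}
#'   arc position of each origin along the initial curve.
#' @export
evolveBetweenCurves <- function(initial, target, step = 1, spacing = 50,
                                maxIterations = 500, anchors = NULL,
                                gridDim = NULL) {
  if (nrow(initial) < 3 || nrow(target) < 3)
    stop("curves need at least 3 points", call. = FALSE)
  denseT <- .densifyPolygon(target, 0.5)
  if (is.null(gridDim))
    gridDim <- c(ceiling(max(denseT[, 2])) + 10, ceiling(max(denseT[, 1])) + 10)
  tm <- matrix(0, gridDim[1], gridDim[2])
  tm[cbind(pmin(pmax(round(denseT[, 2]), 1), gridDim[1]),
           pmin(pmax(round(denseT[, 1]), 1), gridDim[2]))] <- 1
  dt <- .distanceTo(tm)

  nCtrl <- max(5, round(.polygonPerimeter(initial) / spacing))
  rs <- .resampleClosed(initial, nCtrl)
  pts <- rs$points
  arc <- rs$arc
  anchorId <- integer(0)
  if (!is.null(anchors)) {
    dense <- .densifyPolygon(initial, 0.25)
    arcAll <- .arcPositions(dense)
    for (i in seq_len(nrow(anchors))) {
      d2 <- (dense[, 1] - anchors[i, 1])^2 + (dense[, 2] - anchors[i, 2])^2
      aArc <- arcAll[which.min(d2)]
      newPt <- dense[which.min(d2), , drop = FALSE]
      # snap to an existing control point if one is very close (a 1 px gap
      # between neighbors would tilt the local normal badly)
      dCtrl <- sqrt((pts[, 1] - newPt[1])^2 + (pts[, 2] - newPt[2])^2)
      k <- which.min(dCtrl)
      if (dCtrl[k] < spacing / 4 && !(k %in% anchorId)) {
        pts[k, ] <- newPt
        arc[k] <- aArc
        anchorId <- c(anchorId, k)
      } else {
        pos <- findInterval(aArc, arc)
        pts <- rbind(pts[seq_len(pos), , drop = FALSE], newPt,
                     pts[-seq_len(pos), , drop = FALSE])
        arc <- c(arc[seq_len(pos)], aArc, arc[-seq_len(pos)])
        anchorId[anchorId >= pos + 1L] <- anchorId[anchorId >= pos + 1L] + 1L
        anchorId <- c(anchorId, pos + 1L)
      }
    }
  }
  n0 <- nrow(pts)
  origins <- pts
  path <- numeric(n0)
  isAnchor <- seq_len(n0) %in% anchorId
  # the target lives on a raster: its interpolated distance field bottoms
  # out around half a pixel, so arrival needs at least that much slack
  arrTol <- max(step, 0.75)
  d0 <- .interp2(dt, pts[, 1], pts[, 2])
  active <- d0 > arrTol
  path[!active] <- path[!active] + d0[!active]

  centroidOf <- function(p) colMeans(p)
  for (it in seq_len(maxIterations)) {
    if (!any(active)) break
    n <- nrow(pts)
    prv <- c(n, seq_len(n - 1)); nxt <- c(2:n, 1)
    tx <- pts[nxt, 1] - pts[prv, 1]; ty <- pts[nxt, 2] - pts[prv, 2]
    tl <- sqrt(tx^2 + ty^2) + 1e-12
    nx <- ty / tl; ny <- -tx / tl
    ctr <- centroidOf(pts)
    flip <- (nx * (pts[, 1] - ctr[1]) + ny * (pts[, 2] - ctr[2])) < 0
    nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]
    # arrival is checked before stepping so points never cross the target:
    # a point within one step advances by exactly the remaining distance
    d <- .interp2(dt, pts[, 1], pts[, 2])
    arriving <- active & d <= arrTol
    adv <- ifelse(arriving, d, step)
    pts[active, 1] <- pts[active, 1] + adv[active] * nx[active]
    pts[active, 2] <- pts[active, 2] + adv[active] * ny[active]
    path[active] <- path[active] + adv[active]
    active[arriving] <- FALSE

    # maintain sampling density: split long gaps, merge bunched points
    gap <- sqrt(rowSums((pts[nxt, , drop = FALSE] - pts)^2))
    long <- which(gap > 2 * spacing)
    if (length(long) > 0) {
      for (i in rev(long)) {
        j <- if (i == n) 1 else i + 1
        mid <- (pts[i, ] + pts[j, ]) / 2
        midO <- (origins[i, ] + origins[j, ]) / 2
        midPath <- (path[i] + path[j]) / 2
        dmid <- .interp2(dt, mid[1], mid[2])
        newActive <- dmid > arrTol
        insertAt <- i
        pts <- rbind(pts[seq_len(insertAt), , drop = FALSE], mid,
                     pts[-seq_len(insertAt), , drop = FALSE])
        origins <- rbind(origins[seq_len(insertAt), , drop = FALSE], midO,
                         origins[-seq_len(insertAt), , drop = FALSE])
        path <- append(path, midPath + if (newActive) 0 else dmid,
                       after = insertAt)
        active <- append(active, newActive, after = insertAt)
        isAnchor <- append(isAnchor, FALSE, after = insertAt)
        arc <- append(arc, mean(arc[c(i, min(j, length(arc)))]),
                      after = insertAt)
      }
    } else {
      short <- which(gap < spacing / 4 & !isAnchor & !isAnchor[nxt] &
                       nrow(pts) > 8)
      if (length(short) > 0) {
        drop <- unique(pmin(short + 1, nrow(pts)))
        drop <- drop[!isAnchor[drop]]
        if (length(drop) > 0 && length(drop) < nrow(pts) - 4) {
          keepIdx <- setdiff(seq_len(nrow(pts)), drop)
          pts <- pts[keepIdx, , drop = FALSE]
          origins <- origins[keepIdx, , drop = FALSE]
          path <- path[keepIdx]; active <- active[keepIdx]
          isAnchor <- isAnchor[keepIdx]; arc <- arc[keepIdx]
        }
      }
    }
  }
  if (any(active))
    stop("points failed to reach the target within ", maxIterations,
         " iterations: indices ", paste(which(active), collapse = ", "),
         call. = FALSE)
  list(points = pts, origins = origins, pathLength = path,
       anchorIndex = which(isAnchor), arcLength = arc)
}

#' Principal axis of the rib eye
#'
#' Centroid from the first image moments; direction as the major principal
#' axis of the second central moments (canonicalized to a positive x
#' component); half-length as the maximal extent of the mask along that
#' direction.
#'
#' @param ribeye binary rib eye mask.
#' @return list with \code{centroid} (x, y), unit \code{direction},
#'   \code{halfLength} (px) and \code{degenerate} flag.
#' @export
ribeyeAxis <- function(ribeye) {
  .assertMask(ribeye)
  px <- which(ribeye == 1, arr.ind = TRUE)
  if (nrow(px) == 0) stop("rib eye mask is empty", call. = FALSE)
  x <- px[, 2]; y <- px[, 1]
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2); mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  degenerate <- FALSE
  spread <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
  if (spread < 1e-3 * (mu20 + mu02)) {
    warning("mask is nearly isotropic; principal direction is degenerate, ",
            "using the x axis")
    theta <- 0
    degenerate <- TRUE
  } else {
    theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)
  }
  dir <- c(cos(theta), sin(theta))
  if (dir[1] < 0 || (dir[1] == 0 && dir[2] < 0)) dir <- -dir
  proj <- (x - cx) * dir[1] + (y - cy) * dir[2]
  list(centroid = c(x = cx, y = cy), direction = c(x = dir[1], y = dir[2]),
       halfLength = max(abs(proj)), degenerate = degenerate)
}

# farthest intersection of ray q + t*d (t > 0) with a closed polygon
.rayPolygonExit <- function(q, d, poly) {
  n <- nrow(poly)
  nxt <- c(2:n, 1)
  best <- -Inf
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[nxt[i], ]
    e <- b - a
    den <- d[1] * (-e[2]) - d[2] * (-e[1])
    if (abs(den) < 1e-12) next
    rhs <- a - q
    t <- (rhs[1] * (-e[2]) - rhs[2] * (-e[1])) / den
    s <- (d[1] * rhs[2] - d[2] * rhs[1]) / den
    if (t > 0 && s >= -1e-9 && s <= 1 + 1e-9) best <- max(best, t)
  }
  if (!is.finite(best)) return(NULL)
  q + best * d
}

#' Measure the backfat thickness profile
#'
#' Full pipeline: background elimination and meat detection, inner curve
#' (meat convex hull) and outer curve (steak/hull union boundary), normal
#' curve evolution between them, and the two standard marks where the
#' perpendiculars at 1/2 and 3/4 of the rib eye principal axis meet the
#' band. The profiled section runs between those two marks.
#'
#' The acquisition protocol orients the cut consistently, so the backfat
#' side of the axis is a configuration choice: \code{"down"} (default) and
#' \code{"up"} select the image-downward or -upward perpendicular;
#' \code{"auto"} picks the direction with the larger curve separation at
#' the feet (the backfat layer is thicker than the thin fat rim elsewhere),
#' for frames of unknown orientation. A perpendicular whose foot shows no
#' band (separation below \code{minBand}) raises an error naming the axis
#' fraction.
#'
#' @param img H x W x 3 array, values 0-255.
#' @param ribeye binary rib eye mask (e.g. from \code{\link{segmentRibeye}}).
#' @param step,spacing,maxIterations evolution controls, see
#'   \code{\link{evolveBetweenCurves}}.
#' @param minBand minimal curve separation (px) for a perpendicular to count
#'   as hitting the band (default 2.5).
#' @param side which perpendicular direction points at the backfat:
#'   \code{"down"} (default), \code{"up"} or \code{"auto"}.
#' @param scalePxPerUnit optional physical scale; thicknesses stay in px.
#' @return a \linkS4class{ThicknessProfile}.
#' @export
measureBackfat <- function(img, ribeye, step = 1, spacing = 50,
                           maxIterations = 500, minBand = 2.5,
                           side = c("down", "up", "auto"),
                           scalePxPerUnit = NA_real_) {
  side <- match.arg(side)
  steak <- removeBackground(img)
  mn <- detectMeatNonmeat(img, steak)
  initial <- buildInitialCurve(mn$meat)
  target <- buildTargetCurve(steak, initial)

  ax <- ribeyeAxis(ribeye)
  e1 <- ax$centroid - ax$halfLength * ax$direction
  u <- c(-ax$direction[2], ax$direction[1])
  denseT <- .densifyPolygon(target, 0.5)
  H <- nrow(steak); W <- ncol(steak)
  tm <- matrix(0, H, W)
  tm[cbind(pmin(pmax(round(denseT[, 2]), 1), H),
           pmin(pmax(round(denseT[, 1]), 1), W))] <- 1
  dt <- .distanceTo(tm)

  feetFor <- function(dirSign) {
    lapply(c(0.5, 0.75), function(f) {
      q <- e1 + f * 2 * ax$halfLength * ax$direction
      .rayPolygonExit(q, dirSign * u, initial)
    })
  }
  sepOf <- function(feet) {
    if (any(vapply(feet, is.null, logical(1)))) return(-Inf)
    min(vapply(feet, function(p) .interp2(dt, p[1], p[2]), numeric(1)))
  }
  downSign <- if (u[2] >= 0) 1 else -1   # sign making the perpendicular
  feet <- switch(side,                   # point toward increasing y
    down = feetFor(downSign),
    up = feetFor(-downSign),
    auto = {
      fPlus <- feetFor(1); fMinus <- feetFor(-1)
      if (sepOf(fPlus) >= sepOf(fMinus)) fPlus else fMinus
    })
  seps <- vapply(feet, function(p)
    if (is.null(p)) -Inf else .interp2(dt, p[1], p[2]), numeric(1))
  for (i in c(1, 2)) {
    if (seps[i] < minBand)
      stop(sprintf(
        "perpendicular at axis fraction %s does not meet the backfat band",
        c("1/2", "3/4")[i]), call. = FALSE)
  }
  anchors <- do.call(rbind, feet)

  ev <- evolveBetweenCurves(initial, target, step = step, spacing = spacing,
                            maxIterations = maxIterations, anchors = anchors,
                            gridDim = c(H, W))
  if (length(ev$anchorIndex) < 2)
    stop("mark anchor points were lost during the evolution", call. = FALSE)
  # section between the two marks: take the shorter arc
  n <- length(ev$pathLength)
  i1 <- ev$anchorIndex[1]; i2 <- ev$anchorIndex[2]
  if (i1 > i2) { tmp <- i1; i1 <- i2; i2 <- tmp }
  inner <- i1:i2
  outer <- c(i2:n, 1:i1)
  arcOf <- function(idx) {
    o <- ev$origins[idx, , drop = FALSE]
    sum(sqrt(rowSums(diff(o)^2)))
  }
  sel <- if (arcOf(inner) <= arcOf(outer)) inner else outer
  o <- ev$origins[sel, , drop = FALSE]
  segLen <- c(0, sqrt(rowSums(diff(o)^2)))
  pos <- cumsum(segLen)
  if (max(pos) > 0) pos <- pos / max(pos)
  keepIdx <- !duplicated(pos)
  new("ThicknessProfile",
      arcPosition = pos[keepIdx], thicknessPx = ev$pathLength[sel][keepIdx],
      markHalf = ev$pathLength[ev$anchorIndex[1]],
      markThreeQuarter = ev$pathLength[ev$anchorIndex[2]],
      markPoints = anchors, scalePxPerUnit = scalePxPerUnit)
}
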