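# Shared raster helpers. Convention throughout the package: grayscale images
# and masks are base-R matrices indexed [row, col]; point coordinates are
# (x = col, y = row), 1-based; masks are 0/1.

.clamp <- function(x, lo = 0, hi = 255) pmax(pmin(x, hi), lo)  # keeps dim(x)

# replicate-padding shifts (Neumann boundary)
.shiftUp    <- function(m) m[c(2:nrow(m), nrow(m)), , drop = FALSE]
.shiftDown  <- function(m) m[c(1, 1:(nrow(m) - 1)), , drop = FALSE]
.shiftLeft  <- function(m) m[, c(2:ncol(m), ncol(m)), drop = FALSE]
.shiftRight <- function(m) m[, c(1, 1:(ncol(m) - 1)), drop = FALSE]

# central-difference gradient; x along columns, y along rows
.gradX <- function(m) (.shiftLeft(m) - .shiftRight(m)) / 2
.gradY <- function(m) (.shiftUp(m) - .shiftDown(m)) / 2

.assertMatrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x) || length(x) == 0)
    stop(name, " must be a non-empty numeric matrix", call. = FALSE)
  if (any(!is.finite(x)))
    stop(name, " must be finite everywhere", call. = FALSE)
  invisible(x)
}

.assertMask <- function(x, name = deparse(substitute(x))) {
  .assertMatrix(x, name)
  if (!all(x %in% c(0, 1)))
    stop(name, " must be a binary 0/1 mask", call. = FALSE)
  invisible(x)
}

.largestComponent <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) == 0) return(mask * 0)
  sizes <- tabulate(lab[lab > 0])
  (lab == which.max(sizes)) * 1
}

.componentCount <- function(mask) max(EBImage::bwlabel(mask))

# Gaussian smoothing on a plain matrix (EBImage backed)
.gsmooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  as.matrix(EBImage::gblur(m, sigma = sigma))
}

# rasterize a closed polygon (vertices as (x, y) rows) on an H x W grid by
# even-odd scanline filling; handles non-convex rings
.rasterizePolygon <- function(vertices, H, W) {
  mask <- matrix(0, H, W)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  rows <- max(1L, floor(min(vy))):min(H, ceiling(max(vy)))
  nxt <- c(2:n, 1)
  for (r in rows) {
    xs <- numeric(0)
    for (i in seq_len(n)) {
      y1 <- vy[i]; y2 <- vy[nxt[i]]
      if ((y1 <= r && y2 > r) || (y2 <= r && y1 > r))   # half-open crossing
        xs <- c(xs, vx[i] + (r - y1) / (y2 - y1) * (vx[nxt[i]] - vx[i]))
    }
    xs <- sort(xs)
    k <- 1
    while (k + 1 <= length(xs)) {
      c1 <- max(1L, ceiling(xs[k] - 1e-9))
      c2 <- min(W, floor(xs[k + 1] + 1e-9))
      if (c1 <= c2) mask[r, c1:c2] <- 1
      k <- k + 2
    }
  }
  mask
}

.rasterizeConvexPolygon <- function(vertices, H, W)
  .rasterizePolygon(vertices, H, W)

# boundary pixels of a mask (8-connected erosion residue)
.maskBoundary <- function(mask) {
  er <- as.matrix(EBImage::erode(mask, EBImage::makeBrush(3, "box")))
  (mask == 1 & er == 0) * 1
}

# Euclidean distance (px) from every pixel to the nearest set pixel of mask
.distanceTo <- function(mask) {
  if (sum(mask) == 0) stop("distance target is empty", call. = FALSE)
  as.matrix(EBImage::distmap(1 - mask))
}

# bilinear lookup of matrix m at points (x = col, y = row); clamps to bounds
.interp2 <- function(m, x, y) {
  H <- nrow(m); W <- ncol(m)
  x <- pmin(pmax(x, 1), W); y <- pmin(pmax(y, 1), H)
  x0 <- pmin(floor(x), W - 1); y0 <- pmin(floor(y), H - 1)
  fx <- x - x0; fy <- y - y0
  m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    m[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    m[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    m[cbind(y0 + 1, x0 + 1)] * fx * fy
}

# run expr under a private RNG stream derived from seed (NULL = use current)
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
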