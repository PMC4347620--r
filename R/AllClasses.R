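#' @import methods
NULL

#' Rib eye segmentation result
#'
#' Holds the binary rib eye mask produced by the three-stage level-set
#' evolution, the interior pixel count, and per-stage diagnostics.
#'
#' @slot mask integer matrix (0/1), same size as the input image.
#' @slot areaPx interior pixel count of the final zero level set.
#' @slot stageIterations named integer vector of iterations run per stage.
#' @slot diagnostics list of run diagnostics (stop reasons, parameters used).
#' @exportClass RibeyeSegmentation
setClass("RibeyeSegmentation",
  representation(mask = "matrix", areaPx = "numeric",
                 stageIterations = "integer", diagnostics = "list"),
  validity = function(object) {
    if (!all(object@mask %in% c(0, 1))) return("mask must be binary 0/1")
    if (length(object@areaPx) != 1 || object@areaPx < 0)
      return("areaPx must be a single non-negative count")
    if (abs(object@areaPx - sum(object@mask)) > 0.5)
      return("areaPx must equal the mask pixel count")
    TRUE
  })

#' Backfat thickness profile
#'
#' Per-point backfat thicknesses along the evolved section of the inner
#' curve, plus the two standard marks at the perpendicular projections of
#' 1/2 and 3/4 of the rib eye principal axis.
#'
#' @slot arcPosition numeric, strictly increasing positions in [0,1] along
#'   the profiled section.
#' @slot thicknessPx numeric, non-negative path-length thicknesses (px).
#' @slot markHalf thickness (px) at the 1/2-axis perpendicular.
#' @slot markThreeQuarter thickness (px) at the 3/4-axis perpendicular.
#' @slot markPoints 2x2 matrix of the mark foot points (x, y).
#' @slot scalePxPerUnit optional physical scale (px per length unit); NA if
#'   unknown, in which case thicknesses are in pixels only.
#' @exportClass ThicknessProfile
setClass("ThicknessProfile",
  representation(arcPosition = "numeric", thicknessPx = "numeric",
                 markHalf = "numeric", markThreeQuarter = "numeric",
                 markPoints = "matrix", scalePxPerUnit = "numeric"),
  prototype(scalePxPerUnit = NA_real_),
  validity = function(object) {
    if (length(object@arcPosition) != length(object@thicknessPx))
      return("arcPosition and thicknessPx must have equal length")
    if (any(object@thicknessPx < 0)) return("thickness must be non-negative")
    if (length(object@arcPosition) > 1 && any(diff(object@arcPosition) <= 0))
      return("arcPosition must be strictly increasing")
    if (any(object@arcPosition < 0 | object@arcPosition > 1))
      return("arcPosition must lie in [0,1]")
    TRUE
  })

#' Ultrasound region of interest
#'
#' An 80x80 analysis square placed between the subcutaneous fat band and the
#' two rib echoes of a B-mode frame.
#'
#' @slot x,y top-left corner (column, row), 1-based.
#' @slot side side length in pixels (always 80).
#' @slot ribPositions 2x2 matrix of detected rib centers (x, y).
#' @slot fatRows integer range (first, last) of the fat band rows.
#' @slot imageDim dimensions (rows, cols) of the source frame.
#' @exportClass USROI
setClass("USROI",
  representation(x = "numeric", y = "numeric", side = "numeric",
                 ribPositions = "matrix", fatRows = "numeric",
                 imageDim = "numeric"),
  validity = function(object) {
    if (object@side != 80) return("ROI side must be exactly 80 px")
    if (object@x < 1 || object@y < 1 ||
        object@y + object@side - 1 > object@imageDim[1] ||
        object@x + object@side - 1 > object@imageDim[2])
      return("ROI must lie entirely within the image")
    TRUE
  })

#' Principal component reduction of the texture feature space
#'
#' Centered (optionally standardized) PCA used to map the 42-dimensional
#' texture descriptor to k components before regression.
#'
#' @slot center feature means (length p).
#' @slot scale feature scalings applied before projection (1s if unscaled).
#' @slot loadings p x k matrix with orthonormal columns.
#' @slot explainedVarianceRatio fraction of total variance per component,
#'   non-increasing.
#' @exportClass PCAModel
setClass("PCAModel",
  representation(center = "numeric", scale = "numeric", loadings = "matrix",
                 explainedVarianceRatio = "numeric"),
  validity = function(object) {
    p <- length(object@center)
    if (nrow(object@loadings) != p) return("loadings rows must match center")
    g <- crossprod(object@loadings)
    if (max(abs(g - diag(ncol(object@loadings)))) > 1e-8)
      return("loading columns must be orthonormal (tolerance 1e-8)")
    r <- object@explainedVarianceRatio
    if (any(r < -1e-12 | r > 1 + 1e-12)) return("variance ratios must be in [0,1]")
    if (length(r) > 1 && any(diff(r) > 1e-12))
      return("variance ratios must be non-increasing")
    TRUE
  })

#' Intramuscular fat regression model
#'
#' PCA reduction plus an RBF-kernel support vector regressor mapping texture
#' features of an ultrasound ROI to IMF%.
#'
#' @slot pca the fitted \linkS4class{PCAModel}.
#' @slot svm the fitted \code{e1071::svm} regressor (NULL when the training
#'   labels were constant).
#' @slot gamma selected RBF kernel width.
#' @slot tolerance selected termination tolerance.
#' @slot constant fallback constant prediction (NA unless labels constant).
#' @slot cvTable data.frame of the cross-validated grid (gamma, tolerance,
#'   rmse).
#' @slot featureNames names of the input features, in registry order.
#' @exportClass IMFModel
setClass("IMFModel",
  representation(pca = "PCAModel", svm = "ANY", gamma = "numeric",
                 tolerance = "numeric", constant = "numeric",
                 cvTable = "data.frame", featureNames = "character"))

#' Ground-truthed steak phantom
#'
#' A synthetic color carcass image together with the exact masks and
#' parameters it was rasterized from.
#'
#' @slot image H x W x 3 array, values 0-255.
#' @slot truth list of ground-truth masks and geometry (steak, meat, nonmeat,
#'   ribeye, backfat band, true area, thickness profile).
#' @slot spec the generating specification list.
#' @exportClass SteakPhantom
setClass("SteakPhantom",
  representation(image = "array", truth = "list", spec = "list"),
  validity = function(object) {
    d <- dim(object@image)
    if (length(d) != 3 || d[3] != 3) return("image must be H x W x 3")
    if (min(object@image) < 0 || max(object@image) > 255)
      return("image values must lie in [0,255]")
    TRUE
  })

#' Ground-truthed ultrasound phantom
#'
#' A synthetic speckled B-mode frame with a subcutaneous fat band, two rib
#' echoes and an inter-rib texture driven by a latent IMF scalar.
#'
#' @slot image H x W matrix, values 0-255.
#' @slot truth list of ground truth (fat band mask/rows, rib positions,
#'   imf scalar, ROI zone).
#' @slot spec the generating specification list.
#' @exportClass USPhantom
setClass("USPhantom",
  representation(image = "matrix", truth = "list", spec = "list"),
  validity = function(object) {
    if (min(object@image) < 0 || max(object@image) > 255)
      return("image values must lie in [0,255]")
    TRUE
  })
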