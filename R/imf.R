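#' Fit a PCA reduction of the feature space
#'
#' Centered principal component analysis (optionally standardized) via the
#' singular value decomposition, keeping \code{k} components.
#'
#' @param features n x p numeric matrix (n > k).
#' @param k number of components (default 10).
#' @param scale standardize features to unit variance before the
#'   decomposition (default FALSE); near-constant features get scale 1.
#' @return a \linkS4class{PCAModel}.
#' @export
fitPCA <- function(features, k = 10, scale = FALSE) {
  features <- as.matrix(features)
  n <- nrow(features); p <- ncol(features)
  if (n <= k) stop("need more observations than components", call. = FALSE)
  if (p < k) stop("cannot keep more components than features", call. = FALSE)
  ctr <- colMeans(features)
  scl <- rep(1, p)
  if (scale) {
    s <- apply(features, 2, stats::sd)
    scl <- ifelse(s > 1e-10, s, 1)
  }
  pc <- stats::prcomp(sweep(sweep(features, 2, ctr), 2, scl, "/"),
                      center = FALSE, scale. = FALSE)
  vars <- pc$sdev^2
  ratios <- vars / sum(vars)
  rank <- sum(vars > max(vars) * 1e-12)
  if (rank < k)
    warning("feature matrix has rank ", rank, " < k = ", k,
            "; trailing variance ratios are ~0")
  ld <- pc$rotation[, seq_len(k), drop = FALSE]
  r <- ratios[seq_len(k)]
  r[seq_len(k) > rank] <- 0
  new("PCAModel", center = ctr, scale = scl, loadings = ld,
      explainedVarianceRatio = r)
}

#' Project features into PCA component space
#'
#' @param model a \linkS4class{PCAModel}.
#' @param features numeric vector (length p) or n x p matrix.
#' @return n x k matrix of component scores.
#' @export
applyPCA <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model@center))
    stop("feature dimension mismatch: expected ", length(model@center),
         call. = FALSE)
  sweep(sweep(as.matrix(features), 2, model@center), 2, model@scale, "/") %*%
    model@loadings
}

#' Train the IMF% support vector regressor
#'
#' Standardizes the 42 features, reduces them to \code{k} principal
#' components, grid-searches the RBF kernel width gamma and the termination
#' tolerance by cross-validated RMSE on the training set only, and fits the
#' final epsilon-regression on all training data.
#'
#' @param features n x 42 matrix (n >= 20).
#' @param labels IMF\% values, length n.
#' @param cvFolds cross-validation folds (default 5).
#' @param gammaGrid log grid for the RBF gamma (default 2^-10 .. 2^3).
#' @param tolGrid termination tolerances (default 1e-4, 1e-3, 1e-2).
#' @param cost regularization constant, fixed (default 1).
#' @param k retained PCA components (default 10).
#' @return an \linkS4class{IMFModel}.
#' @export
trainIMFModel <- function(features, labels, cvFolds = 5,
                          gammaGrid = 2^seq(-10, 3),
                          tolGrid = c(1e-4, 1e-3, 1e-2), cost = 1, k = 10) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 20) stop("need at least 20 training samples", call. = FALSE)
  if (length(labels) != n || any(!is.finite(labels)))
    stop("labels must be finite and match the feature rows", call. = FALSE)
  pca <- fitPCA(features, k = k, scale = TRUE)
  if (stats::sd(labels) < 1e-10) {
    warning("constant training labels; model predicts the constant")
    return(new("IMFModel", pca = pca, svm = NULL, gamma = NA_real_,
               tolerance = NA_real_, constant = labels[1],
               cvTable = data.frame(), featureNames = colnames(features) %||%
                 imfFeatureNames()))
  }
  z <- applyPCA(pca, features)
  folds <- sample(rep(seq_len(cvFolds), length.out = n))
  grid <- expand.grid(gamma = gammaGrid, tolerance = tolGrid)
  grid$rmse <- NA_real_
  for (i in seq_len(nrow(grid))) {
    errs <- numeric(0)
    for (f in seq_len(cvFolds)) {
      tr <- folds != f
      fit <- e1071::svm(z[tr, , drop = FALSE], labels[tr],
                        type = "eps-regression", kernel = "radial",
                        gamma = grid$gamma[i], tolerance = grid$tolerance[i],
                        cost = cost)
      pred <- stats::predict(fit, z[!tr, , drop = FALSE])
      errs <- c(errs, (pred - labels[!tr])^2)
    }
    grid$rmse[i] <- sqrt(mean(errs))
  }
  best <- which.min(grid$rmse)
  fit <- e1071::svm(z, labels, type = "eps-regression", kernel = "radial",
                    gamma = grid$gamma[best], tolerance = grid$tolerance[best],
                    cost = cost)
  new("IMFModel", pca = pca, svm = fit, gamma = grid$gamma[best],
      tolerance = grid$tolerance[best], constant = NA_real_, cvTable = grid,
      featureNames = colnames(features) %||% imfFeatureNames())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict IMF% from ROI texture features
#'
#' @param model an \linkS4class{IMFModel}.
#' @param features numeric vector of length 42 or an n x 42 matrix.
#' @return numeric predictions.
#' @export
predictIMF <- function(model, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != length(model@pca@center))
    stop("feature vector must have length ", length(model@pca@center),
         call. = FALSE)
  if (!is.na(model@constant)) return(rep(model@constant, nrow(features)))
  as.numeric(stats::predict(model@svm, applyPCA(model@pca, features)))
}

#' @describeIn IMFModel-class predict method delegating to
#'   \code{\link{predictIMF}}
#' @param object an \linkS4class{IMFModel}
#' @param ... the feature vector or matrix
#' @export
setMethod("predict", "IMFModel",
          function(object, ...) predictIMF(object, ...))
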