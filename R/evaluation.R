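#' Relative area error
#'
#' \eqn{\epsilon_1 = |A_{auto} - A_{manual}| / A_{manual}}, the error
#' magnitude of an automatic area against the manual reference.
#'
#' @param aAuto automatic area (px).
#' @param aManual manual reference area (px, > 0).
#' @return non-negative scalar.
#' @export
relativeAreaError <- function(aAuto, aManual) {
  if (any(aManual <= 0)) stop("manual area must be positive", call. = FALSE)
  abs(aAuto - aManual) / aManual
}

#' Concordance error
#'
#' \eqn{\epsilon_2 = 1 - A_{inter} / A_{union}}: one minus the Jaccard
#' overlap of the automatic and manual masks. 0 for identical masks, 1 for
#' disjoint ones.
#'
#' @param rAuto,rManual binary masks of the same shape.
#' @return scalar in [0, 1].
#' @export
concordance <- function(rAuto, rManual) {
  .assertMask(rAuto); .assertMask(rManual)
  if (!all(dim(rAuto) == dim(rManual)))
    stop("masks must have the same shape", call. = FALSE)
  uni <- sum(rAuto == 1 | rManual == 1)
  if (uni == 0) stop("both masks are empty", call. = FALSE)
  (uni - sum(rAuto == 1 & rManual == 1)) / uni
}

#' Regression evaluation: RMSE and squared Pearson correlation
#'
#' @param pred,truth paired numeric vectors (length >= 2; truth not
#'   constant).
#' @return list with \code{rmse} and \code{r2}.
#' @export
regressionEval <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 2)
    stop("need at least 2 paired values", call. = FALSE)
  if (stats::sd(truth) < 1e-12)
    stop("truth is constant; r2 is undefined", call. = FALSE)
  list(rmse = sqrt(mean((pred - truth)^2)),
       r2 = stats::cor(pred, truth)^2)
}

#' Seeded random train/test splits
#'
#' Training size is \code{round(n * fraction)}. The default fraction is
#' 0.67 — the two-decimal form of the nominal 2/3 — because it reproduces
#' the reference train/test sizes of both evaluation protocols (153
#' observations split 103/50; 69 animal groups split 46/23, i.e. 184/92
#' images at 4 per animal), which an exact 2/3 cannot: 2/3 of 153 is
#' exactly 102. With \code{groups}, whole groups are assigned to one side
#' (rounding on the group count) and indices of their members are
#' returned.
#'
#' @param n number of observations.
#' @param fraction training fraction (default 0.67, see above).
#' @param repetitions number of independent splits (default 1).
#' @param seed RNG seed (NULL = current stream).
#' @param groups optional grouping vector of length n (e.g. animal ids).
#' @return list of \code{repetitions} lists with \code{train} and
#'   \code{test} index vectors.
#' @export
makeSplits <- function(n, fraction = 0.67, repetitions = 1, seed = NULL,
                       groups = NULL) {
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  .withSeed(seed, {
    lapply(seq_len(repetitions), function(r) {
      if (is.null(groups)) {
        tr <- sort(sample.int(n, round(n * fraction)))
      } else {
        g <- unique(groups)
        gTr <- sample(g, round(length(g) * fraction))
        tr <- which(groups %in% gTr)
      }
      list(train = tr, test = setdiff(seq_len(n), tr))
    })
  })
}

#' Repeated split evaluation protocol
#'
#' Repeatedly splits the data, fits with \code{fitFun}, predicts the
#' held-out side with \code{predictFun}, and reports per-repetition RMSE,
#' squared Pearson correlation, the RMSE of the mean-of-training baseline,
#' and the fraction of held-out cases whose relative error falls under each
#' threshold.
#'
#' @param x n x p feature matrix.
#' @param y length-n response.
#' @param fitFun function(xTrain, yTrain) returning a model.
#' @param predictFun function(model, xTest) returning predictions.
#' @param fraction training fraction (default 0.67, the nominal 2/3; see
#'   \code{\link{makeSplits}}).
#' @param repetitions number of repeated splits (default 100).
#' @param seed RNG seed for the splits (and fits).
#' @param groups optional grouping vector; splits are made per group.
#' @param thresholds relative-error thresholds reported as fractions
#'   (default 10\% and 15\%).
#' @return data.frame with one row per repetition; columns rep, nTrain,
#'   nTest, rmse, r2, baselineRmse and fracUnder<thr> per threshold.
#' @export
evaluateProtocol <- function(x, y, fitFun, predictFun, fraction = 0.67,
                             repetitions = 100, seed = 1, groups = NULL,
                             thresholds = c(0.10, 0.15)) {
  x <- as.matrix(x)
  n <- nrow(x)
  splits <- makeSplits(n, fraction, repetitions, seed = seed, groups = groups)
  rows <- lapply(seq_along(splits), function(i) {
    sp <- splits[[i]]
    model <- .withSeed(seed + i, fitFun(x[sp$train, , drop = FALSE],
                                        y[sp$train]))
    pred <- predictFun(model, x[sp$test, , drop = FALSE])
    ev <- regressionEval(pred, y[sp$test])
    base <- sqrt(mean((mean(y[sp$train]) - y[sp$test])^2))
    relErr <- abs(pred - y[sp$test]) / pmax(abs(y[sp$test]), 1e-12)
    out <- data.frame(rep = i, nTrain = length(sp$train),
                      nTest = length(sp$test), rmse = ev$rmse, r2 = ev$r2,
                      baselineRmse = base)
    for (th in thresholds)
      out[[sprintf("fracUnder%g", 100 * th)]] <- mean(relErr < th)
    out
  })
  do.call(rbind, rows)
}
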