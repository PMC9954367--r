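#' Recursive feature elimination with grouped cross-validation
#'
#' Repeatedly fits a linear estimator on standardized features, removes the
#' fraction (or count) \code{step} of remaining features with the smallest
#' absolute weights, and records the mean cross-validated balanced accuracy
#' at every subset size. Folds are grouped by case so pixels of one patient
#' never straddle train and validation. The returned subset is the size
#' maximizing the CV score, preferring the smaller subset on ties --
#' shrinking the dimensionality of the feature space to limit overfitting.
#'
#' @param fm a \linkS4class{PixelFeatureMatrix} with both classes present.
#' @param estimator "svm" or "sgd" (linear weights are used for ranking).
#' @param nFolds cross-validation folds (grouped by case).
#' @param step features removed per round: a fraction of the remaining set
#'   when < 1, an absolute count when >= 1 (default 10\%).
#' @param seed integer seed.
#' @param config see \code{\link{classifierConfig}}.
#' @param maxRows optional cap on rows used during selection; rows are
#'   subsampled deterministically, stratified by case and label.
#' @return A \linkS4class{SelectionResult}.
#' @export
rfeCV <- function(fm, estimator = "svm", nFolds = 5L, step = 0.1,
                  seed = 1L, config = classifierConfig(), maxRows = NULL) {
  if (nFolds < 2) stop("nFolds must be >= 2")
  y <- featureInfo(fm)$label
  if (length(unique(y)) < 2) stop("need both classes for selection")
  if (!is.null(maxRows) && nrow(fm@features) > maxRows) {
    set.seed(deriveSeed(seed, 23L))
    strata <- paste(featureInfo(fm)$case, y)
    keep <- unlist(lapply(split(seq_along(strata), strata), function(rows) {
      take <- max(1L, round(length(rows) * maxRows / length(strata)))
      if (length(rows) <= take) rows else sample(rows, take)
    }), use.names = FALSE)
    fm <- subsetRows(fm, sort(keep))
    y <- featureInfo(fm)$label
  }
  info <- featureInfo(fm)
  folds <- assignFolds(info$case, nFolds, deriveSeed(seed, 31L))
  x <- featureValues(fm)

  cvScore <- function(feats) {
    scores <- vapply(sort(unique(folds)), function(f) {
      tr <- folds != f
      xt <- x[tr, feats, drop = FALSE]
      yt <- y[tr]
      if (length(unique(yt)) < 2) return(NA_real_)
      std <- standardizeFit(xt)
      fit <- fitLinearCore(standardizeApply(xt, std), yt, estimator,
                           config, deriveSeed(seed, 100L + f))
      xv <- standardizeApply(x[!tr, feats, drop = FALSE], std)
      pred <- as.integer(as.numeric(xv %*% fit$w) + fit$b > 0)
      m <- classificationMetrics(confusionCounts(pred, y[!tr]))
      ba <- m[["balanced_accuracy"]]
      if (is.na(ba)) m[["accuracy"]] else ba
    }, numeric(1))
    mean(scores, na.rm = TRUE)
  }

  remaining <- colnames(x)
  eliminated <- character(0)
  sizes <- integer(0); scores <- numeric(0); sets <- list()
  repeat {
    sizes <- c(sizes, length(remaining))
    scores <- c(scores, cvScore(remaining))
    sets[[length(sets) + 1L]] <- remaining
    if (length(remaining) == 1L) break
    std <- standardizeFit(x[, remaining, drop = FALSE])
    fit <- fitLinearCore(standardizeApply(x[, remaining, drop = FALSE], std),
                         y, estimator, config, deriveSeed(seed, 55L))
    nDrop <- if (step < 1) max(1L, floor(step * length(remaining)))
             else as.integer(step)
    nDrop <- min(nDrop, length(remaining) - 1L)
    ord <- order(abs(fit$w))
    drop <- remaining[ord[seq_len(nDrop)]]
    eliminated <- c(eliminated, drop)
    remaining <- setdiff(remaining, drop)
  }
  best <- which(scores == max(scores))
  best <- best[which.min(sizes[best])]  # ties -> smaller subset
  new("SelectionResult",
      ranking = c(eliminated, remaining),
      selected = sets[[best]],
      cvScores = data.frame(size = sizes, score = scores),
      estimator = estimator)
}
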