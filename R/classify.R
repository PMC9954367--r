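#' Classifier training configuration
#'
#' @param cost SVM soft-margin cost C.
#' @param kernel SVM kernel ("linear" default; weights are needed for
#'   recursive feature elimination).
#' @param alpha L2 regularization strength of the SGD linear model.
#' @param epochs SGD training epochs.
#' @param batch SGD mini-batch size.
#' @param eta0 SGD initial learning rate (inverse-scaling schedule
#'   \code{eta0 / t^0.25}).
#' @param svmTolerance libsvm termination tolerance.
#' @return List of settings.
#' @export
classifierConfig <- function(cost = 1, kernel = "linear", alpha = 1e-4,
                             epochs = 100L, batch = 32L, eta0 = 0.05,
                             svmTolerance = 1e-6) {
  list(cost = cost, kernel = kernel, alpha = alpha,
       epochs = as.integer(epochs), batch = as.integer(batch), eta0 = eta0,
       svmTolerance = svmTolerance)
}

standardizeFit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

standardizeApply <- function(x, std) {
  sweep(sweep(x, 2, std$center, "-"), 2, std$scale, "/")
}

# Inverse-frequency class weights: n / (2 n_c).
classWeights <- function(y) {
  n <- length(y)
  c("0" = n / (2 * sum(y == 0)), "1" = n / (2 * sum(y == 1)))
}

# Fit a linear decision function w x + b on standardized features such that
# a positive score predicts class 1 (high cellularity).
fitLinearCore <- function(xs, y, kind, config, seed) {
  if (kind == "svm") {
    cw <- classWeights(y)
    # average-loss convention: the soft-margin penalty is normalized by the
    # training-set size (reference 1000 rows), so duplicating the training
    # set leaves the decision function unchanged
    model <- e1071::svm(xs, factor(y, levels = c(0, 1)),
                        kernel = config$kernel,
                        cost = config$cost * 1000 / length(y),
                        class.weights = cw, scale = FALSE,
                        tolerance = if (is.null(config$svmTolerance)) 1e-6
                                    else config$svmTolerance)
    w <- as.numeric(t(model$coefs) %*% model$SV)
    b <- -model$rho
    # libsvm orients decision values toward its internally-first class;
    # flip so a positive score always means class 1
    positiveClass <- model$levels[model$labels[1]]
    if (positiveClass == "0") { w <- -w; b <- -b }
    list(w = w, b = b)
  } else if (kind == "sgd") {
    set.seed(seed)
    n <- nrow(xs); p <- ncol(xs)
    yy <- ifelse(y == 1, 1, -1)
    cw <- classWeights(y)
    sw <- ifelse(y == 1, cw["1"], cw["0"])
    w <- numeric(p); b <- 0
    t <- 0
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch)
      for (s in starts) {
        t <- t + 1
        eta <- config$eta0 / t^0.25
        idx <- ord[s:min(s + config$batch - 1, n)]
        xb <- xs[idx, , drop = FALSE]
        margin <- yy[idx] * (as.numeric(xb %*% w) + b)
        act <- margin < 1
        w <- w * (1 - eta * config$alpha)
        if (any(act)) {
          g <- colSums(xb[act, , drop = FALSE] *
                         (yy[idx][act] * sw[idx][act])) / length(idx)
          w <- w + eta * g
          b <- b + eta * sum(yy[idx][act] * sw[idx][act]) / length(idx)
        }
      }
    }
    list(w = w, b = b)
  } else stop("unknown estimator kind: ", kind)
}

#' Train a linear cellularity classifier
#'
#' Trains either a soft-margin (hinge-loss) support vector machine via
#' libsvm or a linear model fitted by mini-batch stochastic gradient
#' descent on the hinge loss with an inverse-scaling learning rate.
#' Features are standardized using training statistics only; class
#' imbalance is handled by inverse-frequency class weights. Deterministic
#' under a fixed seed.
#'
#' @param fm training \linkS4class{PixelFeatureMatrix} with both classes
#'   present.
#' @param kind "svm" or "sgd".
#' @param config see \code{\link{classifierConfig}}.
#' @param seed integer seed (SGD shuffling).
#' @param features optional subset of feature names to train on.
#' @return A \linkS4class{TrainedClassifier}.
#' @export
trainClassifier <- function(fm, kind = c("svm", "sgd"),
                            config = classifierConfig(), seed = 1L,
                            features = NULL) {
  kind <- match.arg(kind)
  y <- featureInfo(fm)$label
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  x <- featureValues(fm)
  if (!is.null(features)) {
    missing <- setdiff(features, colnames(x))
    if (length(missing))
      stop("missing feature column(s): ", paste(missing, collapse = ", "))
    x <- x[, features, drop = FALSE]
  }
  std <- standardizeFit(x)
  xs <- standardizeApply(x, std)
  fit <- fitLinearCore(xs, y, kind, config, seed)
  new("TrainedClassifier", kind = kind, featureNames = colnames(x),
      weights = fit$w, intercept = fit$b,
      center = std$center, scale = std$scale, config = config)
}

#' Block-wise per-pixel prediction
#'
#' Iterates over the feature matrix in blocks of \code{blockSize} rows per
#' case and classifies every pixel of each block as high-cellularity (1)
#' or not (0); predictions stay aligned with the matrix rows so they can
#' be mapped back to voxel coordinates.
#'
#' @param model a \linkS4class{TrainedClassifier}.
#' @param fm a \linkS4class{PixelFeatureMatrix} containing the model's
#'   feature columns.
#' @return Integer vector of per-pixel predicted labels.
#' @export
predictBlocks <- function(model, fm) {
  x <- featureValues(fm)
  missing <- setdiff(model@featureNames, colnames(x))
  if (length(missing))
    stop("missing feature column(s): ", paste(missing, collapse = ", "))
  x <- x[, model@featureNames, drop = FALSE]
  info <- featureInfo(fm)
  pred <- integer(nrow(x))
  grp <- paste(info$case, info$block)
  for (g in unique(grp)) {
    rows <- which(grp == g)
    xs <- standardizeApply(x[rows, , drop = FALSE],
                           list(center = model@center, scale = model@scale))
    score <- as.numeric(xs %*% model@weights) + model@intercept
    pred[rows] <- as.integer(score > 0)
  }
  pred
}

# Group-aware fold assignment: groups (cases) are shuffled deterministically
# and dealt round-robin, so pixels of one case never straddle folds. Falls
# back to row-level folds when there is a single group.
assignFolds <- function(groups, nFolds, seed) {
  u <- unique(groups)
  if (length(u) == 1) {
    set.seed(seed)
    return(sample(rep_len(seq_len(nFolds), length(groups))))
  }
  if (length(u) < nFolds) {
    warning(sprintf("only %d case(s): using %d fold(s) instead of %d",
                    length(u), length(u), nFolds))
    nFolds <- length(u)
  }
  set.seed(seed)
  u <- sample(u)
  foldOfGroup <- stats::setNames(rep_len(seq_len(nFolds), length(u)), u)
  as.integer(foldOfGroup[as.character(groups)])
}

#' Grouped k-fold cross-validation
#'
#' Splits the data into folds stratified at case level (pixels of one
#' patient never straddle train and validation), trains the chosen
#' estimator on the remaining folds and scores the held-out fold. With
#' fewer cases than folds, the largest feasible fold count is used with a
#' warning.
#'
#' @param fm a \linkS4class{PixelFeatureMatrix}.
#' @param kind "svm" or "sgd".
#' @param nFolds number of folds (default 10).
#' @param config see \code{\link{classifierConfig}}.
#' @param seed integer seed.
#' @return data.frame with one row per fold: fold, n, accuracy,
#'   balanced_accuracy.
#' @export
crossValidateFolds <- function(fm, kind = "svm", nFolds = 10L,
                               config = classifierConfig(), seed = 1L) {
  info <- featureInfo(fm)
  folds <- assignFolds(info$case, nFolds, deriveSeed(seed, 17L))
  out <- lapply(sort(unique(folds)), function(f) {
    tr <- subsetRows(fm, folds != f)
    te <- subsetRows(fm, folds == f)
    model <- trainClassifier(tr, kind, config, seed = deriveSeed(seed, f))
    pred <- predictBlocks(model, te)
    m <- classificationMetrics(confusionCounts(pred, featureInfo(te)$label))
    data.frame(fold = f, n = nrow(featureValues(te)),
               accuracy = m[["accuracy"]],
               balanced_accuracy = m[["balanced_accuracy"]])
  })
  do.call(rbind, out)
}

# Row subset of a PixelFeatureMatrix (internal).
subsetRows <- function(fm, sel) {
  new("PixelFeatureMatrix", features = fm@features[sel, , drop = FALSE],
      info = fm@info[sel, , drop = FALSE], blockSize = fm@blockSize)
}
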