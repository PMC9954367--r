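# synthetic selection problem: nInf informative features with effect size d,
# nNoise pure-noise features, grouped into cases
plantedData <- function(n = 240, nInf = 5, nNoise = 50, d = 2, nGroups = 6,
                        seed = 1) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * (nInf + nNoise)), n)
  for (j in seq_len(nInf)) x[y == 1, j] <- x[y == 1, j] + d
  colnames(x) <- c(sprintf("inf%02d", seq_len(nInf)),
                   sprintf("noise%02d", seq_len(nNoise)))
  featureMatrix(x, y, case = rep(sprintf("g%d", seq_len(nGroups)),
                                 length.out = n))
}

test_that("RFE retains planted informative features", {
  fm <- plantedData(seed = 42)
  sel <- rfeCV(fm, estimator = "svm", nFolds = 3, seed = 7)
  expect_gte(sum(grepl("^inf", selectedFeatures(sel))), 4)
  expect_setequal(sel@ranking, featureNames(fm))  # full elimination order
  expect_gt(max(cvScores(sel)$score), 0.9)
})

test_that("RFE on pure noise scores near chance", {
  fm <- plantedData(nInf = 0, nNoise = 30, d = 0, seed = 9)
  sel <- rfeCV(fm, estimator = "svm", nFolds = 3, seed = 5)
  sc <- cvScores(sel)$score
  expect_true(all(abs(sc - 0.5) < 0.12))
})

test_that("step = 1 produces a full elimination permutation", {
  fm <- plantedData(n = 60, nInf = 1, nNoise = 2, seed = 3)
  sel <- rfeCV(fm, estimator = "svm", nFolds = 2, step = 1, seed = 1)
  expect_length(sel@ranking, 3)
  expect_setequal(sel@ranking, featureNames(fm))
  expect_error(rfeCV(featureMatrix(matrix(rnorm(20), 10), rep(1, 10)),
                     nFolds = 2), "class")
})

test_that("both classifier kinds fit a separable problem perfectly", {
  set.seed(4)
  x <- rbind(matrix(rnorm(100, 3), 50), matrix(rnorm(100, -3), 50))
  colnames(x) <- c("u", "v")
  fm <- featureMatrix(x, c(rep(1, 50), rep(0, 50)))
  for (kind in c("svm", "sgd")) {
    model <- trainClassifier(fm, kind, seed = 2)
    pred <- predictBlocks(model, fm)
    expect_equal(mean(pred == featureInfo(fm)$label), 1,
                 info = kind)
  }
})

test_that("training is deterministic and robust to duplication", {
  set.seed(4)
  x <- rbind(matrix(rnorm(80, 1.5), 40), matrix(rnorm(80, -1.5), 40))
  colnames(x) <- c("u", "v")
  y <- c(rep(1, 40), rep(0, 40))
  fm <- featureMatrix(x, y)
  m1 <- trainClassifier(fm, "sgd", seed = 11)
  m2 <- trainClassifier(fm, "sgd", seed = 11)
  expect_identical(m1@weights, m2@weights)
  # duplicating the training set leaves the SVM decision function intact
  fm2 <- featureMatrix(rbind(x, x), c(y, y))
  s1 <- trainClassifier(fm, "svm", seed = 1)
  s2 <- trainClassifier(fm2, "svm", seed = 1)
  d1 <- as.numeric(scale(x, s1@center, s1@scale) %*% s1@weights) +
    s1@intercept
  d2 <- as.numeric(scale(x, s2@center, s2@scale) %*% s2@weights) +
    s2@intercept
  expect_lt(max(abs(d1 - d2)), 1e-6)
  # and the SGD boundary classifies the duplicated set identically
  g2 <- trainClassifier(fm2, "sgd", seed = 11)
  expect_equal(predictBlocks(g2, fm), predictBlocks(m1, fm))
})

test_that("block-wise prediction preserves row bookkeeping", {
  set.seed(6)
  x <- matrix(rnorm(1000 * 3), 1000)
  colnames(x) <- c("a", "b", "c")
  fm <- featureMatrix(x, rep(0:1, 500))
  model <- new("TrainedClassifier", kind = "svm",
               featureNames = c("a", "b", "c"),
               weights = c(1, 0, 0), intercept = 0,
               center = c(a = 0, b = 0, c = 0),
               scale = c(a = 1, b = 1, c = 1), config = list())
  pred <- predictBlocks(model, fm)
  expect_length(pred, 1000)
  expect_equal(pred, as.integer(x[, "a"] > 0))
  expect_equal(max(featureInfo(fm)$block), 3)
  # a weight on one feature constant per block gives uniform block labels
  xc <- cbind(a = rep(c(-1, 1), each = 400)[1:800], b = rnorm(800))
  fmc <- featureMatrix(xc, rep(0:1, 400))
  model2 <- initialize(model, featureNames = c("a", "b"),
                       weights = c(1, 0), center = c(a = 0, b = 0),
                       scale = c(a = 1, b = 1))
  predc <- predictBlocks(model2, fmc)
  blocks <- featureInfo(fmc)$block
  expect_true(all(vapply(split(predc, blocks),
                         function(p) length(unique(p)) == 1, TRUE)))
  # missing feature columns are named in the error
  expect_error(predictBlocks(model, featureMatrix(x[, 1:2], rep(0:1, 500))),
               "c")
})

test_that("grouped cross-validation respects cases and falls back", {
  set.seed(8)
  n <- 200
  y <- rep(0:1, 100)
  x <- cbind(sig = ifelse(y == 1, 5, -5) + rnorm(n) * 0.1,
             jnk = rnorm(n))
  fm <- featureMatrix(x, y, case = rep(sprintf("c%02d", 1:10),
                                       each = 20))
  cv <- crossValidateFolds(fm, "svm", nFolds = 10, seed = 3)
  expect_equal(nrow(cv), 10)
  expect_true(all(cv$accuracy == 1))
  # fold sizes differ by at most one group (20 rows here)
  expect_lte(diff(range(cv$n)), 20)
  fmSmall <- featureMatrix(x, y, case = rep(sprintf("c%d", 1:4), each = 50))
  expect_warning(cv2 <- crossValidateFolds(fmSmall, "svm", nFolds = 10,
                                           seed = 3), "fold")
  expect_equal(nrow(cv2), 4)
})

test_that("null data cross-validates near chance", {
  set.seed(12)
  x <- matrix(rnorm(300 * 5), 300)
  fm <- featureMatrix(x, sample(rep(0:1, 150)),
                      case = rep(sprintf("c%02d", 1:10), each = 30))
  cv <- crossValidateFolds(fm, "svm", nFolds = 10, seed = 4)
  expect_lt(abs(mean(cv$balanced_accuracy) - 0.5), 0.1)
})

test_that("held-out rows cannot leak into selection or training", {
  fm <- plantedData(seed = 15)
  info <- featureInfo(fm)
  train <- heteromap:::subsetRows(fm, info$case != "g1")
  sel1 <- rfeCV(train, nFolds = 3, seed = 2)
  # corrupt the held-out case; the training-side result must not move
  x <- featureValues(fm)
  x[info$case == "g1", ] <- rnorm(sum(info$case == "g1") * ncol(x))
  fmNoisy <- featureMatrix(x, info$label, case = info$case)
  train2 <- heteromap:::subsetRows(fmNoisy,
                                   featureInfo(fmNoisy)$case != "g1")
  sel2 <- rfeCV(train2, nFolds = 3, seed = 2)
  expect_identical(selectedFeatures(sel1), selectedFeatures(sel2))
  expect_identical(cvScores(sel1), cvScores(sel2))
})
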