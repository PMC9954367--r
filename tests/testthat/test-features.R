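featureTestVolume <- function(npix = 1000L, nrow = 25L, ncol = 40L) {
  # one slice holding exactly npix masked pixels with mild texture
  set.seed(31)
  sl <- matrix(rnorm(nrow * ncol, 50, 5), nrow, ncol)
  m <- matrix(FALSE, nrow, ncol)
  m[seq_len(npix)] <- TRUE
  labs <- array(0L, c(nrow, ncol, 1))
  labs[, , 1][m] <- sample(c(1L, 2L), npix, replace = TRUE)
  list(roi = MRIVolume(array(sl, c(nrow, ncol, 1))),
       mask = new("TumorMask", mask = array(m, c(nrow, ncol, 1)),
                  spacing = c(1, 1, 1)),
       labels = new("CellularityLabelMap", labels = labs,
                    cutoff = 0.85e-3, band = NULL))
}

test_that("tumor pixels are chunked into blocks of 400", {
  d <- featureTestVolume(1000L)
  fm <- pixelFeatureMatrix(d$roi, d$mask, d$labels,
                           featureConfig(families = "firstorder",
                                         shape = FALSE))
  expect_equal(nrow(featureValues(fm)), 1000L)
  expect_equal(as.numeric(table(featureInfo(fm)$block)), c(400, 400, 200))
  expect_false(anyNA(featureValues(fm)))
})

test_that("feature extraction is deterministic and ordered", {
  d <- featureTestVolume(150L, 15L, 15L)
  cfg <- featureConfig()
  a <- pixelFeatureMatrix(d$roi, d$mask, d$labels, cfg)
  b <- pixelFeatureMatrix(d$roi, d$mask, d$labels, cfg)
  expect_identical(featureValues(a), featureValues(b))
  info <- featureInfo(a)
  ord <- order(info$slice, info$y, info$x)
  expect_identical(ord, seq_len(nrow(info)))
  # full feature complement: filters + first-order + 5 texture families
  # + shape
  expect_gte(ncol(featureValues(a)), 110)
  expect_false(any(!is.finite(featureValues(a))))
})

test_that("texture features separate subregions that differ in texture only", {
  # same mean T2 in both subregions; only variance/correlation length differ
  spec <- quickSpec(noiseSigma = 0.8, t2Low = 55, t2High = 55,
                    t2TextureAmpLow = 12, t2TextureAmpHigh = 2,
                    t2TextureScaleLow = 2, t2TextureScaleHigh = 8)
  case <- generatePhantom(spec)
  mask <- new("TumorMask", mask = case@truthMask,
              spacing = volSpacing(t2Volume(case)))
  labels <- new("CellularityLabelMap", labels = case@truthLabels,
                cutoff = 0.85e-3, band = NULL)
  roi <- extractRoi(t2Volume(case), mask)
  off <- roi$offset; dm <- dim(volData(roi$roi))
  croppedLabels <- new("CellularityLabelMap",
                       labels = labels@labels[off[1] + seq_len(dm[1]),
                                              off[2] + seq_len(dm[2]),
                                              off[3] + seq_len(dm[3]),
                                              drop = FALSE],
                       cutoff = 0.85e-3, band = NULL)
  fm <- pixelFeatureMatrix(roi$roi, roi$mask, croppedLabels,
                           featureConfig(shape = FALSE))
  y <- featureInfo(fm)$label
  x <- featureValues(fm)
  texCols <- grep("^(glcm|glrlm|glszm|gldm|ngtdm|fo)_", colnames(x))
  aucs <- apply(x[, texCols], 2, aucOf, y = y)
  expect_gt(max(pmax(aucs, 1 - aucs)), 0.8)
})

test_that("constant features are dropped idempotently", {
  x <- cbind(a = rnorm(20), b = rep(5, 20), c = c(rep(1, 19), 2))
  fm <- featureMatrix(x, labels = rep(c(0, 1), 10))
  red <- removeConstantFeatures(fm)
  expect_identical(featureNames(red), c("a", "c"))
  expect_identical(attr(red, "dropped"), "b")
  red2 <- removeConstantFeatures(red)
  expect_identical(featureNames(red2), featureNames(red))
  expect_length(attr(red2, "dropped"), 0)
  allconst <- featureMatrix(cbind(z = rep(1, 10)), labels = rep(0:1, 5))
  expect_error(removeConstantFeatures(allconst), "constant")
})

test_that("feature matrices of several cases combine consistently", {
  a <- featureMatrix(matrix(rnorm(40), 10, 4), rep(0:1, 5), case = "a")
  b <- featureMatrix(matrix(rnorm(40), 10, 4), rep(0:1, 5), case = "b")
  ab <- bindFeatureMatrices(list(a, b))
  expect_equal(nrow(featureValues(ab)), 20)
  expect_equal(unique(featureInfo(ab)$case), c("a", "b"))
})
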