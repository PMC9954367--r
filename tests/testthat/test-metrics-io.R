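test_that("confusion counts match hand enumeration", {
  cc <- confusionCounts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(cc, c(TP = 2, FP = 0, TN = 2, FN = 0))
  flip <- confusionCounts(c(0, 0, 1, 1), c(1, 1, 0, 0))
  expect_equal(flip[["TP"]] + flip[["TN"]], 0)
  cc2 <- confusionCounts(c(1, 1, 1, 0, 0, 1, 0, 1),
                         c(1, 0, 1, 1, 0, 1, 0, 0))
  expect_equal(cc2, c(TP = 3, FP = 2, TN = 2, FN = 1))
  expect_error(confusionCounts(c(1, 0), c(1, 0, 1)), "mismatch")
  expect_error(confusionCounts(c(2, 0), c(1, 0)), "binary")
})

test_that("metrics follow their closed forms", {
  m <- classificationMetrics(c(TP = 3, FP = 2, TN = 2, FN = 1))
  expect_equal(m[["accuracy"]], 0.625)
  expect_equal(m[["sensitivity"]], 0.75)
  expect_equal(m[["specificity"]], 0.5)
  expect_equal(m[["balanced_accuracy"]], 0.625)
  perfect <- classificationMetrics(c(TP = 5, FP = 0, TN = 7, FN = 0))
  expect_equal(unname(perfect), rep(1, 4))
  # all-positive prediction on mixed truth
  allpos <- classificationMetrics(c(TP = 4, FP = 6, TN = 0, FN = 0))
  expect_equal(allpos[["sensitivity"]], 1)
  expect_equal(allpos[["specificity"]], 0)
  expect_equal(allpos[["balanced_accuracy"]], 0.5)
  # zero denominators yield missing values, never NaN
  onesided <- classificationMetrics(c(TP = 4, FP = 0, TN = 0, FN = 1))
  expect_true(is.na(onesided[["specificity"]]))
  expect_false(any(is.nan(onesided)))
  expect_error(classificationMetrics(c(TP = 0, FP = 0, TN = 0, FN = 0)),
               "no evaluated")
})

test_that("accuracy equals the prevalence-weighted recall identity", {
  set.seed(21)
  for (r in 1:25) {
    cc <- c(TP = rpois(1, 20), FP = rpois(1, 10),
            TN = rpois(1, 30), FN = rpois(1, 8)) + 1
    m <- classificationMetrics(cc)
    prev <- (cc[["TP"]] + cc[["FN"]]) / sum(cc)
    expect_equal(m[["accuracy"]],
                 prev * m[["sensitivity"]] +
                   (1 - prev) * m[["specificity"]],
                 tolerance = 1e-12)
    expect_equal(unname(classificationMetrics(
      confusionCounts(rep(c(1, 0), cc[c("TP", "TN")]),
                      rep(c(1, 0), cc[c("TP", "TN")])))), rep(1, 4))
  }
})

test_that("study I/O round-trips volumes and metadata losslessly", {
  dir <- file.path(tempdir(), "study-roundtrip")
  spec <- quickSpec(translation = c(4, 0, 0))
  case <- applyMisalignment(generatePhantom(spec), spec)
  writeStudy(case, dir)
  back <- readStudy(dir)
  expect_equal(caseId(back), caseId(case))
  expect_equal(volData(t2Volume(back)), volData(t2Volume(case)),
               tolerance = 1e-7)
  expect_equal(volData(adcVolume(back)), volData(adcVolume(case)),
               tolerance = 1e-7)
  expect_equal(sort(bValues(back)), sort(bValues(case)))
  expect_equal(isAligned(back), FALSE)
  expect_equal(sum(back@truthMask), sum(case@truthMask))
  unlink(dir, recursive = TRUE)
})

test_that("a study without an ADC map falls back to fitting one", {
  dir <- file.path(tempdir(), "study-noadc")
  case <- generatePhantom(quickSpec(noiseSigma = 0))
  writeStudy(case, dir)
  file.remove(file.path(dir, "adc.nii.gz"))
  expect_message(back <- readStudy(dir), "fitting")
  expect_lt(max(abs(volData(adcVolume(back)) - volData(adcVolume(case)))),
            1e-6)
  unlink(dir, recursive = TRUE)
})

test_that("grid mismatches are reported with both shapes", {
  dir <- file.path(tempdir(), "study-mismatch")
  case <- generatePhantom(quickSpec())
  writeStudy(case, dir)
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 2))),
                     file.path(dir, "dwi_b600.nii.gz"))
  expect_error(readStudy(dir), "4x4x2")
  unlink(dir, recursive = TRUE)
})

test_that("overlay export writes per-slice panels and a color table", {
  dir <- file.path(tempdir(), "overlay")
  case <- generatePhantom(quickSpec())
  mask <- new("TumorMask", mask = case@truthMask,
              spacing = volSpacing(t2Volume(case)))
  lab <- labelCellularity(adcVolume(case), mask,
                          uncertainBand = c(0.85e-3, 1.1e-3))
  files <- exportOverlay(t2Volume(case), lab, pred = labelArray(lab),
                         dir = dir)
  pngs <- list.files(dir, pattern = "slice_.*png")
  expect_equal(length(pngs), dim(volData(t2Volume(case)))[3])
  expect_true(file.exists(file.path(dir, "colors.json")))
  # perfect predictor: the two panels are pixel-identical
  img <- png::readPNG(file.path(dir, pngs[4]))
  half <- dim(img)[1] / 2
  expect_identical(img[seq_len(half), , ], img[half + seq_len(half), , ])
  # all-background map warns and writes grayscale slices
  empty <- new("CellularityLabelMap",
               labels = array(0L, dim(volData(t2Volume(case)))),
               cutoff = 0.85e-3, band = NULL)
  expect_warning(exportOverlay(t2Volume(case), empty,
                               dir = file.path(dir, "bg")),
                 "background")
  unlink(dir, recursive = TRUE)
})
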