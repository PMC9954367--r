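test_that("k-means splits well-separated intensities at the optimum", {
  vol <- MRIVolume(array(c(0, 0, 0, 10, 10), c(5, 1, 1)))
  mask <- segmentTumorKmeans(vol, k = 2, seed = 1)
  expect_identical(as.logical(maskArray(mask)),
                   c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # well-separated clusters: any seed finds the same global optimum
  mask2 <- segmentTumorKmeans(vol, k = 2, seed = 999)
  expect_identical(maskArray(mask), maskArray(mask2))
  expect_error(segmentTumorKmeans(MRIVolume(array(5, c(4, 4, 2)))),
               "constant")
})

test_that("tumor segmentation reaches Dice >= 0.99 on a clean phantom", {
  case <- generatePhantom(quickSpec())
  mask <- segmentTumorKmeans(dwiVolume(case, 1200))
  expect_gte(diceCoef(maskArray(mask), case@truthMask), 0.99)
})

test_that("segmentation keeps only the largest connected component", {
  vol <- array(1, c(10, 10, 3))
  vol[2:6, 2:6, 1:3] <- 50      # big blob
  vol[9, 9, 1] <- 50            # isolated bright voxel
  mask <- segmentTumorKmeans(MRIVolume(vol), k = 2, seed = 1)
  expect_false(maskArray(mask)[9, 9, 1])
  expect_true(all(maskArray(mask)[2:6, 2:6, 1:3]))
})

test_that("ADC labeling follows the cut-off and partitions the mask", {
  adc <- array(1.6e-3, c(6, 6, 2))
  adc[2, 2, 1] <- 0.5e-3    # highly cellular
  adc[3, 3, 1] <- 1.2e-3    # low cellularity
  adc[4, 4, 1] <- 0.9e-3    # uncertain band
  m <- array(FALSE, dim(adc)); m[2:4, 2:4, 1] <- TRUE
  mask <- new("TumorMask", mask = m, spacing = c(1, 1, 1))
  lab <- labelCellularity(MRIVolume(adc), mask,
                          uncertainBand = c(0.85e-3, 1.0e-3))
  expect_equal(labelArray(lab)[2, 2, 1], 1L)
  expect_equal(labelArray(lab)[3, 3, 1], 2L)
  expect_equal(labelArray(lab)[4, 4, 1], 3L)
  expect_equal(labelArray(lab)[1, 1, 1], 0L)  # outside mask: background
  # partition property: labels exhaust the mask
  expect_equal(sum(labelArray(lab) > 0), sum(m))
  # negative ADC inside the mask is invalid
  bad <- adc; bad[2, 3, 1] <- -1e-4
  expect_error(labelCellularity(MRIVolume(bad), mask), "negative")
})

test_that("raising the cut-off never shrinks the high-cellularity set", {
  case <- generatePhantom(quickSpec())
  mask <- new("TumorMask", mask = case@truthMask,
              spacing = volSpacing(t2Volume(case)))
  cuts <- c(0.5e-3, 0.85e-3, 1.2e-3, 2e-3)
  sizes <- vapply(cuts, function(ct)
    sum(labelArray(labelCellularity(adcVolume(case), mask, ct)) == 1L), 0)
  expect_true(all(diff(sizes) >= 0))
})

test_that("ROI extraction crops tightly and preserves coordinates", {
  t2 <- MRIVolume(array(as.numeric(seq_len(8 * 9 * 5)), c(8, 9, 5)))
  m <- array(FALSE, c(8, 9, 5))
  m[3:6, 4:8, 2:5] <- TRUE
  mask <- new("TumorMask", mask = m, spacing = c(1, 1, 1))
  roi <- extractRoi(t2, mask)
  expect_equal(dim(volData(roi$roi)), c(4, 5, 4))
  expect_equal(roi$offset, c(2L, 3L, 1L))   # 0-based, half-open convention
  # round trip: cropped voxel (i,j,k) maps back to offset + (i,j,k)
  expect_equal(volData(roi$roi)[2, 3, 1],
               volData(t2)[roi$offset[1] + 2, roi$offset[2] + 3,
                           roi$offset[3] + 1])
  # full-volume mask gives back the input
  full <- new("TumorMask", mask = array(TRUE, c(8, 9, 5)),
              spacing = c(1, 1, 1))
  expect_identical(volData(extractRoi(t2, full)$roi), volData(t2))
  empty <- new("TumorMask", mask = array(FALSE, c(8, 9, 5)),
               spacing = c(1, 1, 1))
  expect_error(extractRoi(t2, empty), "empty")
})

test_that("computeAdc inverts the decay model and handles degeneracies", {
  sh <- c(3, 3, 1)
  dwi <- list("0" = MRIVolume(array(100, sh)),
              "1200" = MRIVolume(array(100 * exp(-1200 * 0.85e-3), sh)))
  fit <- computeAdc(dwi)
  expect_equal(volData(fit)[1, 1, 1], 0.85e-3, tolerance = 1e-9)
  # constant signal over b has zero slope
  flat <- list("0" = MRIVolume(array(50, sh)),
               "1200" = MRIVolume(array(50, sh)))
  expect_equal(max(abs(volData(computeAdc(flat)))), 0)
  # non-positive signals are flagged invalid
  neg <- dwi
  d <- volData(neg[["1200"]]); d[2, 2, 1] <- -1
  neg[["1200"]] <- MRIVolume(d)
  out <- computeAdc(neg)
  expect_false(attr(volData(out), "validMask")[2, 2, 1])
  expect_equal(volData(out)[2, 2, 1], 0)
  expect_error(computeAdc(dwi["1200"]), "b = 0")
})
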