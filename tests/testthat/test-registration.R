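test_that("rmsDifference matches hand arithmetic and is a metric", {
  a <- MRIVolume(array(c(0, 0), c(2, 1, 1)))
  b <- MRIVolume(array(c(3, 4), c(2, 1, 1)))
  expect_equal(rmsDifference(a, a), 0)
  expect_equal(rmsDifference(a, b), sqrt((9 + 16) / 2))
  off <- MRIVolume(volData(a) + 3)
  expect_equal(rmsDifference(a, off), 3)
  expect_equal(rmsDifference(a, b), rmsDifference(b, a))
  expect_error(rmsDifference(a, b, mask = array(FALSE, c(2, 1, 1))),
               "empty")
  expect_error(rmsDifference(a, MRIVolume(array(0, c(3, 1, 1)))), "grid")
})

test_that("mutual information attains the marginal entropy on identity", {
  set.seed(3)
  f <- MRIVolume(array(rnorm(8 * 8 * 4, 50, 10), c(8, 8, 4)))
  mi <- mattesMutualInformation(f, f, nBins = 8L, nSamples = 20000L)
  # marginal entropy of the same samples under the same binning
  v <- heteromap:::cpp_sample3(volData(f), c(8L, 8L, 4L),
                               heteromap:::samplePoints(c(8, 8, 4),
                                                        20000, 7L))
  bin <- pmin(pmax(floor((v - min(volData(f))) /
                           diff(range(volData(f))) * 8) + 1, 1), 8)
  p <- tabulate(bin, 8) / length(bin)
  expect_equal(mi, -sum(p[p > 0] * log(p[p > 0])), tolerance = 1e-12)
})

test_that("mutual information is invariant to intensity inversion", {
  # 8x8 toy with exactly equal bin occupancy; inversion permutes the bins
  set.seed(4)
  vals <- sample(rep(1:8, each = 8))
  f <- MRIVolume(array(rep(vals, 2), c(8, 8, 2)))
  inv <- MRIVolume(9 - volData(f))
  miSame <- mattesMutualInformation(f, f, nBins = 8L, nSamples = 5000L)
  miInv <- mattesMutualInformation(f, inv, nBins = 8L, nSamples = 5000L)
  expect_equal(miSame, miInv, tolerance = 1e-12)
})

test_that("mutual information of independent noise is near zero", {
  set.seed(3)
  f <- MRIVolume(array(rnorm(8 * 8 * 4, 50, 10), c(8, 8, 4)))
  miSelf <- mattesMutualInformation(f, f, nBins = 8L, nSamples = 20000L)
  # bound frozen from a Monte-Carlo run over 20 independent-noise pairs
  # (mean 0.013, max 0.027 nats): mean + 3 empirical sd
  noise <- MRIVolume(array(rnorm(8 * 8 * 4), c(8, 8, 4)))
  miNoise <- mattesMutualInformation(f, noise, nBins = 8L,
                                     nSamples = 20000L)
  expect_lt(miNoise, 0.05)
  expect_gt(miSelf, 10 * miNoise)
})

test_that("affine registration recovers identity and pure translation", {
  spec <- quickSpec(noiseSigma = 0.5)
  c0 <- generatePhantom(spec)
  f <- t2Volume(c0)
  # loose bounds here: a reduced sampling budget keeps this check quick
  cfg <- affineConfig(dof = "rigid", sampleFrac = 0.4, maxit = 500L)
  affId <- registerAffine(f, f, cfg)
  expect_lt(sqrt(sum(affId@translation^2)), 0.5)
  expect_lt(rotationErrorDeg(affId@matrix, diag(3)), 0.5)

  spec2 <- quickSpec(noiseSigma = 0.5, translation = c(5, 0, 0),
                     rotation = c(0, 0, 0), warpAmplitude = 0)
  c1 <- applyMisalignment(generatePhantom(spec2), spec2)
  aff <- registerAffine(t2Volume(c1), dwiVolume(c1, 1200), cfg)
  # in our convention the recovered sampling-map translation equals the
  # content shift
  expect_lt(max(abs(aff@translation - c(5, 0, 0))), 1)
})

test_that("a constant moving image flags a degenerate metric", {
  f <- MRIVolume(array(rnorm(4^3), c(4, 4, 4)))
  flat <- MRIVolume(array(1, c(4, 4, 4)))
  expect_warning(aff <- registerAffine(f, flat), "constant")
  expect_false(aff@converged)
})

test_that("demons yields a zero field on identical images", {
  spec <- quickSpec(noiseSigma = 0.5)
  f <- dwiVolume(generatePhantom(spec), 1200)
  dem <- registerDemons(f, f)
  expect_lt(max(abs(dem@field)), 1e-6)
})

test_that("demons recovers a smooth bump warp on a textured pair", {
  set.seed(5)
  shape <- c(40L, 40L, 16L); sp <- c(2, 2, 2)
  f <- 50 + 20 * heteromap:::smoothNoiseField(shape, sp, 8)
  cs <- lapply(1:3, function(a) (seq_len(shape[a]) - 1) * sp[a])
  r2 <- outer(outer((cs[[1]] - 40)^2, (cs[[2]] - 40)^2, `+`),
              (cs[[3]] - 16)^2, `+`)
  disp <- array(0, c(shape, 3))
  disp[, , , 1] <- 4 * exp(-r2 / (2 * 12^2)) / sp[1]  # 2-voxel peak
  m <- heteromap:::resampleDisplacement(f, disp)
  pre <- rmsDifference(f, m)
  dem <- registerDemons(MRIVolume(f, sp), MRIVolume(m, sp),
                        demonsConfig(maxit = 200L, sigmaField = 3,
                                     tol = 1e-7))
  post <- tail(dem@trace$rms, 1)
  expect_lte(post / pre, 0.2)
  # the accepted-step trace never increases
  expect_true(all(diff(dem@trace$rms) <= 0))
  expect_lte(post, pre)
})

test_that("demons warns and returns a zero field without gradients", {
  flat <- MRIVolume(array(2, c(4, 4, 4)))
  other <- MRIVolume(array(3, c(4, 4, 4)))
  expect_warning(dem <- registerDemons(flat, other), "gradient")
  expect_equal(max(abs(dem@field)), 0)
})

test_that("study alignment restores the ADC tumor position", {
  spec <- quickSpec(translation = c(5, -4, 0), rotation = c(0, 0, 4),
                    warpAmplitude = 1.5)
  c1 <- applyMisalignment(generatePhantom(spec), spec)
  al <- alignStudy(c1)
  expect_true(isAligned(al))
  expect_true(all(c("rmsBefore", "rmsAfter") %in%
                    names(al@meta$alignment)))
  # tumor centroid of the aligned ADC map within one voxel of ground truth
  sp <- volSpacing(t2Volume(al))
  tumorish <- volData(adcVolume(al)) < 1.3e-3 & volData(adcVolume(al)) > 0
  truth <- c1@truthMask
  cenA <- heteromap:::intensityCentroid(array(as.numeric(tumorish),
                                              dim(truth)), sp)
  cenT <- heteromap:::intensityCentroid(array(as.numeric(truth),
                                              dim(truth)), sp)
  expect_lt(max(abs(cenA - cenT) / sp), 1)
})

test_that("aligning an already-aligned study changes almost nothing", {
  spec <- quickSpec(seed = 12L)
  c0 <- generatePhantom(spec)
  al <- alignStudy(c0)
  rep <- al@meta$alignment
  # resampling smooths noise slightly, so the matched RMS may drop; it must
  # never get materially worse
  expect_lte(rep$rmsAfter, rep$rmsBefore * 1.01)
  aff <- rep$affine
  expect_lt(sqrt(sum(aff@translation^2)), 1)
  expect_lt(rotationErrorDeg(aff@matrix, diag(3)), 1)
})
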