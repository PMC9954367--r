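#' Create a synthetic phantom specification
#'
#' Returns a \linkS4class{PhantomSpec} describing a pelvic-MRI-like study:
#' an ellipsoidal tumor embedded in homogeneous background, split into a
#' low-ADC (highly cellular) and a high-ADC subregion by a smooth random
#' field, imaged as a multi-b DWI series under the monoexponential model
#' \code{S(b) = S0 exp(-b ADC)}, an ADC map, and a T2-weighted volume whose
#' mean intensity and texture differ between the subregions. Defaults mimic
#' a small pelvic field of view at 3T resolution with tumor/background
#' contrast-to-noise well above 5.
#'
#' @param shape grid size in voxels.
#' @param spacing voxel spacing in mm.
#' @param center,radii tumor ellipsoid centre and radii in mm.
#' @param adcBackground,adcLow,adcHigh ADC values (mm^2/s) of background and
#'   of the low-/high-ADC subregions; the low value sits below and the high
#'   value above the 0.85e-3 mm^2/s cellularity cut-off.
#' @param lowFraction fraction of tumor volume given to the low-ADC
#'   subregion.
#' @param subregionScale correlation length (mm) of the field shaping the
#'   subregions.
#' @param bValues acquired diffusion weightings (s/mm^2).
#' @param s0Background,s0Tumor baseline signal amplitudes.
#' @param t2Background,t2Low,t2High mean T2 intensities.
#' @param t2TextureAmpLow,t2TextureAmpHigh,t2TextureScaleLow,
#'   t2TextureScaleHigh amplitude and correlation length of the
#'   within-region T2 texture.
#' @param noiseSigma additive Gaussian noise sd.
#' @param translation,rotation,warpAmplitude,warpScale misalignment applied
#'   to the DWI/ADC frame by \code{\link{applyMisalignment}}: translation
#'   (mm), rotation (degrees about x, y, z), and a Gaussian-smoothed random
#'   elastic warp (amplitude mm, smoothness mm).
#' @param seed integer seed fixing all sampled quantities.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(shape = c(48L, 48L, 12L), spacing = c(2, 2, 4),
                        center = NULL, radii = c(24, 15, 12),
                        adcBackground = 1.6e-3, adcLow = 0.65e-3,
                        adcHigh = 1.05e-3, lowFraction = 0.45,
                        subregionScale = 10,
                        bValues = c(0, 600, 1200),
                        s0Background = 40, s0Tumor = 100,
                        t2Background = 25, t2Low = 45, t2High = 70,
                        t2TextureAmpLow = 7, t2TextureAmpHigh = 3,
                        t2TextureScaleLow = 3, t2TextureScaleHigh = 6,
                        anatomyScale = 10, anatomyAmpT2 = 8,
                        anatomyAmpS0 = 0.3,
                        noiseSigma = 1.5,
                        translation = c(5, -4, 0), rotation = c(0, 0, 4),
                        warpAmplitude = 2, warpScale = 12,
                        seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(center)) center <- (shape - 1) * spacing / 2
  new("PhantomSpec", shape = shape, spacing = as.numeric(spacing),
      center = as.numeric(center), radii = as.numeric(radii),
      adcBackground = adcBackground, adcLow = adcLow, adcHigh = adcHigh,
      lowFraction = lowFraction, subregionScale = subregionScale,
      bValues = as.numeric(bValues),
      s0Background = s0Background, s0Tumor = s0Tumor,
      t2Background = t2Background, t2Low = t2Low, t2High = t2High,
      t2TextureAmpLow = t2TextureAmpLow, t2TextureAmpHigh = t2TextureAmpHigh,
      t2TextureScaleLow = t2TextureScaleLow,
      t2TextureScaleHigh = t2TextureScaleHigh,
      anatomyScale = anatomyScale, anatomyAmpT2 = anatomyAmpT2,
      anatomyAmpS0 = anatomyAmpS0,
      noiseSigma = noiseSigma,
      translation = as.numeric(translation), rotation = as.numeric(rotation),
      warpAmplitude = warpAmplitude, warpScale = warpScale,
      seed = as.integer(seed))
}

ellipsoidMask <- function(shape, spacing, center, radii) {
  cs <- axisCoords(shape, spacing)
  dx <- (cs[[1]] - center[1]) / radii[1]
  dy <- (cs[[2]] - center[2]) / radii[2]
  dz <- (cs[[3]] - center[3]) / radii[3]
  outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= 1
}

#' Generate a synthetic MRI study case
#'
#' Builds the aligned (ground-truth frame) study: noiseless ADC field, DWI
#' series following \code{S(b) = S0 exp(-b ADC) + noise}, and a T2 volume
#' with distinct subregion means and textures. Ground-truth tumor mask and
#' cellularity labels (1 = high cellularity / low ADC) are attached.
#' Bit-identical under a fixed seed.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param caseId case identifier string.
#' @return A \linkS4class{StudyCase} flagged aligned.
#' @export
generatePhantom <- function(spec, caseId = "phantom") {
  validObject(spec)
  shape <- spec@shape; spacing <- spec@spacing
  fov <- (shape - 1) * spacing
  if (any(spec@center - spec@radii < 0) || any(spec@center + spec@radii > fov))
    stop("tumor ellipsoid extends outside the grid")
  fields <- phantomFields(spec)
  grid <- gridCoordsMM(shape, spacing)
  vals <- evalPhantomAt(spec, fields, grid)

  dwi <- dwiFromFields(spec, vals, shape, spacing)
  adcVol <- MRIVolume(array(vals$adc, dim = shape), spacing)

  tumor <- array(vals$tumor, dim = shape)
  low <- array(vals$low, dim = shape)
  high <- tumor & !low

  # T2 stays in the reference frame: build it on the grid directly
  set.seed(deriveSeed(spec@seed, 300L))
  t2 <- array(spec@t2Background, dim = shape)
  t2[!tumor] <- t2[!tumor] + spec@anatomyAmpT2 * fields$anatomy[!tumor]
  t2[low] <- spec@t2Low
  t2[high] <- spec@t2High
  texLow <- smoothNoiseField(shape, spacing, spec@t2TextureScaleLow)
  texHigh <- smoothNoiseField(shape, spacing, spec@t2TextureScaleHigh)
  t2[low] <- t2[low] + spec@t2TextureAmpLow * texLow[low]
  t2[high] <- t2[high] + spec@t2TextureAmpHigh * texHigh[high]
  if (spec@noiseSigma > 0)
    t2 <- t2 + array(stats::rnorm(prod(shape), sd = spec@noiseSigma),
                     dim = shape)

  labels <- array(0L, dim = shape)
  labels[low] <- 1L   # low ADC -> high cellularity
  labels[high] <- 2L

  new("StudyCase", caseId = caseId, t2 = MRIVolume(t2, spacing), dwi = dwi,
      adc = adcVol, aligned = TRUE,
      truthMask = tumor, truthLabels = labels,
      trueTransform = list(), meta = list(spec = spec))
}

# Grid-based random fields of the phantom (seeded once per spec): the
# subregion-layout field with its low/high threshold, and the shared
# background anatomy field.
phantomFields <- function(spec) {
  shape <- spec@shape; spacing <- spec@spacing
  set.seed(spec@seed)
  f <- smoothNoiseField(shape, spacing, spec@subregionScale)
  anatomy <- smoothNoiseField(shape, spacing, spec@anatomyScale)
  tumor <- ellipsoidMask(shape, spacing, spec@center, spec@radii)
  thr <- stats::quantile(f[tumor], 1 - spec@lowFraction, names = FALSE)
  list(f = f, anatomy = anatomy, thr = thr)
}

gridCoordsMM <- function(shape, spacing) {
  cs <- axisCoords(shape, spacing)
  rbind(rep(cs[[1]], times = shape[2] * shape[3]),
        rep(rep(cs[[2]], each = shape[1]), times = shape[3]),
        rep(cs[[3]], each = shape[1] * shape[2]))
}

# Evaluate the continuous phantom (ADC and baseline-signal fields) at
# arbitrary physical coordinates (3 x n, mm). Geometry is analytic; the
# smooth random fields are interpolated from their grid representation.
# Points outside the grid take background values.
evalPhantomAt <- function(spec, fields, coordsMM) {
  shape <- spec@shape; spacing <- spec@spacing
  s <- ((coordsMM[1, ] - spec@center[1]) / spec@radii[1])^2 +
    ((coordsMM[2, ] - spec@center[2]) / spec@radii[2])^2 +
    ((coordsMM[3, ] - spec@center[3]) / spec@radii[3])^2
  tumor <- s <= 1
  idx <- coordsMM / spacing
  fv <- cpp_sample3(fields$f, as.integer(shape), idx)
  av <- cpp_sample3(fields$anatomy, as.integer(shape), idx)
  fv[is.na(fv)] <- fields$thr - 1  # outside: treat as high-ADC side
  av[is.na(av)] <- 0
  low <- tumor & (fv >= fields$thr)
  adc <- rep(spec@adcBackground, length(s))
  adc[tumor & !low] <- spec@adcHigh
  adc[low] <- spec@adcLow
  s0 <- spec@s0Background * pmax(0.1, 1 + spec@anatomyAmpS0 * av)
  s0[tumor] <- spec@s0Tumor
  list(adc = adc, s0 = s0, tumor = tumor, low = low)
}

# Assemble the DWI series from evaluated fields; acquisition noise uses one
# derived seed per b-value so an identity misalignment reproduces the
# aligned volumes exactly.
dwiFromFields <- function(spec, vals, shape, spacing) {
  dwi <- list()
  for (i in seq_along(spec@bValues)) {
    b <- spec@bValues[i]
    sig <- vals$s0 * exp(-b * vals$adc)
    if (spec@noiseSigma > 0) {
      set.seed(deriveSeed(spec@seed, 200L + i))
      sig <- sig + stats::rnorm(length(sig), sd = spec@noiseSigma)
    }
    dwi[[as.character(b)]] <- MRIVolume(array(sig, dim = shape), spacing)
  }
  dwi
}

#' Misalign the DWI/ADC frame of a phantom
#'
#' Re-images the phantom in a displaced frame: every DWI volume and the ADC
#' map are regenerated at coordinates moved through one shared rigid
#' transform composed with a Gaussian-smoothed random elastic warp, with
#' fresh acquisition noise from the same per-volume seeds -- the physical
#' model of a patient who moved between the T2 and DWI acquisitions. The T2
#' volume is untouched and the true transform is recorded for registration
#' tests. Content of the moved volumes shifts by \code{+translation}: a
#' tumor at x appears at x + t. With zero translation, rotation and warp
#' the output equals the input exactly.
#'
#' @param case an aligned \linkS4class{StudyCase} carrying its PhantomSpec.
#' @param spec the \linkS4class{PhantomSpec} holding misalignment parameters.
#' @return The misaligned \linkS4class{StudyCase}, flagged raw.
#' @export
applyMisalignment <- function(case, spec) {
  if (!case@aligned) stop("case must be aligned before misalignment")
  shape <- dim(case@t2@data); spacing <- case@t2@spacing
  R <- rotationMatrix3(spec@rotation * pi / 180)
  center <- (shape - 1) * spacing / 2
  # content moves by +t under sampling map y(x) = R^-1 (x - c - t) + c + u
  A <- solve(R)
  trans <- as.numeric(-A %*% spec@translation)
  disp <- NULL
  if (spec@warpAmplitude > 0) {
    set.seed(deriveSeed(spec@seed, 101L))
    disp <- vapply(1:3, function(a)
      spec@warpAmplitude * smoothNoiseField(shape, spacing, spec@warpScale),
      array(0, dim = shape))
    disp <- array(disp, dim = c(shape, 3))
  }
  grid <- gridCoordsMM(shape, spacing)
  y <- A %*% (grid - center) + center + trans
  if (!is.null(disp)) y <- y + rbind(as.numeric(disp[, , , 1]),
                                     as.numeric(disp[, , , 2]),
                                     as.numeric(disp[, , , 3]))
  fields <- phantomFields(spec)
  vals <- evalPhantomAt(spec, fields, y)
  if (sum(vals$tumor) < 0.5 * sum(case@truthMask))
    stop("misalignment pushes the tumor outside the grid")
  dwi <- dwiFromFields(spec, vals, shape, spacing)
  adc <- MRIVolume(array(vals$adc, dim = shape), spacing)
  initialize(case, dwi = dwi, adc = adc, aligned = FALSE,
             trueTransform = list(rotation = spec@rotation,
                                  translation = spec@translation,
                                  center = center, A = A,
                                  affineTranslation = trans,
                                  elastic = disp))
}

#' Generate a cohort of synthetic study cases
#'
#' Samples per-case jitter of the tumor geometry, subregion layout, ADC and
#' T2 contrast, and misalignment, deterministically from one seed; stands in
#' for a multi-patient study.
#'
#' @param nCases number of cases (at least 2, for leave-one-patient-out).
#' @param baseSpec template \linkS4class{PhantomSpec}.
#' @param seed integer master seed.
#' @param misalign logical, apply the per-case misalignment (default TRUE).
#' @return List of \linkS4class{StudyCase} objects.
#' @export
generateCohort <- function(nCases, baseSpec = phantomSpec(), seed = 1L,
                           misalign = TRUE) {
  if (nCases < 2) stop("nCases must be >= 2 (leave-one-patient-out needs 2)")
  lapply(seq_len(nCases), function(i) {
    set.seed(deriveSeed(seed, i))
    jit <- function(x, lo, hi) x * stats::runif(length(x), lo, hi)
    spec <- initialize(baseSpec,
      center = baseSpec@center + stats::runif(3, -4, 4),
      radii = jit(baseSpec@radii, 0.85, 1.15),
      lowFraction = stats::runif(1, 0.35, 0.55),
      adcLow = baseSpec@adcLow * stats::runif(1, 0.9, 1.1),
      adcHigh = baseSpec@adcHigh * stats::runif(1, 0.95, 1.15),
      t2Low = baseSpec@t2Low * stats::runif(1, 0.9, 1.1),
      t2High = baseSpec@t2High * stats::runif(1, 0.9, 1.1),
      translation = stats::runif(3, -1, 1) * c(6, 6, 3),
      rotation = c(0, 0, stats::runif(1, -5, 5)),
      warpAmplitude = stats::runif(1, 1, 2.5),
      seed = deriveSeed(seed, 1000L + i))
    case <- generatePhantom(spec, caseId = sprintf("case%02d", i))
    if (misalign) case <- applyMisalignment(case, spec) else case
  })
}
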