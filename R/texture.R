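#' Texture matrices of a discretized image region
#'
#' Holds the gray-level co-occurrence (GLCM, per angle), run-length (GLRLM,
#' per direction), size-zone (GLSZM), dependence (GLDM) and neighbouring
#' gray-tone difference (NGTDM) matrices of one discretized 2D region,
#' plus the normalization constants.
#'
#' @slot glcm list of unnormalized symmetric co-occurrence count matrices,
#'   one per angle.
#' @slot glrlm list of run-length count matrices, one per direction.
#' @slot glszm zone count matrix (gray level x zone size).
#' @slot gldm dependence count matrix (gray level x dependence).
#' @slot ngtdm two-column matrix (n_i, s_i) per gray level.
#' @slot ng number of gray levels.
#' @slot np number of pixels in the region.
#' @export
setClass("TextureMatrices",
  representation(glcm = "list", glrlm = "list", glszm = "matrix",
                 gldm = "matrix", ngtdm = "matrix", ng = "integer",
                 np = "integer"))

glcmOffsets <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L))
glrlmDirections <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))

glcmFeatureNames <- paste0("glcm_", c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy",
  "MaximumProbability", "MCC", "SumAverage", "SumEntropy", "SumSquares"))
glrlmFeatureNames <- paste0("glrlm_", c(
  "ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "GrayLevelVariance",
  "RunVariance", "RunEntropy", "LowGrayLevelRunEmphasis",
  "HighGrayLevelRunEmphasis", "ShortRunLowGrayLevelEmphasis",
  "ShortRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LongRunHighGrayLevelEmphasis"))
glszmFeatureNames <- paste0("glszm_", c(
  "SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
  "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "GrayLevelVariance",
  "ZoneVariance", "ZoneEntropy", "LowGrayLevelZoneEmphasis",
  "HighGrayLevelZoneEmphasis", "SmallAreaLowGrayLevelEmphasis",
  "SmallAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LargeAreaHighGrayLevelEmphasis"))
gldmFeatureNames <- paste0("gldm_", c(
  "SmallDependenceEmphasis", "LargeDependenceEmphasis",
  "GrayLevelNonUniformity", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "GrayLevelVariance",
  "DependenceVariance", "DependenceEntropy", "LowGrayLevelEmphasis",
  "HighGrayLevelEmphasis", "SmallDependenceLowGrayLevelEmphasis",
  "SmallDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis",
  "LargeDependenceHighGrayLevelEmphasis"))
ngtdmFeatureNames <- paste0("ngtdm_", c(
  "Coarseness", "Contrast", "Busyness", "Complexity", "Strength"))

#' Build all texture matrices for a discretized region
#'
#' @param disc integer matrix of gray levels 1..ng, 0 outside the region
#'   (see \code{\link{discretizeImage}}).
#' @param ng number of gray levels (defaults to the maximum level present).
#' @param alpha gray-level tolerance of the dependence matrix (default 0).
#' @param angles subset of 1:4 selecting GLCM angles (0, 45, 90, 135
#'   degrees) and GLRLM directions.
#' @return A \linkS4class{TextureMatrices}.
#' @export
textureMatrices <- function(disc, ng = max(disc), alpha = 0L,
                            angles = 1:4) {
  if (!any(disc > 0)) stop("region is empty")
  ng <- as.integer(ng)
  storage.mode(disc) <- "integer"
  new("TextureMatrices",
      glcm = lapply(glcmOffsets[angles],
                    function(o) cpp_glcm(disc, ng, o[1], o[2])),
      glrlm = lapply(glrlmDirections[angles],
                     function(o) cpp_glrlm(disc, ng, o[1], o[2])),
      glszm = cpp_glszm(disc, ng),
      gldm = cpp_gldm(disc, ng, as.integer(alpha)),
      ngtdm = cpp_ngtdm(disc, ng),
      ng = ng, np = sum(disc > 0L))
}

log2z <- function(x) ifelse(x > 0, log2(x), 0)

#' First-order intensity statistics
#'
#' The standard 19-feature first-order set over a vector of masked
#' intensities. Entropy and uniformity are computed on an equal-width
#' discretization of the values (\code{nBins} levels); standard deviation,
#' variance, skewness and kurtosis use the population (N) convention, and
#' skewness/kurtosis of a constant input are defined as 0.
#'
#' @param values numeric vector (at least one value).
#' @param nBins bins for entropy/uniformity (default 32).
#' @param pixelArea physical area (mm^2) per pixel, for total energy.
#' @return Named numeric vector of 19 features.
#' @export
computeFirstOrder <- function(values, nBins = 32L, pixelArea = 1) {
  if (length(values) == 0) stop("empty input")
  n <- length(values)
  rng <- range(values)
  lev <- if (diff(rng) == 0) rep(1L, n) else
    pmin(floor((values - rng[1]) / diff(rng) * nBins) + 1, nBins)
  p <- tabulate(lev, nbins = nBins) / n
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  q <- stats::quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  inner <- values[values >= q[1] & values <= q[5]]
  c(fo_Energy = sum(values^2),
    fo_TotalEnergy = pixelArea * sum(values^2),
    fo_Entropy = -sum(p * log2z(p)),
    fo_Minimum = rng[1],
    fo_Percentile10 = q[1],
    fo_Percentile90 = q[5],
    fo_Maximum = rng[2],
    fo_Mean = mu,
    fo_Median = q[3],
    fo_InterquartileRange = q[4] - q[2],
    fo_Range = diff(rng),
    fo_MeanAbsoluteDeviation = mean(abs(values - mu)),
    fo_RobustMeanAbsoluteDeviation =
      if (length(inner)) mean(abs(inner - mean(inner))) else 0,
    fo_RootMeanSquared = sqrt(mean(values^2)),
    fo_StandardDeviation = sqrt(m2),
    fo_Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    fo_Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    fo_Variance = m2,
    fo_Uniformity = sum(p^2))
}

glcmFeaturesOneAngle <- function(C, ng) {
  s <- sum(C)
  P <- C / s
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal and cross-diagonal distributions (observed k only; absent k
  # have zero probability and contribute nothing downstream)
  sumTab <- rowsum(as.numeric(P), as.numeric(i + j))
  kSum <- as.numeric(rownames(sumTab)); pSum <- sumTab[, 1]
  diffTab <- rowsum(as.numeric(P), as.numeric(abs(i - j)))
  kDiff <- as.numeric(rownames(diffTab)); pDiff <- diffTab[, 1]
  HX <- -sum(px * log2z(px)); HY <- -sum(py * log2z(py))
  HXY <- -sum(P * log2z(P))
  pxy <- outer(px, py)
  HXY1 <- -sum(P * log2z(pxy))
  HXY2 <- -sum(pxy * log2z(pxy))
  da <- sum(kDiff * pDiff)
  occ <- which(px > 0)
  mcc <- if (length(occ) < 2) 1 else {
    Q <- matrix(0, length(occ), length(occ))
    Psub <- P[occ, occ, drop = FALSE]
    pxs <- px[occ]; pys <- py[occ]
    for (a in seq_along(occ))
      Q[a, ] <- as.numeric(Psub %*% (Psub[a, ] / pys)) / pxs[a]
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  corr <- if (sx * sy > 0) (sum(P * i * j) - mux * muy) / (sx * sy) else 1
  c(glcm_Autocorrelation = sum(P * i * j),
    glcm_ClusterProminence = sum((i + j - mux - muy)^4 * P),
    glcm_ClusterShade = sum((i + j - mux - muy)^3 * P),
    glcm_ClusterTendency = sum((i + j - mux - muy)^2 * P),
    glcm_Contrast = sum((i - j)^2 * P),
    glcm_Correlation = corr,
    glcm_DifferenceAverage = da,
    glcm_DifferenceEntropy = -sum(pDiff * log2z(pDiff)),
    glcm_DifferenceVariance = sum((kDiff - da)^2 * pDiff),
    glcm_Id = sum(P / (1 + abs(i - j))),
    glcm_Idm = sum(P / (1 + (i - j)^2)),
    glcm_Idmn = sum(P / (1 + (i - j)^2 / ng^2)),
    glcm_Idn = sum(P / (1 + abs(i - j) / ng)),
    glcm_Imc1 = if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0,
    glcm_Imc2 = sqrt(pmax(0, 1 - exp(-2 * (HXY2 - HXY)))),
    glcm_InverseVariance = sum(P[i != j] / (i - j)[i != j]^2),
    glcm_JointAverage = mux,
    glcm_JointEnergy = sum(P^2),
    glcm_JointEntropy = HXY,
    glcm_MaximumProbability = max(P),
    glcm_MCC = mcc,
    glcm_SumAverage = sum(kSum * pSum),
    glcm_SumEntropy = -sum(pSum * log2z(pSum)),
    glcm_SumSquares = sum((i - mux)^2 * P))
}

#' Gray-level co-occurrence features
#'
#' The 24-feature co-occurrence set (autocorrelation, contrast, correlation,
#' joint energy/entropy, cluster statistics, informational measures, MCC,
#' ...), computed per angle from the normalized symmetric GLCM and averaged
#' over angles with at least one co-occurring pair.
#'
#' @param tm a \linkS4class{TextureMatrices}.
#' @return Named numeric vector of 24 features.
#' @export
computeGlcmFeatures <- function(tm) {
  mats <- Filter(function(C) sum(C) > 0, tm@glcm)
  if (!length(mats)) stop("empty co-occurrence matrix")
  out <- rowMeans(vapply(mats, glcmFeaturesOneAngle,
                         numeric(24), ng = tm@ng))
  names(out) <- glcmFeatureNames
  out
}

runZoneFeatures <- function(P, np, prefix, sizeNames) {
  Ns <- sum(P)
  i <- row(P); j <- col(P)
  pn <- P / Ns
  pg <- rowSums(pn); ps <- colSums(pn)
  mug <- sum(seq_along(pg) * pg)
  mus <- sum(seq_along(ps) * ps)
  out <- c(
    sum(P / col(P)^2) / Ns,                       # small emphasis
    sum(P * col(P)^2) / Ns,                       # large emphasis
    sum(rowSums(P)^2) / Ns,                       # gray-level non-uniformity
    sum(rowSums(P)^2) / Ns^2,                     # ... normalized
    sum(colSums(P)^2) / Ns,                       # size non-uniformity
    sum(colSums(P)^2) / Ns^2,                     # ... normalized
    Ns / np,                                      # percentage
    sum((i - mug)^2 * pn),                        # gray-level variance
    sum((j - mus)^2 * pn),                        # size variance
    -sum(pn * log2z(pn)),                         # entropy
    sum(P / row(P)^2) / Ns,                       # low gray-level emphasis
    sum(P * row(P)^2) / Ns,                       # high gray-level emphasis
    sum(P / (row(P)^2 * col(P)^2)) / Ns,          # small + low
    sum(P * row(P)^2 / col(P)^2) / Ns,            # small + high
    sum(P * col(P)^2 / row(P)^2) / Ns,            # large + low
    sum(P * row(P)^2 * col(P)^2) / Ns)            # large + high
  names(out) <- paste0(prefix, c(
    paste0("Short", sizeNames, "Emphasis"),
    paste0("Long", sizeNames, "Emphasis"),
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    paste0(sizeNames, "LengthNonUniformity"),
    paste0(sizeNames, "LengthNonUniformityNormalized"),
    paste0(sizeNames, "Percentage"),
    "GrayLevelVariance", paste0(sizeNames, "Variance"),
    paste0(sizeNames, "Entropy"),
    paste0("LowGrayLevel", sizeNames, "Emphasis"),
    paste0("HighGrayLevel", sizeNames, "Emphasis"),
    paste0("Short", sizeNames, "LowGrayLevelEmphasis"),
    paste0("Short", sizeNames, "HighGrayLevelEmphasis"),
    paste0("Long", sizeNames, "LowGrayLevelEmphasis"),
    paste0("Long", sizeNames, "HighGrayLevelEmphasis")))
  out
}

#' Gray-level run-length features
#'
#' The 16-feature run-length set (run percentage, short/long-run emphases,
#' gray-level and run-length non-uniformity, run entropy, ...), computed
#' per direction and averaged over directions containing runs.
#'
#' @param tm a \linkS4class{TextureMatrices}.
#' @return Named numeric vector of 16 features.
#' @export
computeGlrlmFeatures <- function(tm) {
  mats <- Filter(function(R) sum(R) > 0, tm@glrlm)
  if (!length(mats)) stop("empty run-length matrix")
  out <- rowMeans(vapply(mats, runZoneFeatures, numeric(16),
                         np = tm@np, prefix = "glrlm_", sizeNames = "Run"))
  names(out) <- glrlmFeatureNames
  out
}

#' Gray-level size-zone features
#'
#' The 16-feature size-zone set over 8-connected constant-level zones
#' (small/large area emphases, zone percentage, zone entropy, ...).
#'
#' @param tm a \linkS4class{TextureMatrices}.
#' @return Named numeric vector of 16 features.
#' @export
computeGlszmFeatures <- function(tm) {
  if (sum(tm@glszm) == 0) stop("empty size-zone matrix")
  out <- runZoneFeatures(tm@glszm, tm@np, "glszm_", "Zone")
  names(out) <- glszmFeatureNames
  out
}

#' Gray-level dependence features
#'
#' The 14-feature dependence set: a pixel's dependence is 1 plus the number
#' of neighbours (Chebyshev distance 1) whose gray level differs by at most
#' alpha from the centre. Includes dependence non-uniformity, small/large
#' dependence emphases and their gray-level-weighted versions.
#'
#' @param tm a \linkS4class{TextureMatrices}.
#' @return Named numeric vector of 14 features.
#' @export
computeGldmFeatures <- function(tm) {
  P <- tm@gldm
  Nz <- sum(P)
  if (Nz == 0) stop("empty dependence matrix")
  i <- row(P); j <- col(P)
  pn <- P / Nz
  mug <- sum(seq_len(nrow(P)) * rowSums(pn))
  mud <- sum(seq_len(ncol(P)) * colSums(pn))
  c(gldm_SmallDependenceEmphasis = sum(P / j^2) / Nz,
    gldm_LargeDependenceEmphasis = sum(P * j^2) / Nz,
    gldm_GrayLevelNonUniformity = sum(rowSums(P)^2) / Nz,
    gldm_DependenceNonUniformity = sum(colSums(P)^2) / Nz,
    gldm_DependenceNonUniformityNormalized = sum(colSums(P)^2) / Nz^2,
    gldm_GrayLevelVariance = sum((i - mug)^2 * pn),
    gldm_DependenceVariance = sum((j - mud)^2 * pn),
    gldm_DependenceEntropy = -sum(pn * log2z(pn)),
    gldm_LowGrayLevelEmphasis = sum(P / i^2) / Nz,
    gldm_HighGrayLevelEmphasis = sum(P * i^2) / Nz,
    gldm_SmallDependenceLowGrayLevelEmphasis = sum(P / (i^2 * j^2)) / Nz,
    gldm_SmallDependenceHighGrayLevelEmphasis = sum(P * i^2 / j^2) / Nz,
    gldm_LargeDependenceLowGrayLevelEmphasis = sum(P * j^2 / i^2) / Nz,
    gldm_LargeDependenceHighGrayLevelEmphasis = sum(P * i^2 * j^2) / Nz)
}

#' Neighbouring gray-tone difference features
#'
#' The 5-feature NGTDM set (coarseness, contrast, busyness, complexity,
#' strength) from the per-level occurrence probabilities p_i and summed
#' absolute differences s_i between each pixel and its neighbourhood
#' average. Coarseness is \code{1 / (1e-6 + sum(p_i s_i))}, so a constant
#' region yields 1e6.
#'
#' @param tm a \linkS4class{TextureMatrices}.
#' @return Named numeric vector of 5 features.
#' @export
computeNgtdmFeatures <- function(tm) {
  n <- tm@ngtdm[, 1]
  s <- tm@ngtdm[, 2]
  Np <- sum(n)
  if (Np == 0) stop("empty neighbourhood difference matrix")
  p <- n / Np
  lev <- seq_along(p)
  act <- which(p > 0)
  ngp <- length(act)
  ps <- sum(p * s)
  contrast <- if (ngp > 1) {
    sum(outer(p[act], p[act]) * outer(lev[act], lev[act], `-`)^2) /
      (ngp * (ngp - 1)) * sum(s) / Np
  } else 0
  busyDen <- sum(abs(outer(lev[act] * p[act], lev[act] * p[act], `-`)))
  busyness <- if (busyDen > 0) ps / busyDen else 0
  complexity <- if (ngp > 0) {
    pi_ <- p[act]; si_ <- s[act]; li <- lev[act]
    sum(abs(outer(li, li, `-`)) *
          (outer(pi_ * si_, pi_ * si_, function(a, b) a + b)) /
          outer(pi_, pi_, `+`)) / Np
  } else 0
  strength <- if (sum(s) > 0 && ngp > 1) {
    sum(outer(p[act], p[act], `+`) * outer(lev[act], lev[act], `-`)^2) /
      sum(s)
  } else 0
  c(ngtdm_Coarseness = 1 / (1e-6 + ps),
    ngtdm_Contrast = contrast,
    ngtdm_Busyness = busyness,
    ngtdm_Complexity = complexity,
    ngtdm_Strength = strength)
}
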