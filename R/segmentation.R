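#' Automatic tumor segmentation by K-means on high-b DWI
#'
#' Lloyd K-means on the voxel intensities of the b = 1200 volume (tumor is
#' hyperintense at high diffusion weighting); the cluster with the highest
#' mean intensity is taken as tumor and reduced to its largest 3D connected
#' component (6-connectivity). Initial centres are placed at evenly spaced
#' intensity quantiles, making the clustering deterministic; \code{seed}
#' additionally pins down R's RNG for reproducibility of any ties.
#'
#' @param dwiB1200 \linkS4class{MRIVolume}, the b = 1200 DWI volume.
#' @param k number of clusters (default 2: tumor vs rest).
#' @param seed integer seed.
#' @return A \linkS4class{TumorMask}.
#' @export
segmentTumorKmeans <- function(dwiB1200, k = 2L, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  v <- as.numeric(dwiB1200@data)
  if (stats::sd(v) == 0) stop("cannot cluster a constant image")
  set.seed(seed)
  centers <- matrix(stats::quantile(v, probs = seq(0.05, 0.95,
                                                   length.out = k),
                                    names = FALSE), ncol = 1)
  if (anyDuplicated(centers))
    centers <- matrix(seq(min(v), max(v), length.out = k), ncol = 1)
  km <- stats::kmeans(matrix(v, ncol = 1), centers = centers,
                      iter.max = 100L, algorithm = "Lloyd")
  tumorCluster <- which.max(km$centers)
  mask <- array(km$cluster == tumorCluster, dim = dim(dwiB1200@data))
  lab <- cpp_label3d(mask, as.integer(dim(mask)))
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    mask <- array(lab == which.max(sizes), dim = dim(mask))
  }
  new("TumorMask", mask = mask, spacing = dwiB1200@spacing)
}

#' ADC-threshold cellularity labeling
#'
#' Within the tumor mask, voxels with ADC below the cut-off are labelled
#' high cellularity (code 1); voxels inside the optional uncertain band are
#' labelled uncertain (code 3); the rest low cellularity (code 2); outside
#' the mask, background (code 0). Binary classification downstream treats
#' high vs everything else in the mask (uncertain collapses into low).
#'
#' @param adc \linkS4class{MRIVolume} ADC map (mm^2/s), aligned to the mask
#'   grid.
#' @param mask \linkS4class{TumorMask}.
#' @param cutoff ADC cut-off in mm^2/s (default 0.85e-3, the highly
#'   cellular tumor threshold).
#' @param uncertainBand optional numeric(2) ADC interval labelled uncertain
#'   (used for visualization only).
#' @return A \linkS4class{CellularityLabelMap}.
#' @export
labelCellularity <- function(adc, mask, cutoff = 0.85e-3,
                             uncertainBand = NULL) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (!identical(dim(adc@data), dim(mask@mask)))
    stop("ADC map and mask must share the same grid")
  a <- adc@data
  m <- mask@mask
  if (any(a[m] < 0)) stop("negative ADC values inside the tumor mask")
  labels <- array(0L, dim = dim(a))
  labels[m] <- 2L
  labels[m & a < cutoff] <- 1L
  if (!is.null(uncertainBand)) {
    stopifnot(length(uncertainBand) == 2, uncertainBand[1] < uncertainBand[2])
    unc <- m & a >= uncertainBand[1] & a < uncertainBand[2] & a >= cutoff
    labels[unc] <- 3L
  }
  new("CellularityLabelMap", labels = labels, cutoff = cutoff,
      band = uncertainBand)
}

#' Extract the tumor region of interest
#'
#' Tight bounding-box crop of the T2 volume and the mask with background
#' zeroed; the 0-based crop offset is returned so per-pixel predictions can
#' be mapped back to the original grid. Bounding boxes are half-open in
#' 0-based voxel indices.
#'
#' @param t2 \linkS4class{MRIVolume}.
#' @param mask non-empty \linkS4class{TumorMask} on the same grid.
#' @return List with elements \code{roi} (MRIVolume, background zeroed),
#'   \code{mask} (TumorMask of the crop) and \code{offset} (integer(3),
#'   0-based).
#' @export
extractRoi <- function(t2, mask) {
  m <- mask@mask
  if (!any(m)) stop("tumor mask is empty")
  idx <- which(m, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  sub <- t2@data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msub <- m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  sub[!msub] <- 0
  list(roi = MRIVolume(sub, t2@spacing),
       mask = new("TumorMask", mask = msub, spacing = t2@spacing),
       offset = as.integer(lo - 1L))
}

#' Fit an ADC map from a multi-b DWI series
#'
#' Per-voxel least-squares slope of \code{-log(S(b)/S(0))} against b under
#' the monoexponential decay model; the fallback when no scanner ADC map is
#' supplied. Voxels with non-positive signal at any b are flagged invalid
#' and get ADC 0; fitted values are clipped at 0.
#'
#' @param dwi named list of \linkS4class{MRIVolume}s keyed by b-value;
#'   at least two b-values including 0.
#' @return \linkS4class{MRIVolume} ADC map (mm^2/s) with an attribute
#'   \code{validMask} (logical array) on its data marking fitted voxels.
#' @export
computeAdc <- function(dwi) {
  b <- as.numeric(names(dwi))
  if (length(b) < 2 || !0 %in% b)
    stop("need >= 2 b-values including b = 0")
  ord <- order(b)
  b <- b[ord]
  shape <- dim(dwi[[1]]@data)
  sig <- vapply(dwi[ord], function(v) as.numeric(v@data),
                numeric(prod(shape)))
  valid <- rowSums(sig <= 0) == 0
  logs <- matrix(0, nrow = nrow(sig), ncol = ncol(sig))
  logs[valid, ] <- log(sig[valid, , drop = FALSE])
  # slope of log S vs b, per voxel: ADC = -cov(b, logS) / var(b)
  bc <- b - mean(b)
  denom <- sum(bc^2)
  slope <- as.numeric(logs %*% bc) / denom
  adc <- pmax(-slope, 0)
  adc[!valid] <- 0
  out <- array(adc, dim = shape)
  attr(out, "validMask") <- array(valid, dim = shape)
  MRIVolume(out, dwi[[1]]@spacing)
}
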