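#' Feature extraction configuration
#'
#' @param window side (pixels) of the sliding window in which texture and
#'   first-order statistics are computed around each tumor pixel (odd).
#' @param nBins gray levels for discretization.
#' @param blockSize pixels per prediction block (default 400).
#' @param families texture families to compute.
#' @param shape include per-slice 2D shape features (broadcast to the
#'   slice's pixels).
#' @param minWindowPixels rows whose window contains fewer masked pixels
#'   are dropped (with a logged count).
#' @param filter filter-bank settings, see \code{\link{filterBankConfig}}.
#' @return List of settings for \code{\link{pixelFeatureMatrix}}.
#' @export
featureConfig <- function(window = 5L, nBins = 32L, blockSize = 400L,
                          families = c("firstorder", "glcm", "glrlm",
                                       "glszm", "gldm", "ngtdm"),
                          shape = TRUE, minWindowPixels = 2L,
                          filter = filterBankConfig()) {
  stopifnot(window %% 2 == 1)
  list(window = as.integer(window), nBins = as.integer(nBins),
       blockSize = as.integer(blockSize), families = families,
       shape = shape, minWindowPixels = as.integer(minWindowPixels),
       filter = filter)
}

# Per-slice 2D shape descriptors of the mask, broadcast to its pixels.
sliceShapeFeatures <- function(msk, spacing) {
  px <- spacing[1] * spacing[2]
  n <- sum(msk)
  area <- n * px
  # perimeter: exposed 4-neighbour edges, weighted by edge length
  pad <- matrix(FALSE, nrow(msk) + 2, ncol(msk) + 2)
  pad[2:(nrow(msk) + 1), 2:(ncol(msk) + 1)] <- msk
  core <- pad[2:(nrow(msk) + 1), 2:(ncol(msk) + 1)]
  per <- sum(core & !pad[1:nrow(msk), 2:(ncol(msk) + 1)]) * spacing[2] +
    sum(core & !pad[3:(nrow(msk) + 2), 2:(ncol(msk) + 1)]) * spacing[2] +
    sum(core & !pad[2:(nrow(msk) + 1), 1:ncol(msk)]) * spacing[1] +
    sum(core & !pad[2:(nrow(msk) + 1), 3:(ncol(msk) + 2)]) * spacing[1]
  idx <- which(msk, arr.ind = TRUE)
  xy <- cbind(idx[, 1] * spacing[1], idx[, 2] * spacing[2])
  ev <- if (nrow(xy) > 1) {
    eigen(stats::cov(xy), only.values = TRUE)$values
  } else c(0, 0)
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  c(shape_Area = area,
    shape_Perimeter = per,
    shape_PerimeterToArea = if (area > 0) per / area else 0,
    shape_MajorAxisLength = major,
    shape_MinorAxisLength = minor,
    shape_Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    shape_Sphericity = if (per > 0) 2 * sqrt(pi * area) / per else 0)
}

# Degenerate windows (e.g. an isolated pixel with no co-occurring pairs)
# get zero-valued texture features rather than errors, keeping the matrix
# free of missing values.
textureFamilyFeatures <- function(tm, families) {
  safe <- function(f, nms) tryCatch(f(tm), error = function(e)
    stats::setNames(numeric(length(nms)), nms))
  out <- numeric(0)
  if ("glcm" %in% families)
    out <- c(out, safe(computeGlcmFeatures, glcmFeatureNames))
  if ("glrlm" %in% families)
    out <- c(out, safe(computeGlrlmFeatures, glrlmFeatureNames))
  if ("glszm" %in% families)
    out <- c(out, safe(computeGlszmFeatures, glszmFeatureNames))
  if ("gldm" %in% families)
    out <- c(out, safe(computeGldmFeatures, gldmFeatureNames))
  if ("ngtdm" %in% families)
    out <- c(out, safe(computeNgtdmFeatures, ngtdmFeatureNames))
  out
}

#' Per-pixel radiomic feature matrix of a tumor region
#'
#' For every tumor pixel, per slice, the feature vector concatenates the
#' value of every filter-bank image at that pixel, first-order and texture
#' (GLCM/GLRLM/GLSZM/GLDM/NGTDM) statistics computed in a sliding window
#' centred at the pixel and intersected with the mask, and per-slice 2D
#' shape descriptors. Rows are ordered deterministically (slice, then row,
#' then column) and chunked into blocks of \code{blockSize}; the binary
#' cellularity label (1 = high) is attached from the label map.
#'
#' @param roiT2 \linkS4class{MRIVolume}, T2 region of interest (see
#'   \code{\link{extractRoi}}).
#' @param mask \linkS4class{TumorMask} on the same grid.
#' @param labels \linkS4class{CellularityLabelMap} on the same grid (pass
#'   the cropped map when using a cropped ROI).
#' @param config see \code{\link{featureConfig}}.
#' @param caseId case identifier stored in the row metadata.
#' @return A \linkS4class{PixelFeatureMatrix}; the number of rows dropped
#'   for degenerate windows is in \code{attr(, "droppedRows")}.
#' @export
pixelFeatureMatrix <- function(roiT2, mask, labels, config = featureConfig(),
                               caseId = "case") {
  stopifnot(identical(dim(roiT2@data), dim(mask@mask)),
            identical(dim(roiT2@data), dim(labels@labels)))
  if (!any(mask@mask)) stop("empty ROI")
  spacing <- roiT2@spacing
  half <- (config$window - 1L) %/% 2L
  rows <- list(); info <- list()
  dropped <- 0L
  for (k in seq_len(dim(roiT2@data)[3])) {
    msk <- mask@mask[, , k]
    if (!any(msk)) next
    slice <- roiT2@data[, , k]
    fb <- applyFilterBank(slice, msk, spacing[1:2], config$filter)
    disc <- discretizeImage(slice, msk, config$nBins)
    shp <- if (isTRUE(config$shape)) sliceShapeFeatures(msk, spacing[1:2])
           else NULL
    idx <- which(msk, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    for (q in seq_len(nrow(idx))) {
      r <- idx[q, 1]; cc <- idx[q, 2]
      r0 <- max(1L, r - half); r1 <- min(nrow(disc), r + half)
      c0 <- max(1L, cc - half); c1 <- min(ncol(disc), cc + half)
      wdisc <- disc[r0:r1, c0:c1, drop = FALSE]
      inWin <- wdisc > 0
      if (sum(inWin) < config$minWindowPixels) { dropped <- dropped + 1L; next }
      wvals <- slice[r0:r1, c0:c1, drop = FALSE][inWin]
      filt <- vapply(fb, function(im) im[r, cc], numeric(1))
      names(filt) <- paste0("filter_", names(fb))
      feats <- filt
      if ("firstorder" %in% config$families)
        feats <- c(feats, computeFirstOrder(wvals, config$nBins,
                                            spacing[1] * spacing[2]))
      texFams <- intersect(config$families,
                           c("glcm", "glrlm", "glszm", "gldm", "ngtdm"))
      if (length(texFams)) {
        tm <- textureMatrices(wdisc, ng = config$nBins)
        feats <- c(feats, textureFamilyFeatures(tm, texFams))
      }
      if (!is.null(shp)) feats <- c(feats, shp)
      rows[[length(rows) + 1L]] <- feats
      info[[length(info) + 1L]] <-
        c(slice = k, y = r, x = cc,
          label = as.integer(labels@labels[r, cc, k] == 1L))
    }
  }
  if (!length(rows)) stop("no usable tumor pixels")
  fm <- do.call(rbind, rows)
  meta <- as.data.frame(do.call(rbind, info))
  out <- new("PixelFeatureMatrix", features = fm,
             info = data.frame(case = caseId, slice = meta$slice,
                               y = meta$y, x = meta$x,
                               block = (seq_len(nrow(fm)) - 1L) %/%
                                 config$blockSize + 1L,
                               label = meta$label,
                               stringsAsFactors = FALSE),
             blockSize = config$blockSize)
  attr(out, "droppedRows") <- dropped
  out
}

#' Construct a feature matrix from plain data
#'
#' Convenience constructor for selection/classification experiments on
#' synthetic tabular data: wraps a numeric matrix, binary labels and an
#' optional case/group id into a \linkS4class{PixelFeatureMatrix}.
#'
#' @param x numeric matrix (rows = samples, named columns = features).
#' @param labels binary labels (0/1), length nrow(x).
#' @param case case/group id per row (default one group).
#' @param blockSize block size for block-wise prediction.
#' @return A \linkS4class{PixelFeatureMatrix}.
#' @export
featureMatrix <- function(x, labels, case = "case", blockSize = 400L) {
  x <- as.matrix(x)
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("f%03d", seq_len(ncol(x)))
  if (length(case) == 1) case <- rep(case, nrow(x))
  new("PixelFeatureMatrix", features = x,
      info = data.frame(case = case, slice = 1L, y = seq_len(nrow(x)),
                        x = 1L,
                        block = (seq_len(nrow(x)) - 1L) %/% blockSize + 1L,
                        label = as.integer(labels),
                        stringsAsFactors = FALSE),
      blockSize = as.integer(blockSize))
}

#' Combine feature matrices of several cases
#'
#' @param fms list of \linkS4class{PixelFeatureMatrix} with identical
#'   feature columns.
#' @return One \linkS4class{PixelFeatureMatrix}.
#' @export
bindFeatureMatrices <- function(fms) {
  stopifnot(length(fms) >= 1)
  cols <- featureNames(fms[[1]])
  for (f in fms) stopifnot(identical(featureNames(f), cols))
  new("PixelFeatureMatrix",
      features = do.call(rbind, lapply(fms, featureValues)),
      info = do.call(rbind, lapply(fms, featureInfo)),
      blockSize = fms[[1]]@blockSize)
}

#' Drop constant feature columns
#'
#' Removes columns with zero variance across all rows (features that do not
#' differ from image to image carry no information for classification).
#' Idempotent; dropped names are recorded in \code{attr(, "dropped")}.
#'
#' @param fm a \linkS4class{PixelFeatureMatrix}.
#' @return The reduced \linkS4class{PixelFeatureMatrix}.
#' @export
removeConstantFeatures <- function(fm) {
  x <- fm@features
  if (nrow(x) < 1) stop("feature matrix has no rows")
  keep <- apply(x, 2, function(col) max(col) > min(col))
  if (!any(keep)) stop("all feature columns are constant")
  out <- initialize(fm, features = x[, keep, drop = FALSE])
  attr(out, "dropped") <- colnames(x)[!keep]
  out
}
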