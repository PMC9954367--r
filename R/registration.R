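#' Root-mean-square intensity difference
#'
#' Alignment-quality metric: the smaller the RMS difference between two
#' volumes on the same grid, the better they match.
#'
#' @param a,b \linkS4class{MRIVolume}s or arrays on the same grid.
#' @param mask optional logical array restricting the comparison.
#' @return RMS difference (scalar).
#' @export
rmsDifference <- function(a, b, mask = NULL) {
  av <- if (is(a, "MRIVolume")) a@data else a
  bv <- if (is(b, "MRIVolume")) b@data else b
  if (!identical(dim(av), dim(bv)))
    stop("volumes must share the same grid")
  d <- av - bv
  if (!is.null(mask)) {
    if (!any(mask)) stop("mask is empty")
    d <- d[mask]
  }
  sqrt(mean(d^2))
}

#' Histogram matching of intensities
#'
#' Maps the moving volume's intensities onto the fixed volume's intensity
#' distribution by quantile matching, making a cross-modality pair
#' comparable for intensity-difference-driven (Demons) registration.
#'
#' @param moving,fixed \linkS4class{MRIVolume}s or arrays.
#' @return Array (or MRIVolume, matching the input type) with remapped
#'   intensities.
#' @export
matchHistogram <- function(moving, fixed) {
  mv <- if (is(moving, "MRIVolume")) moving@data else moving
  fv <- if (is(fixed, "MRIVolume")) fixed@data else fixed
  p <- (rank(mv, ties.method = "average") - 0.5) / length(mv)
  out <- array(stats::quantile(fv, probs = p, names = FALSE), dim = dim(mv))
  if (is(moving, "MRIVolume")) MRIVolume(out, moving@spacing) else out
}

# Sample `n` uniform continuous 0-based voxel coordinates, 3 x n.
samplePoints <- function(shape, n, seed) {
  set.seed(seed)
  rbind(stats::runif(n, 0, shape[1] - 1),
        stats::runif(n, 0, shape[2] - 1),
        stats::runif(n, 0, shape[3] - 1))
}

# Joint-histogram MI over paired samples. With overlapPenalty, the MI is
# weighted by the fraction of samples falling inside both volumes --
# without it the optimizer can inflate the metric by pushing samples off
# the grid (fewer samples = higher small-sample MI bias).
miFromSamples <- function(fv, mv, nBins, fRange, mRange,
                          overlapPenalty = FALSE, weights = NULL,
                          parzen = TRUE) {
  if (is.null(weights)) weights <- rep(1, length(fv))
  ok <- !is.na(fv) & !is.na(mv) & weights > 0
  if (sum(ok) < 10) stop("no overlapping samples for mutual information")
  frac <- sum(weights[ok]) / length(fv)
  sw <- weights[ok]
  fv <- fv[ok]; mv <- mv[ok]
  # linear partial-volume (Parzen) binning: each sample spreads over the
  # two nearest bins on each axis, keeping the metric smooth in the
  # transform parameters
  softBin <- function(v, rng) {
    if (rng[2] <= rng[1])
      return(list(i0 = rep(1L, length(v)), i1 = rep(1L, length(v)),
                  w1 = rep(0, length(v))))
    u <- (v - rng[1]) / (rng[2] - rng[1]) * nBins + 0.5
    u <- pmin(pmax(u, 1), nBins)
    i0 <- pmin(floor(u), nBins - 1)
    list(i0 = as.integer(i0), i1 = as.integer(i0 + 1), w1 = u - i0)
  }
  if (!parzen) {
    # hard binning: the classic joint-histogram estimate (identical images
    # then attain exactly their marginal entropy)
    hardBin <- function(v, rng) {
      if (rng[2] <= rng[1]) return(rep(1L, length(v)))
      pmin(pmax(floor((v - rng[1]) / (rng[2] - rng[1]) * nBins) + 1L,
                1L), nBins)
    }
    idx <- hardBin(fv, fRange) + nBins * (hardBin(mv, mRange) - 1L)
    w <- sw
  } else {
    f <- softBin(fv, fRange); m <- softBin(mv, mRange)
    idx <- c(f$i0 + nBins * (m$i0 - 1L), f$i1 + nBins * (m$i0 - 1L),
             f$i0 + nBins * (m$i1 - 1L), f$i1 + nBins * (m$i1 - 1L))
    w <- c((1 - f$w1) * (1 - m$w1), f$w1 * (1 - m$w1),
           (1 - f$w1) * m$w1, f$w1 * m$w1) * rep(sw, 4)
  }
  tab <- rowsum(w, idx)
  joint <- numeric(nBins * nBins)
  joint[as.integer(rownames(tab))] <- tab[, 1]
  p <- joint / sum(joint)
  pf <- rowSums(matrix(p, nBins, nBins))
  pm <- colSums(matrix(p, nBins, nBins))
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (rep(pf, nBins)[nz] *
                                   rep(pm, each = nBins)[nz])))
  if (overlapPenalty) mi * frac else mi
}

#' Mattes-style mutual information between two volumes
#'
#' Joint-histogram mutual information (nats) estimated over randomly
#' sampled points with linear interpolation; higher means a better match.
#' Deterministic under a fixed seed.
#'
#' @param fixed,moving \linkS4class{MRIVolume}s on the same grid.
#' @param nBins histogram bins per intensity axis (default 32).
#' @param nSamples number of sample points (default 10\% of voxels).
#' @param seed sampling seed.
#' @return Mutual information estimate in nats.
#' @export
mattesMutualInformation <- function(fixed, moving, nBins = 32L,
                                    nSamples = NULL, seed = 7L) {
  if (nBins < 2) stop("nBins must be >= 2")
  shape <- dim(fixed@data)
  if (!identical(shape, dim(moving@data)))
    stop("volumes must share the same grid")
  if (is.null(nSamples)) nSamples <- max(1000L, round(0.1 * prod(shape)))
  pts <- samplePoints(shape, nSamples, seed)
  fv <- cpp_sample3(fixed@data, as.integer(shape), pts)
  mv <- cpp_sample3(moving@data, as.integer(shape), pts)
  miFromSamples(fv, mv, nBins, range(fixed@data), range(moving@data),
                parzen = FALSE)
}

#' Affine registration configuration
#'
#' @param dof degrees of freedom: "rigid" (rotation + translation),
#'   "rigid+scale", or "affine" (adds shear).
#' @param maxit maximum Nelder-Mead (Downhill Simplex) iterations.
#' @param tol relative convergence tolerance on the metric.
#' @param nBins mutual-information histogram bins.
#' @param sampleFrac fraction of voxels sampled for the metric.
#' @param seed metric sampling seed.
#' @return List of settings for \code{\link{registerAffine}}.
#' @export
affineConfig <- function(dof = "rigid+scale", maxit = 1000L, tol = 1e-7,
                         nBins = 32L, sampleFrac = 1, seed = 7L) {
  list(dof = dof, maxit = as.integer(maxit), tol = tol,
       nBins = as.integer(nBins), sampleFrac = sampleFrac,
       seed = as.integer(seed))
}

paramsToAffine <- function(p, dof) {
  t <- p[1:3]
  R <- rotationMatrix3(p[4:6])
  A <- R
  if (dof %in% c("rigid+scale", "affine")) A <- A %*% diag(exp(p[7:9]))
  if (dof == "affine") {
    K <- diag(3); K[1, 2] <- p[10]; K[1, 3] <- p[11]; K[2, 3] <- p[12]
    A <- A %*% K
  }
  list(A = A, t = t)
}

#' Affine registration by Downhill Simplex over mutual information
#'
#' Finds the affine map (fixed coordinates to moving coordinates,
#' \code{y = A (x - c) + c + t}) maximizing Mattes mutual information via
#' Nelder-Mead, after a moments (intensity-centroid) initialization of the
#' translation. The optimizer trace is kept for logging.
#'
#' @param fixed,moving \linkS4class{MRIVolume}s on the same grid.
#' @param config see \code{\link{affineConfig}}.
#' @return An \linkS4class{AffineTransform}; \code{converged = FALSE} marks
#'   a degenerate metric or an exhausted iteration budget.
#' @export
registerAffine <- function(fixed, moving, config = affineConfig()) {
  shape <- dim(fixed@data)
  spacing <- fixed@spacing
  center <- (shape - 1) * spacing / 2
  trace <- new.env()
  trace$rows <- list()
  if (stats::sd(moving@data) == 0 || stats::sd(fixed@data) == 0) {
    warning("constant image: mutual information metric is flat")
    return(new("AffineTransform", matrix = diag(3), translation = c(0, 0, 0),
               center = center, converged = FALSE,
               trace = data.frame(eval = integer(), metric = numeric())))
  }
  nSamples <- max(1000L, round(config$sampleFrac * prod(shape)))
  pts <- samplePoints(shape, nSamples, config$seed)
  fv <- cpp_sample3(fixed@data, as.integer(shape), pts)
  ptsMM <- pts * spacing  # 3 x n physical coordinates
  fRange <- range(fixed@data); mRange <- range(moving@data)

  # moments initialization: match bright-structure centroids
  q <- 0.9
  cf <- intensityCentroid(fixed@data, spacing,
                          stats::quantile(fixed@data, q, names = FALSE))
  cm <- intensityCentroid(moving@data, spacing,
                          stats::quantile(moving@data, q, names = FALSE))
  t0 <- if (anyNA(cf) || anyNA(cm)) c(0, 0, 0) else cm - cf

  nPar <- switch(config$dof, rigid = 6L, `rigid+scale` = 9L, affine = 12L)
  p0 <- c(t0, rep(0, nPar - 3))
  # soft inside-volume weight: fades linearly to 0 over the last voxel
  # before the boundary, keeping the overlap-weighted metric smooth in the
  # transform parameters
  softInside <- function(idx) {
    w <- rep(1, ncol(idx))
    for (a in 1:3) {
      d <- pmin(idx[a, ], (shape[a] - 1) - idx[a, ])
      w <- w * pmin(1, pmax(0, d + 1))
    }
    w
  }
  nCoarse <- min(7000L, ncol(pts))
  makeObjective <- function(sel) {
    pm <- ptsMM[, sel, drop = FALSE]
    fvs <- fv[sel]
    function(p) {
      pa <- paramsToAffine(p, config$dof)
      y <- pa$A %*% (pm - center) + center + pa$t
      yIdx <- y / spacing
      mv <- cpp_sample3(moving@data, as.integer(shape), yIdx)
      val <- tryCatch(miFromSamples(fvs, mv, config$nBins, fRange, mRange,
                                    overlapPenalty = TRUE,
                                    weights = softInside(yIdx)),
                      error = function(e) NA_real_)
      if (is.na(val)) val <- 0
      trace$rows[[length(trace$rows) + 1L]] <- val
      -val
    }
  }
  objCoarse <- makeObjective(seq_len(nCoarse))
  objective <- makeObjective(seq_len(ncol(pts)))
  parscale <- c(rep(4, 3), rep(0.08, 3),
                rep(0.04, max(0, nPar - 6)))[seq_len(nPar)]
  # coarse multi-start over in-plane rotation (the least identifiable
  # parameter from a zero init), then refine the best candidate
  starts <- lapply(c(0, -0.1, 0.1, -0.2, 0.2), function(dz) {
    p <- p0; p[6] <- p[6] + dz; p
  })
  coarse <- lapply(starts, function(p)
    stats::optim(p, objCoarse, method = "Nelder-Mead",
                 control = list(maxit = 200L, reltol = 1e-6,
                                parscale = parscale)))
  coarse <- lapply(coarse, function(o) {
    o$value <- objective(o$par); o
  })
  best <- which.min(vapply(coarse, `[[`, 0, "value"))
  opt <- stats::optim(coarse[[best]]$par, objective, method = "Nelder-Mead",
                      control = list(maxit = config$maxit,
                                     reltol = config$tol,
                                     parscale = parscale))
  # restarts re-inflate a collapsed simplex; a quasi-Newton polish then
  # exploits the smoothness of the Parzen-binned metric near the optimum
  for (r in 1:3) {
    opt2 <- stats::optim(opt$par, objective, method = "Nelder-Mead",
                         control = list(maxit = config$maxit,
                                        reltol = config$tol,
                                        parscale = parscale / 2^r))
    if (opt2$value >= opt$value - abs(opt$value) * 1e-6) { opt <- if
      (opt2$value < opt$value) opt2 else opt; break }
    opt <- opt2
  }
  opt3 <- tryCatch(
    stats::optim(opt$par, objective, method = "BFGS",
                 control = list(maxit = 100L, reltol = config$tol,
                                parscale = parscale)),
    error = function(e) NULL)
  if (!is.null(opt3) && opt3$value < opt$value) opt <- opt3
  pa <- paramsToAffine(opt$par, config$dof)
  new("AffineTransform", matrix = pa$A, translation = pa$t, center = center,
      converged = opt$convergence == 0,
      trace = data.frame(eval = seq_along(trace$rows),
                         metric = unlist(trace$rows)))
}

#' Demons registration configuration
#'
#' @param maxit maximum iterations (default 50).
#' @param tol relative RMS improvement below which iteration stops.
#' @param sigmaField Gaussian smoothing sd (mm) applied to the displacement
#'   field each iteration.
#' @param maxStep per-iteration displacement-update cap (voxels).
#' @return List of settings for \code{\link{registerDemons}}.
#' @export
demonsConfig <- function(maxit = 50L, tol = 1e-4, sigmaField = 4,
                         maxStep = 1, presmooth = 0) {
  list(maxit = as.integer(maxit), tol = tol, sigmaField = sigmaField,
       maxStep = maxStep, presmooth = presmooth)
}

#' Demons deformable registration
#'
#' Classic intensity-driven Demons: the displacement update at x is
#' \code{(m(x) - f(x)) grad f(x) / (|grad f(x)|^2 + (m(x) - f(x))^2)}, the
#' field is Gaussian-smoothed each iteration, and iteration stops when the
#' RMS intensity difference stops improving (steps that would increase it
#' are rejected) or the iteration cap is reached. Assumes the pair is
#' already affinely pre-aligned with comparable intensities (histogram
#' matched for cross-modality pairs).
#'
#' @param fixed,moving \linkS4class{MRIVolume}s on the same grid.
#' @param config see \code{\link{demonsConfig}}.
#' @return A \linkS4class{DeformationField} (displacements in mm on the
#'   fixed grid) with the per-iteration RMS trace.
#' @export
registerDemons <- function(fixed, moving, config = demonsConfig()) {
  shape <- dim(fixed@data)
  spacing <- fixed@spacing
  f <- fixed@data
  m <- moving@data
  if (!is.null(config$presmooth) && config$presmooth > 0) {
    # suppress fine structure one modality lacks: forces and the tracked
    # RMS are computed on a smoothed pair, the field applies to the originals
    ps <- config$presmooth / spacing
    f <- cpp_smooth3(f, as.integer(shape), ps)
    m <- cpp_smooth3(m, as.integer(shape), ps)
  }
  zero <- array(0, dim = c(shape, 3))
  gx <- gy <- gz <- array(0, dim = shape)
  gx[2:(shape[1] - 1), , ] <- (f[3:shape[1], , ] - f[1:(shape[1] - 2), , ]) / 2
  gy[, 2:(shape[2] - 1), ] <- (f[, 3:shape[2], ] - f[, 1:(shape[2] - 2), ]) / 2
  gz[, , 2:(shape[3] - 1)] <- (f[, , 3:shape[3]] - f[, , 1:(shape[3] - 2)]) / 2
  g2 <- gx^2 + gy^2 + gz^2
  if (all(g2 == 0)) {
    warning("zero image gradient everywhere: returning zero field")
    return(new("DeformationField", field = zero, spacing = spacing,
               trace = data.frame(iter = 0L, rms = rmsDifference(f, m)),
               converged = FALSE))
  }
  sigVox <- config$sigmaField / spacing
  disp <- zero  # voxel units, current iterate
  best <- zero  # best accepted field
  rmsBest <- rmsDifference(f, m)
  rmsTrace <- rmsBest
  converged <- FALSE
  stalled <- 0L
  for (it in seq_len(config$maxit)) {
    mw <- resampleDisplacement(m, disp)
    # intensity-difference force along the fixed-image gradient; the sign
    # matches our convention of sampling the moving image at x + u(x)
    d <- f - mw
    denom <- g2 + d^2
    scale <- ifelse(denom > 1e-12, d / denom, 0)
    ux <- scale * gx; uy <- scale * gy; uz <- scale * gz
    mag <- sqrt(ux^2 + uy^2 + uz^2)
    cap <- ifelse(mag > config$maxStep, config$maxStep / mag, 1)
    disp[, , , 1] <- cpp_smooth3(disp[, , , 1] + ux * cap,
                                 as.integer(shape), sigVox)
    disp[, , , 2] <- cpp_smooth3(disp[, , , 2] + uy * cap,
                                 as.integer(shape), sigVox)
    disp[, , , 3] <- cpp_smooth3(disp[, , , 3] + uz * cap,
                                 as.integer(shape), sigVox)
    rmsNew <- rmsDifference(f, resampleDisplacement(m, disp))
    if (rmsNew < rmsBest) {
      # accepted step: the returned field and its trace are monotone
      improved <- (rmsBest - rmsNew) / max(rmsBest, 1e-12)
      rmsBest <- rmsNew
      best <- disp
      rmsTrace <- c(rmsTrace, rmsNew)
      stalled <- 0L
      if (improved < config$tol) { converged <- TRUE; break }
    } else {
      # non-improving exploratory step; give up after a few in a row
      stalled <- stalled + 1L
      if (stalled >= 5L) { converged <- TRUE; break }
    }
  }
  fieldMM <- best
  for (a in 1:3) fieldMM[, , , a] <- disp[, , , a] * spacing[a]
  new("DeformationField", field = fieldMM, spacing = spacing,
      trace = data.frame(iter = seq_along(rmsTrace) - 1L, rms = rmsTrace),
      converged = converged)
}

# Resample a volume through affine-then-demons: sampling point for fixed
# voxel x is  Aff(x + u(x))  with u the demons field (mm, fixed grid).
applyAlignment <- function(vol, spacing, affine, field = NULL, fill = 0,
                           clipZero = FALSE) {
  shape <- dim(vol)
  P <- diag(spacing); Pinv <- diag(1 / spacing)
  M <- Pinv %*% affine@matrix %*% P
  off <- as.numeric(Pinv %*% (affine@center + affine@translation -
                                affine@matrix %*% affine@center))
  dispIdx <- NULL
  if (!is.null(field)) {
    dispIdx <- field
    for (a in 1:3) dispIdx[, , , a] <- field[, , , a] / spacing[a]
    dispIdx <- as.numeric(dispIdx)
  }
  # clamp at the volume edge: transforms near identity must not introduce
  # artificial zero borders into the aligned volumes
  out <- cpp_resample3(vol, as.integer(shape), M, off, dispIdx, fill, TRUE)
  if (clipZero) out[out < 0] <- 0
  out
}

#' Two-stage alignment of a study to its T2 frame
#'
#' Registers the b = 1200 DWI volume to the T2 reference (affine by mutual
#' information, then Demons on histogram-matched intensities) and applies
#' the composite transform identically to every DWI b-value volume and to
#' the ADC map, which share the DWI frame. RMS intensity differences
#' (against the histogram-matched T2 reference) are recorded before and
#' after.
#'
#' @param case a \linkS4class{StudyCase}.
#' @param affine config from \code{\link{affineConfig}}.
#' @param demons config from \code{\link{demonsConfig}}.
#' @return The aligned \linkS4class{StudyCase}; \code{x@meta$alignment}
#'   holds the transforms and the RMS report.
#' @export
alignStudy <- function(case, affine = affineConfig(),
                       demons = demonsConfig(maxit = 3L, sigmaField = 12)) {
  t2 <- case@t2
  moving <- dwiVolume(case, 1200)
  spacing <- t2@spacing
  rmsBefore <- rmsDifference(t2@data, matchHistogram(moving@data, t2@data))
  aff <- registerAffine(t2, moving, affine)
  movA <- MRIVolume(applyAlignment(moving@data, spacing, aff), spacing)
  matched <- MRIVolume(matchHistogram(movA@data, t2@data), spacing)
  dem <- registerDemons(t2, matched, demons)
  warp <- function(v, clip = FALSE)
    MRIVolume(applyAlignment(v@data, spacing, aff, dem@field,
                             clipZero = clip), spacing)
  dwi <- lapply(case@dwi, warp)
  adc <- warp(case@adc, clip = TRUE)
  rmsAfter <- rmsDifference(
    t2@data, matchHistogram(dwi[["1200"]]@data, t2@data))
  meta <- case@meta
  meta$alignment <- list(affine = aff, demons = dem,
                         rmsBefore = rmsBefore, rmsAfter = rmsAfter)
  initialize(case, dwi = dwi, adc = adc, aligned = TRUE, meta = meta)
}
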