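# 2-D correlation along one dimension with reflective boundary handling.
# Output position t gets sum_k h[k] * x[t + k - floor((L-1)/2)].
convolveReflect1d <- function(img, h, dim) {
  L <- length(h)
  off <- floor((L - 1) / 2)
  n <- base::dim(img)[dim]
  out <- array(0, base::dim(img))
  for (k in seq_len(L)) {
    idx <- seq_len(n) + (k - 1) - off
    idx <- ifelse(idx < 1, 2 - idx, idx)             # reflect left
    idx <- ifelse(idx > n, 2 * n - idx, idx)         # reflect right
    idx <- pmin(pmax(idx, 1), n)
    if (dim == 1) out <- out + h[k] * img[idx, , drop = FALSE]
    else out <- out + h[k] * img[, idx, drop = FALSE]
  }
  out
}

sepConvolve2d <- function(img, hRow, hCol) {
  convolveReflect1d(convolveReflect1d(img, hRow, 1), hCol, 2)
}

gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r):r)^2 / sigma^2)
  k / sum(k)
}

# Coiflet-1 decomposition filters (low-pass; high-pass by quadrature mirror).
coif1Lo <- c(-0.015655728135465, -0.072732619512854, 0.384864846864203,
             0.852572020212255, 0.337897662457809, -0.072732619512854)
waveletFilters <- function(type = c("coif1", "haar")) {
  type <- match.arg(type)
  lo <- switch(type, coif1 = coif1Lo, haar = c(1, 1) / sqrt(2))
  hi <- rev(lo) * (-1)^(seq_along(lo) - 1)
  list(lo = lo, hi = hi)
}

rescaleToRange <- function(y, target) {
  rngY <- range(y)
  if (diff(rngY) == 0) return(array(mean(target), dim(y)))
  (y - rngY[1]) / diff(rngY) * diff(range(target)) + min(target)
}

#' Filter bank configuration
#'
#' @param logSigmas Laplacian-of-Gaussian scales in mm.
#' @param wavelet wavelet family for the single-level stationary 2D
#'   transform ("coif1" or "haar").
#' @param expScale scaling constant c of the exponential filter
#'   \code{exp(c |x| / max|x|)}.
#' @return List of filter settings.
#' @export
filterBankConfig <- function(logSigmas = c(1, 2, 3), wavelet = "coif1",
                             expScale = 1) {
  list(logSigmas = logSigmas, wavelet = wavelet, expScale = expScale)
}

#' Apply the radiomic filter bank to one slice
#'
#' Produces the derived images feeding per-pixel features: the original
#' slice; the four single-level stationary wavelet subbands (LL/LH/HL/HH,
#' first letter = image rows); Laplacian-of-Gaussian responses at the
#' configured scales; square, square-root, logarithm and exponential
#' intensity transforms rescaled back to the original intensity range;
#' gradient magnitude; and local binary pattern codes (8 neighbours,
#' radius 1). Intensity transforms use absolute values with a +1 shift in
#' the logarithm, so zero-valued images never produce NaN.
#'
#' @param slice 2D numeric matrix.
#' @param mask 2D logical matrix (non-empty); defines the intensity range
#'   used for rescaling.
#' @param spacing in-plane pixel spacing in mm (length 2).
#' @param config see \code{\link{filterBankConfig}}.
#' @return Named list of derived images, each with the slice's shape.
#' @export
applyFilterBank <- function(slice, mask = NULL,
                            spacing = c(1, 1),
                            config = filterBankConfig()) {
  if (is.null(mask)) mask <- array(TRUE, dim(slice))
  if (!any(mask)) stop("mask is empty")
  rng <- range(slice[mask])
  out <- list(original = slice)

  wf <- waveletFilters(config$wavelet)
  out$wavelet_LL <- sepConvolve2d(slice, wf$lo, wf$lo)
  out$wavelet_LH <- sepConvolve2d(slice, wf$lo, wf$hi)
  out$wavelet_HL <- sepConvolve2d(slice, wf$hi, wf$lo)
  out$wavelet_HH <- sepConvolve2d(slice, wf$hi, wf$hi)

  for (s in config$logSigmas) {
    sm <- sepConvolve2d(slice, gaussKernel1d(s / spacing[1]),
                        gaussKernel1d(s / spacing[2]))
    lap <- (convolveReflect1d(sm, c(1, -2, 1), 1) / spacing[1]^2 +
              convolveReflect1d(sm, c(1, -2, 1), 2) / spacing[2]^2)
    out[[sprintf("LoG_%g", s)]] <- s^2 * lap
  }

  out$square <- rescaleToRange(slice^2, rng)
  out$squareroot <- rescaleToRange(sqrt(abs(slice)), rng)
  out$logarithm <- rescaleToRange(log(abs(slice) + 1), rng)
  mx <- max(abs(slice))
  ex <- if (mx > 0) exp(config$expScale * abs(slice) / mx) else
    array(1, dim(slice))
  out$exponential <- rescaleToRange(ex, rng)

  gx <- convolveReflect1d(slice, c(-0.5, 0, 0.5), 1) / spacing[1]
  gy <- convolveReflect1d(slice, c(-0.5, 0, 0.5), 2) / spacing[2]
  out$gradient <- sqrt(gx^2 + gy^2)

  out$lbp <- lbpCodes(slice)
  out
}

# Local binary pattern codes: 8 neighbours at radius 1, reflect boundary;
# bit k set when neighbour >= centre.
lbpCodes <- function(slice) {
  nr <- nrow(slice); nc <- ncol(slice)
  refl <- function(i, n) pmin(pmax(ifelse(i < 1, 2 - i, ifelse(i > n, 2 * n - i, i)), 1), n)
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- array(0, dim(slice))
  for (k in seq_along(offs)) {
    ri <- refl(seq_len(nr) + offs[[k]][1], nr)
    ci <- refl(seq_len(nc) + offs[[k]][2], nc)
    code <- code + 2^(k - 1) * (slice[ri, ci, drop = FALSE] >= slice)
  }
  code
}

#' Equal-width gray-level discretization
#'
#' Bins masked intensities into levels 1..nBins with half-open equal-width
#' bins over the masked range (the top value falls in the last bin); pixels
#' outside the mask get level 0. A constant region maps entirely to level 1.
#'
#' @param image 2D numeric matrix.
#' @param mask 2D logical matrix.
#' @param nBins number of gray levels (>= 2).
#' @return Integer matrix of levels, 0 outside the mask.
#' @export
discretizeImage <- function(image, mask = NULL, nBins = 32L) {
  if (nBins < 2) stop("nBins must be >= 2")
  if (is.null(mask)) mask <- array(TRUE, dim(image))
  if (!any(mask)) stop("mask is empty")
  v <- image[mask]
  rng <- range(v)
  lev <- if (diff(rng) == 0) rep(1L, length(v)) else
    pmin(as.integer(floor((v - rng[1]) / diff(rng) * nBins)) + 1L,
         as.integer(nBins))
  out <- array(0L, dim(image))
  out[mask] <- lev
  out
}
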