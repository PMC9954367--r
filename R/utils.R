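# Internal helpers shared across modules.

# Derive a child seed from a master seed and a stream index; stays below
# 2^31 so it is always a valid R integer.
deriveSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %%
               2147483629)
}

# Spatially correlated Gaussian random field: white noise smoothed with a
# Gaussian of the given correlation length (mm), rescaled to unit sd.
smoothNoiseField <- function(shape, spacing, scale_mm) {
  x <- array(stats::rnorm(prod(shape)), dim = shape)
  if (scale_mm > 0) {
    sig <- scale_mm / spacing
    x <- cpp_smooth3(x, as.integer(shape), sig)
    s <- stats::sd(x)
    if (s > 0) x <- x / s
  }
  x
}

# Voxel-centre physical coordinates (mm) along each axis, origin at voxel 1.
axisCoords <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - 1) * spacing[a])
}

# Rotation matrix from Euler angles (radians), applied as Rz %*% Ry %*% Rx.
rotationMatrix3 <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Resample a volume through a map given in physical mm coordinates,
#   y(x) = A (x - c) + c + t + u(x),
# where u is an optional dense displacement field on the output grid (mm,
# array of dim c(shape, 3)). The volume is sampled at y; points falling
# outside the grid get `fill`.
resampleAffine <- function(vol, spacing, A, center, translation,
                           disp_mm = NULL, fill = 0) {
  shp <- dim(vol)
  P <- diag(spacing)
  Pinv <- diag(1 / spacing)
  # in voxel indices: idx_y = M idx + off + Pinv u, with
  M <- Pinv %*% A %*% P
  off <- as.numeric(Pinv %*% (center + translation - A %*% center))
  if (is.null(disp_mm)) {
    cpp_resample3(vol, as.integer(shp), M, off, NULL, fill)
  } else {
    # the C++ kernel samples at M (idx + d) + off, so fold u in via
    # d = M^{-1} Pinv u
    dv <- matrix(disp_mm, ncol = 3) %*% t(solve(M) %*% Pinv)
    cpp_resample3(vol, as.integer(shp), M, off,
                  as.numeric(array(dv, dim = c(shp, 3))), fill)
  }
}

# Apply a voxel-space displacement field (fixed grid -> moving voxel offset)
# directly: samples input at x + d(x).
resampleDisplacement <- function(vol, disp_vox) {
  shp <- dim(vol)
  # clamp to the volume edge: small displacements at border voxels must not
  # fall off the grid
  cpp_resample3(vol, as.integer(shp), diag(3), c(0, 0, 0),
                as.numeric(disp_vox), 0, TRUE)
}

# Intensity centroid (mm) of a volume, optionally above a threshold.
intensityCentroid <- function(vol, spacing, thresh = NULL) {
  w <- vol
  if (!is.null(thresh)) w <- pmax(vol - thresh, 0)
  shp <- dim(vol)
  cs <- axisCoords(shp, spacing)
  tot <- sum(w)
  if (tot <= 0) return(c(NA_real_, NA_real_, NA_real_))
  c(sum(apply(w, 1, sum) * cs[[1]]),
    sum(apply(w, 2, sum) * cs[[2]]),
    sum(apply(w, 3, sum) * cs[[3]])) / tot
}
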