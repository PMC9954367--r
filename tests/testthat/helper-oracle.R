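# Independent brute-force oracles for the texture and first-order features.
# Everything here is written with plain scalar loops directly from the
# feature definitions, sharing no code with the package implementation.
# Input images are integer level matrices (1..ng inside the region, 0
# outside), matching the package's discretization output.

oLog2 <- function(x) if (x > 0) log2(x) else 0

# ---- GLCM ------------------------------------------------------------------
oracleGlcmCounts <- function(lv, dr, dc, ng) {
  C <- matrix(0, ng, ng)
  for (r in seq_len(nrow(lv))) for (c in seq_len(ncol(lv))) {
    i <- lv[r, c]
    if (i == 0) next
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nrow(lv) || c2 < 1 || c2 > ncol(lv)) next
    j <- lv[r2, c2]
    if (j == 0) next
    C[i, j] <- C[i, j] + 1
    C[j, i] <- C[j, i] + 1
  }
  C
}

oracleGlcmFeaturesOne <- function(C, ng) {
  P <- C / sum(C)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx2 <- 0; sy2 <- 0
  for (i in 1:ng) { sx2 <- sx2 + (i - mux)^2 * px[i]
                    sy2 <- sy2 + (i - muy)^2 * py[i] }
  pSum <- numeric(2 * ng); pDiff <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    pSum[i + j] <- pSum[i + j] + P[i, j]
    pDiff[abs(i - j) + 1] <- pDiff[abs(i - j) + 1] + P[i, j]
  }
  acc <- 0; cp <- 0; cs <- 0; ct <- 0; ctr <- 0; idf <- 0; idm <- 0
  idmn <- 0; idn <- 0; je <- 0; hxy <- 0; iv <- 0; ss <- 0; corrNum <- 0
  for (i in 1:ng) for (j in 1:ng) {
    p <- P[i, j]
    acc <- acc + p * i * j
    cp <- cp + (i + j - mux - muy)^4 * p
    cs <- cs + (i + j - mux - muy)^3 * p
    ct <- ct + (i + j - mux - muy)^2 * p
    ctr <- ctr + (i - j)^2 * p
    idf <- idf + p / (1 + abs(i - j))
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + (i - j)^2 / ng^2)
    idn <- idn + p / (1 + abs(i - j) / ng)
    je <- je + p^2
    hxy <- hxy - p * oLog2(p)
    if (i != j) iv <- iv + p / (i - j)^2
    ss <- ss + (i - mux)^2 * p
    corrNum <- corrNum + p * i * j
  }
  hx <- 0; hy <- 0
  for (i in 1:ng) { hx <- hx - px[i] * oLog2(px[i])
                    hy <- hy - py[i] * oLog2(py[i]) }
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    q <- px[i] * py[j]
    hxy1 <- hxy1 - P[i, j] * oLog2(q)
    hxy2 <- hxy2 - q * oLog2(q)
  }
  da <- 0
  for (k in 0:(ng - 1)) da <- da + k * pDiff[k + 1]
  dv <- 0; de <- 0
  for (k in 0:(ng - 1)) {
    dv <- dv + (k - da)^2 * pDiff[k + 1]
    de <- de - pDiff[k + 1] * oLog2(pDiff[k + 1])
  }
  sa <- 0; se <- 0
  for (k in 2:(2 * ng)) {
    sa <- sa + k * pSum[k]
    se <- se - pSum[k] * oLog2(pSum[k])
  }
  occ <- which(px > 0)
  mcc <- if (length(occ) < 2) 1 else {
    Q <- matrix(0, length(occ), length(occ))
    for (a in seq_along(occ)) for (b in seq_along(occ)) {
      s <- 0
      for (k in seq_along(occ))
        s <- s + P[occ[a], occ[k]] * P[occ[b], occ[k]] /
          (px[occ[a]] * py[occ[k]])
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  corr <- if (sx2 > 0 && sy2 > 0)
    (corrNum - mux * muy) / sqrt(sx2 * sy2) else 1
  c(Autocorrelation = acc, ClusterProminence = cp, ClusterShade = cs,
    ClusterTendency = ct, Contrast = ctr, Correlation = corr,
    DifferenceAverage = da, DifferenceEntropy = de, DifferenceVariance = dv,
    Id = idf, Idm = idm, Idmn = idmn, Idn = idn,
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = iv, JointAverage = mux, JointEnergy = je,
    JointEntropy = hxy, MaximumProbability = max(P), MCC = mcc,
    SumAverage = sa, SumEntropy = se, SumSquares = ss)
}

oracleGlcmFeatures <- function(lv, ng, offsets = list(c(0, 1), c(-1, 1),
                                                     c(-1, 0), c(-1, -1))) {
  per <- list()
  for (o in offsets) {
    C <- oracleGlcmCounts(lv, o[1], o[2], ng)
    if (sum(C) > 0) per[[length(per) + 1]] <- oracleGlcmFeaturesOne(C, ng)
  }
  Reduce(`+`, per) / length(per)
}

# ---- run/zone shared formulas ---------------------------------------------
oracleRunZoneFeatures <- function(P, np) {
  Ns <- sum(P)
  ng <- nrow(P); nl <- ncol(P)
  se <- le <- gln <- rln <- lgl <- hgl <- sl <- sh <- ll <- lh <- 0
  mug <- 0; mus <- 0; gv <- 0; svv <- 0; ent <- 0
  for (i in 1:ng) for (j in 1:nl) {
    p <- P[i, j] / Ns
    se <- se + P[i, j] / j^2
    le <- le + P[i, j] * j^2
    lgl <- lgl + P[i, j] / i^2
    hgl <- hgl + P[i, j] * i^2
    sl <- sl + P[i, j] / (i^2 * j^2)
    sh <- sh + P[i, j] * i^2 / j^2
    ll <- ll + P[i, j] * j^2 / i^2
    lh <- lh + P[i, j] * i^2 * j^2
    mug <- mug + i * p
    mus <- mus + j * p
    ent <- ent - p * oLog2(p)
  }
  for (i in 1:ng) gln <- gln + sum(P[i, ])^2
  for (j in 1:nl) rln <- rln + sum(P[, j])^2
  for (i in 1:ng) for (j in 1:nl) {
    p <- P[i, j] / Ns
    gv <- gv + (i - mug)^2 * p
    svv <- svv + (j - mus)^2 * p
  }
  c(se / Ns, le / Ns, gln / Ns, gln / Ns^2, rln / Ns, rln / Ns^2,
    Ns / np, gv, svv, ent, lgl / Ns, hgl / Ns, sl / Ns, sh / Ns,
    ll / Ns, lh / Ns)
}

# ---- GLRLM -----------------------------------------------------------------
oracleRunCounts <- function(lv, dr, dc, ng) {
  maxlen <- max(dim(lv))
  R <- matrix(0, ng, maxlen)
  nr <- nrow(lv); nc <- ncol(lv)
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    rp <- r0 - dr; cp <- c0 - dc
    if (rp >= 1 && rp <= nr && cp >= 1 && cp <= nc) next  # not a line start
    r <- r0; c <- c0; cur <- 0; len <- 0
    while (r >= 1 && r <= nr && c >= 1 && c <= nc) {
      v <- lv[r, c]
      if (v == cur && v > 0) len <- len + 1
      else {
        if (cur > 0) R[cur, len] <- R[cur, len] + 1
        cur <- v; len <- if (v > 0) 1 else 0
      }
      r <- r + dr; c <- c + dc
    }
    if (cur > 0) R[cur, len] <- R[cur, len] + 1
  }
  R
}

oracleGlrlmFeatures <- function(lv, ng,
                                dirs = list(c(0, 1), c(1, 0), c(1, 1),
                                            c(1, -1))) {
  np <- sum(lv > 0)
  per <- list()
  for (d in dirs) {
    R <- oracleRunCounts(lv, d[1], d[2], ng)
    if (sum(R) > 0)
      per[[length(per) + 1]] <- oracleRunZoneFeatures(R, np)
  }
  Reduce(`+`, per) / length(per)
}

# ---- GLSZM -----------------------------------------------------------------
oracleZoneCounts <- function(lv, ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (lv[r, c] == 0 || seen[r, c]) next
    lev <- lv[r, c]
    stack <- list(c(r, c)); seen[r, c] <- TRUE; size <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (a in -1:1) for (b in -1:1) {
        if (a == 0 && b == 0) next
        r2 <- p[1] + a; c2 <- p[2] + b
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (!seen[r2, c2] && lv[r2, c2] == lev) {
          seen[r2, c2] <- TRUE
          stack[[length(stack) + 1]] <- c(r2, c2)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(lev, size)
  }
  maxsz <- max(vapply(zones, `[`, 0, 2))
  Z <- matrix(0, ng, maxsz)
  for (z in zones) Z[z[1], z[2]] <- Z[z[1], z[2]] + 1
  Z
}

oracleGlszmFeatures <- function(lv, ng) {
  oracleRunZoneFeatures(oracleZoneCounts(lv, ng), sum(lv > 0))
}

# ---- GLDM ------------------------------------------------------------------
oracleGldmFeatures <- function(lv, ng, alpha = 0) {
  nr <- nrow(lv); nc <- ncol(lv)
  D <- matrix(0, ng, 10)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    i <- lv[r, c]
    if (i == 0) next
    dep <- 1
    for (a in -1:1) for (b in -1:1) {
      if (a == 0 && b == 0) next
      r2 <- r + a; c2 <- c + b
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      j <- lv[r2, c2]
      if (j > 0 && abs(i - j) <= alpha) dep <- dep + 1
    }
    D[i, dep] <- D[i, dep] + 1
  }
  Nz <- sum(D)
  sde <- lde <- gln <- dn <- lgl <- hgl <- sdl <- sdh <- ldl <- ldh <- 0
  mug <- mud <- gv <- dv <- ent <- 0
  for (i in 1:ng) for (j in 1:10) {
    p <- D[i, j] / Nz
    sde <- sde + D[i, j] / j^2
    lde <- lde + D[i, j] * j^2
    lgl <- lgl + D[i, j] / i^2
    hgl <- hgl + D[i, j] * i^2
    sdl <- sdl + D[i, j] / (i^2 * j^2)
    sdh <- sdh + D[i, j] * i^2 / j^2
    ldl <- ldl + D[i, j] * j^2 / i^2
    ldh <- ldh + D[i, j] * i^2 * j^2
    mug <- mug + i * p
    mud <- mud + j * p
    ent <- ent - p * oLog2(p)
  }
  for (i in 1:ng) gln <- gln + sum(D[i, ])^2
  for (j in 1:10) dn <- dn + sum(D[, j])^2
  for (i in 1:ng) for (j in 1:10) {
    p <- D[i, j] / Nz
    gv <- gv + (i - mug)^2 * p
    dv <- dv + (j - mud)^2 * p
  }
  c(SmallDependenceEmphasis = sde / Nz, LargeDependenceEmphasis = lde / Nz,
    GrayLevelNonUniformity = gln / Nz, DependenceNonUniformity = dn / Nz,
    DependenceNonUniformityNormalized = dn / Nz^2,
    GrayLevelVariance = gv, DependenceVariance = dv,
    DependenceEntropy = ent,
    LowGrayLevelEmphasis = lgl / Nz, HighGrayLevelEmphasis = hgl / Nz,
    SmallDependenceLowGrayLevelEmphasis = sdl / Nz,
    SmallDependenceHighGrayLevelEmphasis = sdh / Nz,
    LargeDependenceLowGrayLevelEmphasis = ldl / Nz,
    LargeDependenceHighGrayLevelEmphasis = ldh / Nz)
}

# ---- NGTDM -----------------------------------------------------------------
oracleNgtdmFeatures <- function(lv, ng) {
  nr <- nrow(lv); nc <- ncol(lv)
  n <- numeric(ng); s <- numeric(ng)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    i <- lv[r, c]
    if (i == 0) next
    tot <- 0; cnt <- 0
    for (a in -1:1) for (b in -1:1) {
      if (a == 0 && b == 0) next
      r2 <- r + a; c2 <- c + b
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      j <- lv[r2, c2]
      if (j > 0) { tot <- tot + j; cnt <- cnt + 1 }
    }
    if (cnt == 0) next
    n[i] <- n[i] + 1
    s[i] <- s[i] + abs(i - tot / cnt)
  }
  Np <- sum(n)
  p <- n / Np
  act <- which(p > 0)
  ngp <- length(act)
  ps <- sum(p * s)
  contrast <- 0
  if (ngp > 1) {
    acc <- 0
    for (i in act) for (j in act) acc <- acc + p[i] * p[j] * (i - j)^2
    contrast <- acc / (ngp * (ngp - 1)) * sum(s) / Np
  }
  den <- 0
  for (i in act) for (j in act) den <- den + abs(i * p[i] - j * p[j])
  busy <- if (den > 0) ps / den else 0
  comp <- 0
  for (i in act) for (j in act)
    comp <- comp + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
  comp <- comp / Np
  stren <- 0
  if (sum(s) > 0 && ngp > 1) {
    acc <- 0
    for (i in act) for (j in act) acc <- acc + (p[i] + p[j]) * (i - j)^2
    stren <- acc / sum(s)
  }
  c(Coarseness = 1 / (1e-6 + ps), Contrast = contrast, Busyness = busy,
    Complexity = comp, Strength = stren)
}

# ---- first order -----------------------------------------------------------
oracleFirstOrder <- function(v, nBins = 32, pixelArea = 1) {
  n <- length(v)
  mn <- min(v); mx <- max(v)
  lev <- if (mx == mn) rep(1, n) else
    pmin(floor((v - mn) / (mx - mn) * nBins) + 1, nBins)
  p <- numeric(nBins)
  for (l in lev) p[l] <- p[l] + 1 / n
  mu <- sum(v) / n
  m2 <- sum((v - mu)^2) / n
  m3 <- sum((v - mu)^3) / n
  m4 <- sum((v - mu)^4) / n
  q <- stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  inner <- v[v >= q[1] & v <= q[5]]
  ent <- 0
  for (pp in p) ent <- ent - pp * oLog2(pp)
  c(Energy = sum(v^2), TotalEnergy = pixelArea * sum(v^2), Entropy = ent,
    Minimum = mn, Percentile10 = q[1], Percentile90 = q[5], Maximum = mx,
    Mean = mu, Median = q[3], InterquartileRange = q[4] - q[2],
    Range = mx - mn,
    MeanAbsoluteDeviation = sum(abs(v - mu)) / n,
    RobustMeanAbsoluteDeviation = mean(abs(inner - mean(inner))),
    RootMeanSquared = sqrt(sum(v^2) / n),
    StandardDeviation = sqrt(m2),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2, Uniformity = sum(p^2))
}

# random test region: integer levels 1..ng with optional masked-out pixels
randomLevelImage <- function(nr, nc, ng, maskFrac = 0.2) {
  lv <- matrix(sample.int(ng, nr * nc, replace = TRUE), nr, nc)
  if (maskFrac > 0)
    lv[stats::runif(nr * nc) < maskFrac] <- 0L
  if (all(lv == 0)) lv[1, 1] <- 1L
  storage.mode(lv) <- "integer"
  lv
}
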