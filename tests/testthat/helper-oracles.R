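# Independent brute-force oracles for the texture-matrix families.
# Everything here enumerates voxel pairs / runs / zones / neighborhoods
# with plain loops and computes features with naive elementwise sums -- a
# deliberately separate code path from the package's C++ builders and
# vectorized formulas.

oracle_offsets <- function() {
  out <- list()
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    if (dz > 0 || (dz == 0 && dy > 0) || (dz == 0 && dy == 0 && dx > 0)) {
      out[[length(out) + 1]] <- c(dx, dy, dz)
    }
  }
  do.call(rbind, out)
}

in_bounds <- function(p, d) all(p >= 1) && all(p <= d)

oracle_glcm_matrix <- function(lev, off, nl) {
  d <- dim(lev)
  m <- matrix(0, nl, nl)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    a <- lev[x, y, z]
    if (a == 0) next
    q <- c(x, y, z) + off
    if (!in_bounds(q, d)) next
    b <- lev[q[1], q[2], q[3]]
    if (b == 0) next
    m[a, b] <- m[a, b] + 1
    m[b, a] <- m[b, a] + 1
  }
  m
}

oracle_glcm_features <- function(lev, nl = max(lev)) {
  offs <- oracle_offsets()
  acc <- NULL
  nd <- 0
  for (k in seq_len(nrow(offs))) {
    cnt <- oracle_glcm_matrix(lev, offs[k, ], nl)
    if (sum(cnt) == 0) next
    p <- cnt / sum(cnt)
    f <- oracle_glcm_from_p(p)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1
  }
  acc / nd
}

oracle_glcm_from_p <- function(p) {
  ng <- nrow(p)
  px <- py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mux <- muy <- 0
  for (i in 1:ng) {
    mux <- mux + i * px[i]
    muy <- muy + i * py[i]
  }
  sigx2 <- sigy2 <- 0
  for (i in 1:ng) {
    sigx2 <- sigx2 + (i - mux)^2 * px[i]
    sigy2 <- sigy2 + (i - muy)^2 * py[i]
  }
  psum <- numeric(2 * ng)
  pdif <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  ac <- cp <- cs <- ct <- ctr <- ja <- je <- sumsq <- 0
  hxy <- hxy1 <- hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    ac <- ac + i * j * p[i, j]
    cc <- i + j - mux - muy
    cp <- cp + cc^4 * p[i, j]
    cs <- cs + cc^3 * p[i, j]
    ct <- ct + cc^2 * p[i, j]
    ctr <- ctr + (i - j)^2 * p[i, j]
    ja <- ja + i * p[i, j]
    je <- je + p[i, j]^2
    sumsq <- sumsq + (i - mux)^2 * p[i, j]
    if (p[i, j] > 0) {
      hxy <- hxy - p[i, j] * log2(p[i, j])
      if (px[i] * py[j] > 0) {
        hxy1 <- hxy1 - p[i, j] * log2(px[i] * py[j])
      }
    }
    if (px[i] * py[j] > 0) {
      hxy2 <- hxy2 - px[i] * py[j] * log2(px[i] * py[j])
    }
  }
  corr <- if (sigx2 > 0 && sigy2 > 0) {
    (ac - mux * muy) / sqrt(sigx2 * sigy2)
  } else 1
  da <- de <- dv <- id <- idm <- idmn <- idn <- iv <- 0
  for (k in 0:(ng - 1)) {
    pk <- pdif[k + 1]
    da <- da + k * pk
    if (pk > 0) de <- de - pk * log2(pk)
    id <- id + pk / (1 + k)
    idm <- idm + pk / (1 + k^2)
    idmn <- idmn + pk / (1 + (k / ng)^2)
    idn <- idn + pk / (1 + k / ng)
    if (k >= 1) iv <- iv + pk / k^2
  }
  for (k in 0:(ng - 1)) dv <- dv + (k - da)^2 * pdif[k + 1]
  hx <- 0
  for (i in 1:ng) if (px[i] > 0) hx <- hx - px[i] * log2(px[i])
  hy <- 0
  for (j in 1:ng) if (py[j] > 0) hy <- hy - py[j] * log2(py[j])
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  se <- sa <- 0
  for (k in 2:(2 * ng)) {
    sa <- sa + k * psum[k]
    if (psum[k] > 0) se <- se - psum[k] * log2(psum[k])
  }
  keep <- which(px > 0)
  mcc <- if (length(keep) < 2) 1 else {
    q <- matrix(0, length(keep), length(keep))
    for (ii in seq_along(keep)) for (jj in seq_along(keep)) {
      for (kk in seq_along(keep)) {
        q[ii, jj] <- q[ii, jj] +
          p[keep[ii], keep[kk]] * p[keep[jj], keep[kk]] /
          (px[keep[ii]] * py[keep[kk]])
      }
    }
    ev <- sort(Re(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  c(Autocorrelation = ac, ClusterProminence = cp, ClusterShade = cs,
    ClusterTendency = ct, Contrast = ctr, Correlation = corr,
    DifferenceAverage = da, DifferenceEntropy = de, DifferenceVariance = dv,
    Id = id, Idm = idm, Idmn = idmn, Idn = idn, Imc1 = imc1, Imc2 = imc2,
    InverseVariance = iv, JointAverage = mux, JointEnergy = je,
    JointEntropy = hxy, MCC = mcc, MaximumProbability = max(p),
    SumAverage = sa, SumEntropy = se, SumSquares = sumsq)
}

oracle_runs <- function(lev, off) {
  d <- dim(lev)
  runs <- list()
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    a <- lev[x, y, z]
    if (a == 0) next
    prev <- c(x, y, z) - off
    if (in_bounds(prev, d) && lev[prev[1], prev[2], prev[3]] == a) next
    len <- 1
    nxt <- c(x, y, z) + off
    while (in_bounds(nxt, d) && lev[nxt[1], nxt[2], nxt[3]] == a) {
      len <- len + 1
      nxt <- nxt + off
    }
    runs[[length(runs) + 1]] <- c(a, len)
  }
  do.call(rbind, runs)
}

oracle_glrlm_features <- function(lev, nl = max(lev)) {
  offs <- oracle_offsets()
  acc <- NULL
  for (k in seq_len(nrow(offs))) {
    rr <- oracle_runs(lev, offs[k, ])
    f <- oracle_rlm_from_runs(rr[, 1], rr[, 2])
    acc <- if (is.null(acc)) f else acc + f
  }
  acc / nrow(offs)
}

oracle_rlm_from_runs <- function(gl, rl) {
  nr <- length(gl)
  np <- sum(rl)
  sre <- mean(1 / rl^2)
  lre <- mean(rl^2)
  gln <- sum(table(gl)^2) / nr
  rln <- sum(table(rl)^2) / nr
  glv <- mean((gl - mean(gl))^2)
  rv <- mean((rl - mean(rl))^2)
  cell <- table(paste(gl, rl)) / nr
  re <- -sum(cell * log2(cell))
  c(ShortRunEmphasis = sre, LongRunEmphasis = lre,
    GrayLevelNonUniformity = gln, GrayLevelNonUniformityNormalized = gln / nr,
    RunLengthNonUniformity = rln,
    RunLengthNonUniformityNormalized = rln / nr,
    RunPercentage = nr / np, GrayLevelVariance = glv, RunVariance = rv,
    RunEntropy = re,
    LowGrayLevelRunEmphasis = mean(1 / gl^2),
    HighGrayLevelRunEmphasis = mean(gl^2),
    ShortRunLowGrayLevelEmphasis = mean(1 / (gl^2 * rl^2)),
    ShortRunHighGrayLevelEmphasis = mean(gl^2 / rl^2),
    LongRunLowGrayLevelEmphasis = mean(rl^2 / gl^2),
    LongRunHighGrayLevelEmphasis = mean(gl^2 * rl^2))
}

# recursive flood fill over the 26-neighborhood
oracle_zones <- function(lev) {
  d <- dim(lev)
  seen <- array(FALSE, dim = d)
  zones <- list()
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (seen[x, y, z] || lev[x, y, z] == 0) next
    a <- lev[x, y, z]
    frontier <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    size <- 0
    while (length(frontier) > 0) {
      p <- frontier[[length(frontier)]]
      frontier[[length(frontier)]] <- NULL
      size <- size + 1
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        q <- p + c(dx, dy, dz)
        if (!in_bounds(q, d)) next
        if (!seen[q[1], q[2], q[3]] && lev[q[1], q[2], q[3]] == a) {
          seen[q[1], q[2], q[3]] <- TRUE
          frontier[[length(frontier) + 1]] <- q
        }
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  do.call(rbind, zones)
}

oracle_glszm_features <- function(lev) {
  zz <- oracle_zones(lev)
  gl <- zz[, 1]
  sz <- zz[, 2]
  nz <- length(gl)
  np <- sum(sz)
  cell <- table(paste(gl, sz)) / nz
  c(SmallAreaEmphasis = mean(1 / sz^2), LargeAreaEmphasis = mean(sz^2),
    GrayLevelNonUniformity = sum(table(gl)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(table(gl)^2) / nz^2,
    SizeZoneNonUniformity = sum(table(sz)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(table(sz)^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = mean((gl - mean(gl))^2),
    ZoneVariance = mean((sz - mean(sz))^2),
    ZoneEntropy = -sum(cell * log2(cell)),
    LowGrayLevelZoneEmphasis = mean(1 / gl^2),
    HighGrayLevelZoneEmphasis = mean(gl^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (gl^2 * sz^2)),
    SmallAreaHighGrayLevelEmphasis = mean(gl^2 / sz^2),
    LargeAreaLowGrayLevelEmphasis = mean(sz^2 / gl^2),
    LargeAreaHighGrayLevelEmphasis = mean(gl^2 * sz^2))
}

oracle_dependences <- function(lev, alpha = 0) {
  d <- dim(lev)
  out <- list()
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    a <- lev[x, y, z]
    if (a == 0) next
    dep <- 1
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!in_bounds(q, d)) next
      b <- lev[q[1], q[2], q[3]]
      if (b != 0 && abs(b - a) <= alpha) dep <- dep + 1
    }
    out[[length(out) + 1]] <- c(a, dep)
  }
  do.call(rbind, out)
}

oracle_gldm_features <- function(lev, alpha = 0) {
  dd <- oracle_dependences(lev, alpha)
  gl <- dd[, 1]
  dp <- dd[, 2]
  nz <- length(gl)
  cell <- table(paste(gl, dp)) / nz
  c(SmallDependenceEmphasis = mean(1 / dp^2),
    LargeDependenceEmphasis = mean(dp^2),
    GrayLevelNonUniformity = sum(table(gl)^2) / nz,
    DependenceNonUniformity = sum(table(dp)^2) / nz,
    DependenceNonUniformityNormalized = sum(table(dp)^2) / nz^2,
    GrayLevelVariance = mean((gl - mean(gl))^2),
    DependenceVariance = mean((dp - mean(dp))^2),
    DependenceEntropy = -sum(cell * log2(cell)),
    LowGrayLevelEmphasis = mean(1 / gl^2),
    HighGrayLevelEmphasis = mean(gl^2),
    SmallDependenceLowGrayLevelEmphasis = mean(1 / (gl^2 * dp^2)),
    SmallDependenceHighGrayLevelEmphasis = mean(gl^2 / dp^2),
    LargeDependenceLowGrayLevelEmphasis = mean(dp^2 / gl^2),
    LargeDependenceHighGrayLevelEmphasis = mean(gl^2 * dp^2))
}

oracle_ngtdm_features <- function(lev, nl = max(lev)) {
  d <- dim(lev)
  ni <- si <- numeric(nl)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    a <- lev[x, y, z]
    if (a == 0) next
    vals <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      q <- c(x + dx, y + dy, z + dz)
      if (!in_bounds(q, d)) next
      b <- lev[q[1], q[2], q[3]]
      if (b != 0) vals <- c(vals, b)
    }
    if (length(vals) == 0) next
    ni[a] <- ni[a] + 1
    si[a] <- si[a] + abs(a - mean(vals))
  }
  nv <- sum(ni)
  p <- ni / nv
  act <- which(p > 0)
  ngp <- length(act)
  coars <- min(1 / max(sum(p * si), 1e-6), 1e6)
  contr <- 0
  if (ngp > 1) {
    for (i in act) for (j in act) contr <- contr + p[i] * p[j] * (i - j)^2
    contr <- contr / (ngp * (ngp - 1)) * sum(si) / nv
  }
  bden <- 0
  for (i in act) for (j in act) bden <- bden + abs(i * p[i] - j * p[j])
  busy <- if (bden > 1e-6) sum(p * si) / bden else 0
  cplx <- 0
  for (i in act) for (j in act) {
    cplx <- cplx + abs(i - j) * (p[i] * si[i] + p[j] * si[j]) / (p[i] + p[j])
  }
  cplx <- cplx / nv
  sden <- sum(si)
  stren <- 0
  if (sden > 1e-6) {
    for (i in act) for (j in act) stren <- stren + (p[i] + p[j]) * (i - j)^2
    stren <- stren / sden
  }
  c(Coarseness = coars, Contrast = contr, Busyness = busy,
    Complexity = cplx, Strength = stren)
}

# random level grid with optional random mask (0 = outside)
random_level_grid <- function(dims = c(6, 6, 6), nlev = 4,
                              mask_frac = 1) {
  lev <- array(sample.int(nlev, prod(dims), replace = TRUE), dim = dims)
  if (mask_frac < 1) {
    drop <- runif(prod(dims)) > mask_frac
    lev[drop] <- 0L
  }
  storage.mode(lev) <- "integer"
  attr(lev, "nlevels") <- nlev
  lev
}

# naive separable correlation with half-sample symmetric boundary
oracle_conv_axis <- function(arr, taps, axis) {
  d <- dim(arr)
  n <- d[axis]
  L <- length(taps)
  off <- (L - 1) %/% 2
  refl <- function(i) {
    j <- (i - 1) %% (2 * n)
    ifelse(j < n, j + 1, 2 * n - j)
  }
  out <- array(0, dim = d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    s <- 0
    for (t in 1:L) {
      p <- c(x, y, z)
      p[axis] <- refl(p[axis] + t - 1 - off)
      s <- s + taps[t] * arr[p[1], p[2], p[3]]
    }
    out[x, y, z] <- s
  }
  out
}

sphere_mask <- function(radius_mm, spacing_mm, margin_vox = 2) {
  dims <- as.integer(ceiling(2 * radius_mm / spacing_mm) + 2 * margin_vox + 1)
  ctr <- (dims - 1) / 2 * spacing_mm
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  r2 <- ((g$x - 1) * spacing_mm[1] - ctr[1])^2 +
    ((g$y - 1) * spacing_mm[2] - ctr[2])^2 +
    ((g$z - 1) * spacing_mm[3] - ctr[3])^2
  segmentation_mask(array(r2 <= radius_mm^2, dim = dims), spacing_mm)
}

all_feature_oracles <- function(lev) {
  list(glcm = oracle_glcm_features(lev),
       glrlm = oracle_glrlm_features(lev),
       glszm = oracle_glszm_features(lev),
       gldm = oracle_gldm_features(lev),
       ngtdm = oracle_ngtdm_features(lev))
}

all_feature_impls <- function(lev) {
  list(glcm = glcm_features(lev),
       glrlm = glrlm_features(lev),
       glszm = glszm_features(lev),
       gldm = gldm_features(lev),
       ngtdm = ngtdm_features(lev))
}
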