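# Texture-matrix feature families. Matrices are built in C++ over the 13
# unique direction offsets of the 26-neighborhood (GLCM/GLRLM) or the full
# 26-neighborhood (GLSZM zones, GLDM dependences, NGTDM tone differences);
# per-direction features are averaged. Gray levels arrive as an integer
# array with 0 outside the ROI (see discretize_roi).

EPS <- 1e-6

#' The 13 unique 3D direction offsets at distance 1
#'
#' One representative of each antipodal pair of the 26-neighborhood.
#' @return Integer matrix, 13 rows x 3 columns.
#' @export
direction_offsets_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  m <- g[keep, , drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

levels_meta <- function(levels) {
  nl <- attr(levels, "nlevels") %||% max(levels)
  stop_if_not(nl >= 1, "empty ROI")
  list(nl = as.integer(nl), dims = as.integer(dim(levels)),
       flat = as.integer(levels))
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

glcm_single <- function(counts) {
  s <- sum(counts)
  p <- counts / s
  ng <- nrow(p)
  i <- seq_len(ng)
  px <- rowSums(p)
  py <- colSums(p)
  mux <- sum(i * px)
  muy <- sum(i * py)
  sigx <- sqrt(sum((i - mux)^2 * px))
  sigy <- sqrt(sum((i - muy)^2 * py))
  ii <- matrix(i, ng, ng)
  jj <- t(ii)
  # distributions of i+j (2..2Ng) and |i-j| (0..Ng-1)
  acc <- rowsum(as.vector(p), as.vector(ii + jj))
  psum <- numeric(2 * ng - 1)
  psum[as.integer(rownames(acc)) - 1L] <- acc
  kdif <- 0:(ng - 1)
  accd <- rowsum(as.vector(p), as.vector(abs(ii - jj)))
  pdif <- numeric(ng)
  pdif[as.integer(rownames(accd)) + 1L] <- accd
  hxy <- entropy2(p)
  hx <- entropy2(px)
  hy <- entropy2(py)
  pxy <- outer(px, py)
  sel <- p > 0 & pxy > 0
  hxy1 <- -sum(p[sel] * log2(pxy[sel]))
  hxy2 <- entropy2(pxy)
  da <- sum(kdif * pdif)
  corr <- if (sigx > 0 && sigy > 0) {
    (sum(ii * jj * p) - mux * muy) / (sigx * sigy)
  } else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  # MCC: Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), restricted to
  # occupied gray levels; sqrt of the second-largest eigenvalue.
  keep <- px > 0
  pk <- p[keep, keep, drop = FALSE]
  mcc <- if (nrow(pk) < 2) 1 else {
    A <- pk / rowSums(pk)
    B <- t(t(pk) / colSums(pk))
    ev <- sort(Re(eigen(A %*% t(B), only.values = TRUE)$values),
               decreasing = TRUE)
    sqrt(max(0, min(1, ev[2])))
  }
  cpm <- ii + jj - mux - muy
  c(Autocorrelation = sum(ii * jj * p),
    ClusterProminence = sum(cpm^4 * p),
    ClusterShade = sum(cpm^3 * p),
    ClusterTendency = sum(cpm^2 * p),
    Contrast = sum((ii - jj)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = entropy2(pdif),
    DifferenceVariance = sum((kdif - da)^2 * pdif),
    Id = sum(pdif / (1 + kdif)),
    Idm = sum(pdif / (1 + kdif^2)),
    Idmn = sum(pdif / (1 + (kdif / ng)^2)),
    Idn = sum(pdif / (1 + kdif / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = if (ng > 1) sum(pdif[-1] / kdif[-1]^2) else 0,
    JointAverage = mux,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(p),
    SumAverage = sum((2:(2 * ng)) * psum),
    SumEntropy = entropy2(psum),
    SumSquares = sum((ii - mux)^2 * p))
}

#' Gray-level co-occurrence matrix features
#'
#' Symmetrized, normalized co-occurrence of gray-level pairs at distance 1
#' over the 13 unique 3D directions; the 24 standard features are computed
#' per direction and averaged. With a single gray level, correlation-type
#' features are defined as 1 and difference-type features as 0 (no `NaN`s).
#'
#' @param levels integer gray-level array (0 outside the ROI), as produced
#'   by [discretize_roi()].
#' @param offsets direction offsets (rows); default [direction_offsets_3d()].
#' @return Named numeric vector of 24 features.
#' @export
glcm_features <- function(levels, offsets = direction_offsets_3d()) {
  storage.mode(offsets) <- "integer"
  lm <- levels_meta(levels)
  stop_if_not(sum(lm$flat > 0) >= 2, "GLCM needs at least 2 in-mask voxels")
  mats <- cpp_glcm_counts(lm$flat, lm$dims, offsets, lm$nl)
  mats <- Filter(function(m) sum(m) > 0, mats)
  stop_if_not(length(mats) > 0, "no co-occurring voxel pairs in any direction")
  rowMeans(vapply(mats, glcm_single, numeric(24)))
}

glrlm_single <- function(P) {
  nr <- sum(P)
  ng <- nrow(P)
  jmax <- ncol(P)
  i <- seq_len(ng)
  j <- seq_len(jmax)
  ri <- rowSums(P)
  cj <- colSums(P)
  np <- sum(P %*% j) # voxel count: runs weighted by length
  p <- P / nr
  mui <- sum(i * rowSums(p))
  muj <- sum(j * colSums(p))
  c(ShortRunEmphasis = sum(t(P) / j^2) / nr,
    LongRunEmphasis = sum(t(P) * j^2) / nr,
    GrayLevelNonUniformity = sum(ri^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    RunLengthNonUniformity = sum(cj^2) / nr,
    RunLengthNonUniformityNormalized = sum(cj^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum((i - mui)^2 * rowSums(p)),
    RunVariance = sum((j - muj)^2 * colSums(p)),
    RunEntropy = entropy2(p),
    LowGrayLevelRunEmphasis = sum(P / i^2) / nr,
    HighGrayLevelRunEmphasis = sum(P * i^2) / nr,
    ShortRunLowGrayLevelEmphasis = sum(t(P / i^2) / j^2) / nr,
    ShortRunHighGrayLevelEmphasis = sum(t(P * i^2) / j^2) / nr,
    LongRunLowGrayLevelEmphasis = sum(t(P / i^2) * j^2) / nr,
    LongRunHighGrayLevelEmphasis = sum(t(P * i^2) * j^2) / nr)
}

#' Gray-level run-length matrix features
#'
#' Maximal runs of equal gray level within the ROI per direction; 16
#' standard features, averaged over the 13 directions.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glrlm_features <- function(levels, offsets = direction_offsets_3d()) {
  storage.mode(offsets) <- "integer"
  lm <- levels_meta(levels)
  mats <- cpp_glrlm_counts(lm$flat, lm$dims, offsets, lm$nl)
  rowMeans(vapply(mats, glrlm_single, numeric(16)))
}

#' Gray-level size-zone matrix features
#'
#' Zones are 26-connected components of equal gray level within the ROI;
#' the zone count matrix P(level, size) yields 16 standard features (a
#' single matrix; size zones have no directionality).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features.
#' @export
glszm_features <- function(levels) {
  lm <- levels_meta(levels)
  z <- cpp_glszm_zones(lm$flat, lm$dims)
  i <- z[, 1]
  s <- z[, 2]
  nz <- length(i)
  np <- sum(s)
  cell <- table(paste(i, s)) / nz # p(i,s) over occupied cells
  mui <- mean(i)
  mus <- mean(s)
  c(SmallAreaEmphasis = mean(1 / s^2),
    LargeAreaEmphasis = mean(s^2),
    GrayLevelNonUniformity = sum(table(i)^2) / nz,
    GrayLevelNonUniformityNormalized = sum(table(i)^2) / nz^2,
    SizeZoneNonUniformity = sum(table(s)^2) / nz,
    SizeZoneNonUniformityNormalized = sum(table(s)^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = mean((i - mui)^2),
    ZoneVariance = mean((s - mus)^2),
    ZoneEntropy = entropy2(as.numeric(cell)),
    LowGrayLevelZoneEmphasis = mean(1 / i^2),
    HighGrayLevelZoneEmphasis = mean(i^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (i^2 * s^2)),
    SmallAreaHighGrayLevelEmphasis = mean(i^2 / s^2),
    LargeAreaLowGrayLevelEmphasis = mean(s^2 / i^2),
    LargeAreaHighGrayLevelEmphasis = mean(i^2 * s^2))
}

#' Gray-level dependence matrix features
#'
#' The dependence of a voxel is 1 plus the number of in-mask 26-neighbors
#' whose gray level differs by at most `alpha`; P(level, dependence)
#' yields 14 standard features.
#'
#' @inheritParams glcm_features
#' @param alpha level-difference tolerance (default 0).
#' @return Named numeric vector of 14 features.
#' @export
gldm_features <- function(levels, alpha = 0L) {
  lm <- levels_meta(levels)
  P <- cpp_gldm_counts(lm$flat, lm$dims, lm$nl, as.integer(alpha))
  nz <- sum(P)
  ng <- nrow(P)
  i <- seq_len(ng)
  d <- seq_len(ncol(P))
  p <- P / nz
  mui <- sum(i * rowSums(p))
  mud <- sum(d * colSums(p))
  c(SmallDependenceEmphasis = sum(t(P) / d^2) / nz,
    LargeDependenceEmphasis = sum(t(P) * d^2) / nz,
    GrayLevelNonUniformity = sum(rowSums(P)^2) / nz,
    DependenceNonUniformity = sum(colSums(P)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(P)^2) / nz^2,
    GrayLevelVariance = sum((i - mui)^2 * rowSums(p)),
    DependenceVariance = sum((d - mud)^2 * colSums(p)),
    DependenceEntropy = entropy2(p),
    LowGrayLevelEmphasis = sum(P / i^2) / nz,
    HighGrayLevelEmphasis = sum(P * i^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(t(P / i^2) / d^2) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(t(P * i^2) / d^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(t(P / i^2) * d^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(t(P * i^2) * d^2) / nz)
}

#' Neighboring gray-tone difference matrix features
#'
#' For each gray level i, `s_i` sums the absolute difference between i and
#' the mean level of the in-mask 26-neighborhood over voxels of level i
#' (voxels without any in-mask neighbor are excluded). Degenerate
#' denominators are guarded with epsilon 1e-6 (a constant ROI gives
#' Busyness = Strength = 0 and Coarseness = 1e6).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features.
#' @export
ngtdm_features <- function(levels) {
  lm <- levels_meta(levels)
  m <- cpp_ngtdm(lm$flat, lm$dims, lm$nl)
  ni <- m[, 1]
  si <- m[, 2]
  nv <- sum(ni)
  stop_if_not(nv > 0, "no voxel has an in-mask neighbor")
  pi_ <- ni / nv
  act <- which(pi_ > 0)
  ngp <- length(act)
  i <- seq_along(pi_)
  coars <- min(1 / max(sum(pi_ * si), EPS), 1e6)
  contr <- if (ngp > 1) {
    dd <- outer(i[act], i[act], `-`)^2
    sum(outer(pi_[act], pi_[act]) * dd) / (ngp * (ngp - 1)) * sum(si) / nv
  } else 0
  busy_den <- sum(abs(outer(i[act] * pi_[act], i[act] * pi_[act], `-`)))
  busy <- if (busy_den > EPS) sum(pi_ * si) / busy_den else 0
  cplx <- if (ngp > 0) {
    num <- outer(pi_[act] * si[act], pi_[act] * si[act], `+`)
    den <- outer(pi_[act], pi_[act], `+`)
    sum(abs(outer(i[act], i[act], `-`)) * num / den) / nv
  } else 0
  stren_den <- sum(si)
  stren <- if (stren_den > EPS) {
    sum(outer(pi_[act], pi_[act], `+`) * outer(i[act], i[act], `-`)^2) /
      stren_den
  } else 0
  c(Coarseness = coars, Contrast = contr, Busyness = busy,
    Complexity = cplx, Strength = stren)
}
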