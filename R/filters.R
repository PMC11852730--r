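# Filter-bank stage: one original image, 8 undecimated wavelet sub-bands,
# and one Laplacian-of-Gaussian response per sigma.

# Built-in 1D decomposition filter taps (orthogonal wavelets).
.wavelet_taps <- list(
  coif1 = list(
    lo = c(-0.015655728135791993, -0.07273261951252645, 0.3848648468648578,
           0.8525720202116004, 0.3378976624574818, -0.07273261951252645),
    hi = c(0.07273261951252645, 0.3378976624574818, -0.8525720202116004,
           0.3848648468648578, 0.07273261951252645, -0.015655728135791993)
  ),
  haar = list(
    lo = c(0.7071067811865476, 0.7071067811865476),
    hi = c(-0.7071067811865476, 0.7071067811865476)
  )
)

#' Filter bank configuration
#'
#' Level-1 undecimated 3D wavelet decomposition (8 sub-bands) plus
#' Laplacian-of-Gaussian responses at fine and coarse scales.
#'
#' @param wavelet_family wavelet name; one of `"coif1"` (default) or
#'   `"haar"`.
#' @param log_sigmas_mm Gaussian scales of the LoG filters, in mm.
#' @return A `filter_bank_config` list.
#' @export
filter_bank_config <- function(wavelet_family = "coif1",
                               log_sigmas_mm = c(3, 5)) {
  stop_if_not(wavelet_family %in% names(.wavelet_taps),
              "unknown wavelet family: ", wavelet_family)
  stop_if_not(all(log_sigmas_mm > 0), "LoG sigmas must be positive")
  structure(list(wavelet_family = wavelet_family,
                 wavelet_level = 1L,
                 log_sigmas_mm = as.numeric(log_sigmas_mm)),
            class = "filter_bank_config")
}

# half-sample symmetric boundary index (edge voxel repeated)
reflect_index <- function(i, n) {
  j <- (i - 1) %% (2 * n)
  ifelse(j < n, j + 1, 2 * n - j)
}

# Filter a 3D array along one axis with the given taps, same-size output,
# symmetric boundary handling.
separable_conv <- function(arr, taps, axis) {
  d <- dim(arr)
  n <- d[axis]
  L <- length(taps)
  off <- (L - 1) %/% 2
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(arr, perm)
  mat <- matrix(ap, nrow = n)
  pos <- (1 - off):(n + L - 1 - off)
  pad <- mat[reflect_index(pos, n), , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(mat))
  for (t in seq_len(L)) {
    out <- out + taps[t] * pad[(1:n) + (t - 1), , drop = FALSE]
  }
  res <- array(out, dim = d[perm])
  aperm(res, order(perm))
}

gaussian_taps <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma_vox^2))
  g / sum(g)
}

# Sampled second derivative of a Gaussian, corrected to zero sum so a
# constant image maps exactly to zero.
gaussian_d2_taps <- function(sigma_vox) {
  r <- max(2L, as.integer(ceiling(4 * sigma_vox)))
  t <- (-r):r
  g <- exp(-t^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  d2 <- g * (t^2 - sigma_vox^2) / sigma_vox^4
  d2 - mean(d2)
}

smooth_gaussian <- function(arr, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  for (a in 1:3) {
    if (sigma_vox[a] > 0) {
      arr <- separable_conv(arr, gaussian_taps(sigma_vox[a]), a)
    }
  }
  arr
}

#' Laplacian-of-Gaussian filter
#'
#' Scale-normalized LoG response (`sigma^2 * (Gxx + Gyy + Gzz) * img`),
#' computed by separable convolution. `sigma_mm` is converted per axis via
#' the voxel spacing; the image is expected to be (near) isotropically
#' resampled first.
#'
#' @param img a [volume_image].
#' @param sigma_mm Gaussian scale in mm.
#' @return A [volume_image] holding the LoG response.
#' @export
log_filter <- function(img, sigma_mm) {
  sig_vox <- sigma_mm / img$spacing_mm
  stop_if_not(all(sig_vox >= 0.5),
              "sigma ", sigma_mm, " mm is under half a voxel; kernel would ",
              "be undersampled")
  acc <- array(0, dim = dim(img$voxels))
  for (a in 1:3) {
    part <- separable_conv(img$voxels, gaussian_d2_taps(sig_vox[a]), a)
    for (b in setdiff(1:3, a)) {
      part <- separable_conv(part, gaussian_taps(sig_vox[b]), b)
    }
    acc <- acc + sig_vox[a]^2 * part
  }
  volume_image(acc, img$spacing_mm, img$origin)
}

#' Undecimated single-level 3D wavelet decomposition
#'
#' Returns the 8 sub-bands `LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH`, each
#' the size of the input. The letters name the filter applied along the
#' `(x, y, z)` axes in that order (`L` low-pass, `H` high-pass).
#'
#' @param img a [volume_image].
#' @param cfg a [filter_bank_config].
#' @return Named list of 8 [volume_image]s.
#' @export
wavelet_subbands <- function(img, cfg = filter_bank_config()) {
  taps <- .wavelet_taps[[cfg$wavelet_family]]
  d <- dim(img$voxels)
  stop_if_not(all(d >= length(taps$lo)),
              "image dims must be at least the filter length (",
              length(taps$lo), ")")
  labels <- c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
  out <- vector("list", 8)
  names(out) <- labels
  # share the per-axis partial filtering: x first, then y, then z
  for (fx in c("L", "H")) {
    vx <- separable_conv(img$voxels, if (fx == "L") taps$lo else taps$hi, 1)
    for (fy in c("L", "H")) {
      vxy <- separable_conv(vx, if (fy == "L") taps$lo else taps$hi, 2)
      for (fz in c("L", "H")) {
        vxyz <- separable_conv(vxy, if (fz == "L") taps$lo else taps$hi, 3)
        out[[paste0(fx, fy, fz)]] <-
          volume_image(vxyz, img$spacing_mm, img$origin)
      }
    }
  }
  out[labels]
}

#' Apply the full filter bank
#'
#' @param img a [volume_image] (preprocessed, isotropic).
#' @param cfg a [filter_bank_config].
#' @return Named list of 11 [volume_image]s: `original`, `wavelet-LLL` ...
#'   `wavelet-HHH`, `log-sigma-3mm`, `log-sigma-5mm` (names follow
#'   `log_sigmas_mm`).
#' @export
apply_filter_bank <- function(img, cfg = filter_bank_config()) {
  wb <- wavelet_subbands(img, cfg)
  names(wb) <- paste0("wavelet-", names(wb))
  logs <- lapply(cfg$log_sigmas_mm, function(s) log_filter(img, s))
  names(logs) <- sprintf("log-sigma-%gmm", cfg$log_sigmas_mm)
  c(list(original = img), wb, logs)
}
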