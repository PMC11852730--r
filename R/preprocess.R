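#' Preprocessing configuration
#'
#' Houses the image-preparation parameters: z-score normalization scale,
#' the outlier threshold (in standard deviations), the fixed bin width used
#' for ROI gray-level discretization, the isotropic target spacing, and the
#' polynomial degree of the bias-field model.
#'
#' The normalization scale multiplies the z-scored image so that a bin
#' width of 25 yields a usable number of gray levels (~24 bins over +/- 3
#' standard deviations at the default scale of 100); a plain z-score
#' (scale 1) would collapse the whole ROI into a single bin.
#'
#' @param normalize_scale multiplier applied after z-scoring (default 100).
#' @param outlier_sigma voxels deviating more than this many SDs from the
#'   ROI mean are excluded from the mask (default 3).
#' @param bin_width intensity width of one gray level (default 25).
#' @param target_spacing_mm isotropic resampling target (default 1,1,1).
#' @param bias_degree polynomial degree of the log-domain bias model.
#' @param bias_on which sequences get bias correction: `"T2"` (default,
#'   ADC maps are computed parameter maps), `"ADC"`, or `"both"`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(normalize_scale = 100, outlier_sigma = 3,
                              bin_width = 25, target_spacing_mm = c(1, 1, 1),
                              bias_degree = 3, bias_on = "T2") {
  stop_if_not(bin_width > 0, "`bin_width` must be > 0")
  stop_if_not(outlier_sigma > 0, "`outlier_sigma` must be > 0")
  stop_if_not(all(target_spacing_mm > 0), "`target_spacing_mm` must be > 0")
  stop_if_not(bias_on %in% c("T2", "ADC", "both"),
              "`bias_on` must be one of T2, ADC, both")
  structure(list(normalize_scale = normalize_scale,
                 outlier_sigma = outlier_sigma,
                 bin_width = bin_width,
                 target_spacing_mm = rep_len(as.numeric(target_spacing_mm), 3),
                 bias_degree = as.integer(bias_degree),
                 bias_on = bias_on),
            class = "preprocess_config")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# polynomial design matrix in coordinates normalized to [-1, 1]
poly_design <- function(coords, degree) {
  terms <- expand.grid(i = 0:degree, j = 0:degree, k = 0:degree)
  terms <- terms[rowSums(terms) <= degree, , drop = FALSE]
  X <- matrix(1, nrow = nrow(coords), ncol = nrow(terms))
  for (t in seq_len(nrow(terms))) {
    X[, t] <- coords[, 1]^terms$i[t] * coords[, 2]^terms$j[t] *
      coords[, 3]^terms$k[t]
  }
  X
}

norm_coords <- function(dims) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  for (a in 1:3) {
    n <- dims[a]
    g[[a]] <- if (n > 1) 2 * (g[[a]] - 1) / (n - 1) - 1 else 0
  }
  as.matrix(g)
}

#' Bias-field correction by log-domain polynomial fit
#'
#' Estimates a smooth multiplicative intensity field as a low-degree
#' polynomial fit to log-intensity over the mask support, and divides the
#' image by it. The mean intensity within the mask is preserved exactly by
#' a final rescale. This targets the same artifact as iterative B-spline
#' bias correctors (smooth coil/field inhomogeneity) with a deliberately
#' simple, testable model.
#'
#' @param img a [volume_image]; must be strictly positive within the mask.
#' @param mask a [segmentation_mask].
#' @param degree polynomial degree of the field model (default 3).
#' @return The corrected [volume_image].
#' @export
bias_field_correct <- function(img, mask, degree = 3) {
  check_aligned(img, mask)
  stop_if_not(mask_count(mask) > 0, "mask is empty")
  inroi <- img$voxels[mask$voxels]
  nbad <- sum(inroi <= 0)
  stop_if_not(nbad == 0, nbad,
              " non-positive voxel(s) within mask; log-domain fit undefined")
  dims <- dim(img$voxels)
  coords <- norm_coords(dims)
  X <- poly_design(coords[as.vector(mask$voxels), , drop = FALSE], degree)
  fit <- stats::lm.fit(X, log(inroi))
  full <- poly_design(coords, degree) %*% fit$coefficients
  fmask <- full[as.vector(mask$voxels)]
  # the fit is only supported on the mask; clamp the extrapolated log-field
  # to its in-mask range so far-field voxels are not blown up
  full <- pmin(pmax(full, min(fmask)), max(fmask))
  field <- exp(array(full - mean(fmask), dim = dims))
  out <- img$voxels / field
  out <- out * mean(inroi) / mean(out[mask$voxels])
  volume_image(out, img$spacing_mm, img$origin)
}

#' Whole-image z-score normalization
#'
#' `(x - mean) / sd * normalize_scale`, with mean and (population) SD taken
#' over the whole image, before any ROI-scoped operation.
#'
#' @param img a [volume_image].
#' @param cfg a [preprocess_config].
#' @return The normalized [volume_image].
#' @export
normalize_intensity <- function(img, cfg = preprocess_config()) {
  s <- pop_sd(img$voxels)
  stop_if_not(s > 0, "constant image: standard deviation is zero")
  volume_image((img$voxels - mean(img$voxels)) / s * cfg$normalize_scale,
               img$spacing_mm, img$origin)
}

#' Exclude intensity-outlier voxels from the mask
#'
#' Voxels whose intensity deviates more than `outlier_sigma` standard
#' deviations from the ROI mean are removed from the mask (exclusion, not
#' clamping). Statistics are computed over the input mask.
#'
#' @param img a [volume_image].
#' @param mask a [segmentation_mask].
#' @param cfg a [preprocess_config].
#' @return The pruned [segmentation_mask].
#' @export
remove_outlier_voxels <- function(img, mask, cfg = preprocess_config()) {
  check_aligned(img, mask)
  stop_if_not(mask_count(mask) > 0, "mask is empty")
  x <- img$voxels[mask$voxels]
  mu <- mean(x)
  s <- pop_sd(x)
  keep <- mask$voxels & (abs(img$voxels - mu) <= cfg$outlier_sigma * s)
  stop_if_not(sum(keep) > 0,
              "outlier removal would empty the mask")
  segmentation_mask(keep, mask$spacing_mm)
}

#' Resample an image/mask pair to isotropic spacing
#'
#' The image is interpolated with a cubic (Keys) kernel, the mask with
#' linear interpolation followed by a 0.5 threshold. Output grid sizes are
#' `round(dim * spacing / target)` per axis; first voxel centres are
#' aligned, so world extent is preserved to within one target voxel.
#'
#' @param img a [volume_image].
#' @param mask a [segmentation_mask].
#' @param cfg a [preprocess_config].
#' @return List with elements `img` and `mask`, both at target spacing.
#' @export
resample_isotropic <- function(img, mask, cfg = preprocess_config()) {
  check_aligned(img, mask)
  dims <- dim(img$voxels)
  target <- cfg$target_spacing_mm
  outdims <- pmax(1L, as.integer(round(dims * img$spacing_mm / target)))
  step <- target / img$spacing_mm
  rimg <- cpp_resample3(as.numeric(img$voxels), as.integer(dims),
                        outdims, step, 3L)
  rmask <- cpp_resample3(as.numeric(mask$voxels), as.integer(dims),
                         outdims, step, 1L)
  mvox <- array(rmask >= 0.5, dim = outdims)
  stop_if_not(sum(mvox) > 0, "resampled mask is empty")
  list(img = volume_image(array(rimg, dim = outdims), target, img$origin),
       mask = segmentation_mask(mvox, target))
}

#' Fixed-bin-width gray-level discretization of an ROI
#'
#' `level(x) = floor((x - min_ROI) / W) + 1` for in-mask voxels; voxels
#' outside the mask get level 0. Anchoring at the ROI minimum makes the
#' levels invariant to adding any constant multiple of `W`.
#'
#' @param img a [volume_image].
#' @param mask a [segmentation_mask].
#' @param cfg a [preprocess_config] (uses `bin_width`).
#' @return Integer array of gray levels with attribute `nlevels`.
#' @export
discretize_roi <- function(img, mask, cfg = preprocess_config()) {
  check_aligned(img, mask)
  stop_if_not(mask_count(mask) > 0, "mask is empty")
  W <- cfg$bin_width
  lev <- array(0L, dim = dim(img$voxels))
  x <- img$voxels[mask$voxels]
  lev[mask$voxels] <- as.integer(floor((x - min(x)) / W)) + 1L
  attr(lev, "nlevels") <- max(lev)
  lev
}

# Full per-sequence preparation chain in its fixed order:
# bias correction -> normalization -> outlier exclusion -> resampling.
# Returns the resampled image, the resampled outlier-pruned mask, and the
# resampled original mask (used for shape features).
preprocess_sequence <- function(img, mask, cfg = preprocess_config(),
                                bias = TRUE) {
  if (bias) img <- bias_field_correct(img, mask, cfg$bias_degree)
  img <- normalize_intensity(img, cfg)
  pruned <- remove_outlier_voxels(img, mask, cfg)
  res <- resample_isotropic(img, pruned, cfg)
  shape_mask <- resample_isotropic(img, mask, cfg)$mask
  list(img = res$img, mask = res$mask, shape_mask = shape_mask)
}
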