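# Synthetic paired T2-like / ADC-like lesion cohort. Lesion texture is a
# class-conditional Gaussian random field: white noise smoothed with a
# class-specific kernel (correlation length), scaled to a class-specific
# texture SD, on a class-specific mean level. The ADC-like volume is
# anti-correlated with the T2 signal (high T2 "cellularity" -> low ADC) on
# a plausible physical scale (400-2500 in 1e-6 mm^2/s units).

#' Class-difference profile of the synthetic cohort
#'
#' Three planted texture differences between Warthin-like (WT) and
#' malignant-like (MT) lesions, each scaled by `strength`: a gray-level
#' mean shift (drives first-order mean/RMS via lesion-background contrast),
#' a spatial correlation-length difference (drives zone-size structure,
#' GLSZM), and an intensity variance ratio (drives run/level emphasis,
#' GLRLM, and first-order spread). `strength = 0` makes the classes
#' exchangeable (null cohort).
#'
#' @param strength scalar effect multiplier (default 1).
#' @return An `effect_profile` list.
#' @export
effect_profile <- function(strength = 1) {
  structure(list(strength = strength,
                 mean_shift = 35 * strength,        # raw a.u., MT - WT
                 corr_length_wt_mm = 2.5,
                 corr_length_mt_mm = 2.5 + 1.5 * strength,
                 var_ratio = 1 + 0.5 * strength),   # MT/WT texture variance
            class = "effect_profile")
}

#' Synthetic cohort specification
#'
#' Defaults emulate the study cohort: 106 lesions (66 WT, 40 MT), ~20% of
#' patients carrying two same-class lesions, in-plane spacing 0.7 mm with
#' 3 mm slices, every lesion over 10 mm in diameter, and 30 lesions (15 per
#' class) carrying a second, boundary-perturbed segmentation for stability
#' analysis.
#'
#' @param n_wt,n_mt lesions per class (default 66 / 40).
#' @param roi_shape ROI grid in voxels (default 32 x 32 x 16).
#' @param spacing_mm voxel spacing (default 0.7 x 0.7 x 3.0 mm).
#' @param effect an [effect_profile].
#' @param noise_sd additive acquisition noise SD, raw a.u. (default 15).
#' @param n_reseg number of lesions with a second segmentation (default 30,
#'   balanced across classes).
#' @param reseg_jitter_mm boundary jitter of the re-segmentation (default
#'   one in-plane voxel).
#' @param bias_amplitude relative amplitude of the planted multiplicative
#'   bias field on T2 (default 0.1).
#' @param seed integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_wt = 66, n_mt = 40, roi_shape = c(32, 32, 16),
                        spacing_mm = c(0.7, 0.7, 3.0),
                        effect = effect_profile(1), noise_sd = 15,
                        n_reseg = 30, reseg_jitter_mm = NULL,
                        bias_amplitude = 0.1, seed = 1) {
  stop_if_not(n_wt >= 2 && n_mt >= 2, "need at least 2 lesions per class")
  stop_if_not(all(roi_shape >= 4), "degenerate roi_shape (dim < 4)")
  stop_if_not(all(spacing_mm > 0), "spacing must be positive")
  stop_if_not(n_reseg <= n_wt + n_mt, "n_reseg exceeds cohort size")
  structure(list(n_wt = as.integer(n_wt), n_mt = as.integer(n_mt),
                 roi_shape = as.integer(roi_shape),
                 spacing_mm = as.numeric(spacing_mm),
                 effect = effect, noise_sd = noise_sd,
                 n_reseg = as.integer(n_reseg),
                 reseg_jitter_mm = reseg_jitter_mm %||% max(spacing_mm[1:2]),
                 bias_amplitude = bias_amplitude,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# smoothed unit-variance Gaussian random field
grf <- function(dims, corr_mm, spacing_mm) {
  w <- array(rnorm(prod(dims)), dim = dims)
  s <- smooth_gaussian(w, corr_mm / spacing_mm)
  (s - mean(s)) / pop_sd(s)
}

# smooth random multiplicative field, amplitude +/- amp
random_bias_field <- function(dims, amp) {
  co <- norm_coords(dims)
  coef <- rnorm(3)
  f <- co %*% coef + 0.5 * rnorm(1) * co[, 1] * co[, 2]
  f <- f / max(abs(f), 1e-12) * amp
  1 + array(f, dim = dims)
}

ellipsoid_mask <- function(dims, spacing_mm, radii_mm) {
  ctr <- (dims - 1) / 2 * spacing_mm
  x <- ((seq_len(dims[1]) - 1) * spacing_mm[1] - ctr[1]) / radii_mm[1]
  y <- ((seq_len(dims[2]) - 1) * spacing_mm[2] - ctr[2]) / radii_mm[2]
  z <- ((seq_len(dims[3]) - 1) * spacing_mm[3] - ctr[3]) / radii_mm[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  segmentation_mask(r2 <= 1, spacing_mm)
}

generate_lesion <- function(spec, label, lesion_id, patient_id) {
  dims <- spec$roi_shape
  sp <- spec$spacing_mm
  eff <- spec$effect
  extent <- dims * sp
  # axis diameters: > 1 cm always; in-plane capped by the ROI
  dmax_ip <- min(20, extent[1] - 3, extent[2] - 3)
  dmax_ax <- min(40, extent[3] - 6)
  diam <- c(runif(2, 12, max(12.5, dmax_ip)), runif(1, 12, max(12.5, dmax_ax)))
  mask <- ellipsoid_mask(dims, sp, pmin(diam, c(extent[1:2] - 2, extent[3])) / 2)

  jit <- function(x) x * rlnorm(1, 0, 0.15)
  is_mt <- label == "MT"
  corr <- jit(if (is_mt) eff$corr_length_mt_mm else eff$corr_length_wt_mm)
  tex_sd <- jit(45 * sqrt(if (is_mt) eff$var_ratio else 1))
  lesion_mean <- 320 + (if (is_mt) eff$mean_shift else 0) + rnorm(1, 0, 8)

  bg <- 250 + 20 * grf(dims, 1.5, sp)
  lesion_tex <- lesion_mean + tex_sd * grf(dims, corr, sp)
  signal <- bg
  signal[mask$voxels] <- lesion_tex[mask$voxels]

  t2 <- signal + rnorm(prod(dims), 0, spec$noise_sd)
  t2 <- t2 * random_bias_field(dims, spec$bias_amplitude)
  t2 <- pmax(t2, 1)

  adc <- 1800 - 2.0 * (signal - 280) + rnorm(prod(dims), 0, 40)
  adc <- pmin(pmax(adc, 400), 2500)

  list(lesion_id = lesion_id, patient_id = patient_id, label = label,
       t2_volume = volume_image(array(t2, dim = dims), sp),
       adc_volume = volume_image(array(adc, dim = dims), sp),
       mask = mask, mask_reseg = NULL)
}

#' Generate a labeled synthetic lesion cohort
#'
#' @param spec a [cohort_spec].
#' @return List of `synthetic_lesion` objects (fields `lesion_id`,
#'   `patient_id`, `label`, `t2_volume`, `adc_volume`, `mask`, and for the
#'   stability subset `mask_reseg`). Deterministic under the spec's seed.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  with_seed(spec$seed, {
    labels <- c(rep("WT", spec$n_wt), rep("MT", spec$n_mt))
    n <- length(labels)
    # ~20% of patients carry a second same-class lesion
    patient <- character(n)
    pid <- 0L
    i <- 1L
    while (i <= n) {
      pid <- pid + 1L
      patient[i] <- sprintf("P%03d", pid)
      if (i < n && labels[i + 1] == labels[i] && runif(1) < 0.25) {
        patient[i + 1] <- sprintf("P%03d", pid)
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
    lesions <- lapply(seq_len(n), function(k) {
      generate_lesion(spec, labels[k], sprintf("L%03d", k), patient[k])
    })
    # balanced stability subset with perturbed re-segmentations
    per_class <- c(WT = min(ceiling(spec$n_reseg / 2), spec$n_wt),
                   MT = min(floor(spec$n_reseg / 2), spec$n_mt))
    reseg_idx <- c(sample(which(labels == "WT"), per_class["WT"]),
                   sample(which(labels == "MT"), per_class["MT"]))
    for (k in reseg_idx) {
      lesions[[k]]$mask_reseg <- simulate_resegmentation(
        lesions[[k]]$mask, spec$reseg_jitter_mm,
        seed = sub_seed(spec$seed, lesions[[k]]$lesion_id))
    }
    lesions
  })
}

#' Simulate an intra-observer re-segmentation
#'
#' Perturbs the mask boundary by a smooth random inward/outward
#' displacement bounded by `jitter_mm`, emulating a second manual
#' delineation by the same reader.
#'
#' @param mask a [segmentation_mask].
#' @param jitter_mm maximum boundary displacement (0 returns the mask
#'   unchanged).
#' @param seed integer seed.
#' @return A perturbed, nonempty [segmentation_mask]; errors if the jitter
#'   empties the mask.
#' @export
simulate_resegmentation <- function(mask, jitter_mm, seed = 1) {
  stop_if_not(mask_count(mask) > 0, "mask is empty")
  if (jitter_mm == 0) return(mask)
  with_seed(seed, {
    dims <- dim(mask$voxels)
    sigma_s <- c(1.5, 1.5, 0.5) # smoothing of the indicator, voxels
    sm <- smooth_gaussian(array(as.numeric(mask$voxels), dim = dims), sigma_s)
    r <- smooth_gaussian(array(rnorm(prod(dims)), dim = dims), c(2, 2, 1))
    r <- r / max(abs(r))
    # boundary gradient of the smoothed indicator ~ 1/(sigma*sqrt(2*pi));
    # a threshold offset tau displaces the boundary by ~tau/gradient
    jitter_vox <- jitter_mm / mask$spacing_mm[1]
    tau <- jitter_vox / (sigma_s[1] * sqrt(2 * pi))
    # restrict the perturbation to the boundary band of the original mask
    new <- (sm > 0.01) & ((sm + tau * r) > 0.5)
    out <- segmentation_mask(new, mask$spacing_mm)
    stop_if_not(sum(new) > 0 && dice_coefficient(mask, out) >= 0.5,
                "jitter emptied (or effectively destroyed) the mask")
    out
  })
}

#' Dice overlap of two masks
#' @param a,b [segmentation_mask]s of identical dimensions.
#' @return Dice coefficient in [0, 1].
#' @export
dice_coefficient <- function(a, b) {
  stop_if_not(identical(dim(a$voxels), dim(b$voxels)), "dimension mismatch")
  2 * sum(a$voxels & b$voxels) / (sum(a$voxels) + sum(b$voxels))
}

#' Write a cohort to disk as NIfTI volumes plus a manifest CSV
#'
#' @param lesions list from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_cohort <- function(lesions, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(lesions, function(l) {
    t2 <- file.path(dir, paste0(l$lesion_id, "_t2.nii.gz"))
    adc <- file.path(dir, paste0(l$lesion_id, "_adc.nii.gz"))
    msk <- file.path(dir, paste0(l$lesion_id, "_mask.nii.gz"))
    write_volume(l$t2_volume, t2)
    write_volume(l$adc_volume, adc)
    write_volume(l$mask, msk)
    reseg <- ""
    if (!is.null(l$mask_reseg)) {
      reseg <- file.path(dir, paste0(l$lesion_id, "_mask_reseg.nii.gz"))
      write_volume(l$mask_reseg, reseg)
    }
    data.frame(lesion_id = l$lesion_id, patient_id = l$patient_id,
               label = l$label, t2 = t2, adc = adc, mask = msk,
               mask_reseg = reseg, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  path <- file.path(dir, "cohort_manifest.csv")
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Read a cohort manifest back into lesion objects
#'
#' @param manifest_path path to a `cohort_manifest.csv` written by
#'   [write_cohort()].
#' @return List of lesions as produced by [generate_cohort()].
#' @export
read_cohort <- function(manifest_path) {
  df <- read.csv(manifest_path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    reseg <- if (is.null(df$mask_reseg)) "" else df$mask_reseg[i]
    list(lesion_id = df$lesion_id[i], patient_id = df$patient_id[i],
         label = df$label[i],
         t2_volume = read_volume(df$t2[i]),
         adc_volume = read_volume(df$adc[i]),
         mask = read_mask(df$mask[i]),
         mask_reseg = if (!is.na(reseg) && nzchar(reseg)) read_mask(reseg)
                      else NULL)
  })
}
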