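#' Feature extraction configuration
#'
#' Defaults reproduce the standard 1037-feature-per-sequence set: 14 shape
#' + 18 first-order + 75 texture features on the original image, and 93
#' (non-shape) features on each of the 10 filtered images (8 wavelet
#' sub-bands + 2 LoG scales).
#'
#' @param families feature families to extract.
#' @param glcm_distance co-occurrence distance in voxels (default 1).
#' @param gldm_alpha dependence level tolerance (default 0).
#' @param use_filters apply the wavelet/LoG filter bank (default TRUE);
#'   turning it off restricts extraction to the original image (107
#'   features per sequence).
#' @return An `extraction_config` list.
#' @export
extraction_config <- function(families = c("shape", "firstorder", "glcm",
                                           "glrlm", "glszm", "gldm",
                                           "ngtdm"),
                              glcm_distance = 1L, gldm_alpha = 0L,
                              use_filters = TRUE) {
  known <- c("shape", "firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm")
  stop_if_not(all(families %in% known), "unknown feature family")
  structure(list(families = families,
                 glcm_distance = as.integer(glcm_distance),
                 gldm_alpha = as.integer(gldm_alpha),
                 use_filters = isTRUE(use_filters)),
            class = "extraction_config")
}

# 18 first-order + 75 texture features of one (possibly filtered) image
# within the ROI mask. Names are "{family}|{feature}".
intensity_features <- function(img, mask, pre_cfg, ex_cfg) {
  levels <- discretize_roi(img, mask, pre_cfg)
  x <- img$voxels[mask$voxels]
  fam <- ex_cfg$families
  out <- c(
    if ("firstorder" %in% fam) {
      prefix_names(first_order_features(x, levels[mask$voxels],
                                        prod(img$spacing_mm)), "firstorder")
    },
    if ("glcm" %in% fam) {
      prefix_names(glcm_features(levels, direction_offsets_3d() *
                                   ex_cfg$glcm_distance), "glcm")
    },
    if ("glrlm" %in% fam) prefix_names(glrlm_features(levels), "glrlm"),
    if ("glszm" %in% fam) prefix_names(glszm_features(levels), "glszm"),
    if ("gldm" %in% fam) {
      prefix_names(gldm_features(levels, ex_cfg$gldm_alpha), "gldm")
    },
    if ("ngtdm" %in% fam) prefix_names(ngtdm_features(levels), "ngtdm"))
  out
}

prefix_names <- function(x, family) {
  setNames(x, paste0(family, "|", names(x)))
}

# All features of one sequence: shape (original geometry) + per-filter
# intensity/texture blocks. Names are "{seq}|{filter}|{family}|{feature}".
extract_sequence <- function(img, mask, seq_name, pre_cfg, filt_cfg, ex_cfg,
                             bias = TRUE) {
  pp <- preprocess_sequence(img, mask, pre_cfg, bias = bias)
  images <- if (ex_cfg$use_filters) {
    apply_filter_bank(pp$img, filt_cfg)
  } else {
    list(original = pp$img)
  }
  blocks <- lapply(names(images), function(fn) {
    v <- intensity_features(images[[fn]], pp$mask, pre_cfg, ex_cfg)
    setNames(v, paste0(fn, "|", names(v)))
  })
  out <- unlist(blocks)
  if ("shape" %in% ex_cfg$families) {
    sh <- prefix_names(shape_features(pp$shape_mask), "original|shape")
    out <- c(sh, out)
  }
  setNames(out, paste0(seq_name, "|", names(out)))
}

#' Extract all radiomic features of one lesion
#'
#' Runs the preprocessing chain and filter bank on both sequences of a
#' lesion and computes the full feature vector: per sequence 14 shape
#' features (from the shared mask geometry) plus 93 intensity/texture
#' features on the original and on each of the 10 filtered images, i.e.
#' 1037 per sequence, 2074 for the T2 + ADC pair. Feature names follow
#' `"{sequence}|{filter}|{family}|{feature}"`.
#'
#' @param lesion a `synthetic_lesion` (or any list with `t2_volume`,
#'   `adc_volume`, `mask`).
#' @param pre_cfg a [preprocess_config].
#' @param filt_cfg a [filter_bank_config].
#' @param ex_cfg an [extraction_config].
#' @param use_reseg use the perturbed re-segmentation mask instead of the
#'   primary mask (for stability analysis).
#' @return Named numeric vector; errors if any feature is non-finite.
#' @export
extract_all <- function(lesion, pre_cfg = preprocess_config(),
                        filt_cfg = filter_bank_config(),
                        ex_cfg = extraction_config(),
                        use_reseg = FALSE) {
  mask <- if (use_reseg) {
    stop_if_not(!is.null(lesion$mask_reseg), "lesion has no re-segmentation")
    lesion$mask_reseg
  } else {
    lesion$mask
  }
  out <- c(
    extract_sequence(lesion$t2_volume, mask, "T2", pre_cfg, filt_cfg, ex_cfg,
                     bias = pre_cfg$bias_on %in% c("T2", "both")),
    extract_sequence(lesion$adc_volume, mask, "ADC", pre_cfg, filt_cfg,
                     ex_cfg,
                     bias = pre_cfg$bias_on %in% c("ADC", "both")))
  bad <- names(out)[!is.finite(out)]
  stop_if_not(length(bad) == 0,
              "non-finite feature value(s): ", paste(head(bad, 5),
                                                     collapse = ", "))
  out
}

#' Extract a feature table for a whole cohort
#'
#' @param lesions list of lesions (see [generate_cohort()]).
#' @inheritParams extract_all
#' @return A `data.frame` with columns `lesion_id`, `patient_id`, `label`,
#'   then one column per feature; one row per lesion, no missing cells.
#' @export
extract_cohort <- function(lesions, pre_cfg = preprocess_config(),
                           filt_cfg = filter_bank_config(),
                           ex_cfg = extraction_config(),
                           use_reseg = FALSE) {
  rows <- lapply(lesions, extract_all, pre_cfg = pre_cfg,
                 filt_cfg = filt_cfg, ex_cfg = ex_cfg,
                 use_reseg = use_reseg)
  nm <- names(rows[[1]])
  for (r in rows) stop_if_not(identical(names(r), nm),
                              "inconsistent feature names across lesions")
  mat <- do.call(rbind, rows)
  df <- data.frame(lesion_id = vapply(lesions, `[[`, "", "lesion_id"),
                   patient_id = vapply(lesions, `[[`, "", "patient_id"),
                   label = vapply(lesions, `[[`, "", "label"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  cbind(df, as.data.frame(mat, check.names = FALSE))
}

#' Names of the feature columns of a feature table
#' @param table a feature table from [extract_cohort()].
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table) {
  setdiff(colnames(table), c("lesion_id", "patient_id", "label"))
}
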