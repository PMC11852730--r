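#' Pipeline configuration
#'
#' Bundles the per-stage configurations with one global seed from which
#' every stochastic stage (cohort generation, train/test split,
#' cross-validation folds) derives its own sub-seed, so a run is fully
#' reproducible from the config alone.
#'
#' @param simulate a [cohort_spec] (its `seed` is overridden by the global
#'   seed's cohort sub-seed).
#' @param preprocess a [preprocess_config].
#' @param filters a [filter_bank_config].
#' @param extraction an [extraction_config].
#' @param selection a [selection_config].
#' @param seed global integer seed.
#' @param out_dir optional output directory for run artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = cohort_spec(),
                            preprocess = preprocess_config(),
                            filters = filter_bank_config(),
                            extraction = extraction_config(),
                            selection = selection_config(),
                            seed = 1, out_dir = NULL) {
  structure(list(simulate = simulate, preprocess = preprocess,
                 filters = filters, extraction = extraction,
                 selection = selection, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

block_from_list <- function(constructor, args, block) {
  known <- names(formals(constructor))
  bad <- setdiff(names(args), known)
  stop_if_not(length(bad) == 0, "unknown key(s) in `", block, "`: ",
              paste(bad, collapse = ", "))
  do.call(constructor, args)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized blocks: `simulate`, `preprocess`, `filters`, `extraction`,
#' `selection`, plus scalar `seed` and `out_dir`. Unknown keys (at either
#' level) are rejected. See
#' `system.file("extdata", "example_config.yaml", package = "paromics")`
#' for a template.
#'
#' @param path YAML file path.
#' @return A [pipeline_config].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("simulate", "preprocess", "filters", "extraction", "selection",
             "seed", "out_dir")
  bad <- setdiff(names(y), known)
  stop_if_not(length(bad) == 0, "unknown config key(s): ",
              paste(bad, collapse = ", "))
  if (!is.null(y$simulate$effect) && is.numeric(y$simulate$effect)) {
    y$simulate$effect <- effect_profile(y$simulate$effect)
  }
  pipeline_config(
    simulate = block_from_list(cohort_spec, y$simulate %||% list(),
                               "simulate"),
    preprocess = block_from_list(preprocess_config, y$preprocess %||% list(),
                                 "preprocess"),
    filters = block_from_list(filter_bank_config, y$filters %||% list(),
                              "filters"),
    extraction = block_from_list(extraction_config, y$extraction %||% list(),
                                 "extraction"),
    selection = block_from_list(selection_config, y$selection %||% list(),
                                "selection"),
    seed = y$seed %||% 1,
    out_dir = y$out_dir)
}

#' Run the full radiomics pipeline
#'
#' Executes, in order: cohort simulation -> preprocessing -> filter bank ->
#' feature extraction (cohort + re-segmentation subset) -> ICC stability
#' gate -> stratified split -> univariate screen -> redundancy pruning ->
#' LASSO score -> per-set cut-off and diagnostic report. If the cascade
#' retains nothing (e.g. a null cohort), the run completes with an
#' intercept-only constant score whose AUC is 0.5.
#'
#' @param config a [pipeline_config].
#' @param lesions optionally, a pre-generated cohort (skips simulation).
#' @return A `pipeline_result` list: `features`, `split`, `cascade`,
#'   `model`, `scores`, `report_train`, `report_test`, `config_hash`,
#'   `seeds`. Artifacts are written when `config$out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config(), lesions = NULL) {
  seeds <- c(cohort = sub_seed(config$seed, "cohort"),
             split = sub_seed(config$seed, "split"),
             cv = sub_seed(config$seed, "cv"))
  if (is.null(lesions)) {
    spec <- config$simulate
    spec$seed <- seeds[["cohort"]]
    lesions <- generate_cohort(spec)
  }
  feats <- extract_cohort(lesions, config$preprocess, config$filters,
                          config$extraction)
  has_reseg <- vapply(lesions, function(l) !is.null(l$mask_reseg), TRUE)
  reseg1 <- reseg2 <- NULL
  if (sum(has_reseg) >= 3) {
    sub <- lesions[has_reseg]
    reseg1 <- extract_cohort(sub, config$preprocess, config$filters,
                             config$extraction)
    reseg2 <- extract_cohort(sub, config$preprocess, config$filters,
                             config$extraction, use_reseg = TRUE)
  }
  split <- stratified_split(feats$label, seed = seeds[["split"]])
  sel_cfg <- config$selection
  sel_cfg$seed <- seeds[["cv"]]
  train <- feats[split$train, , drop = FALSE]
  test <- feats[split$test, , drop = FALSE]
  cascade <- run_selection_cascade(train, reseg1, reseg2, sel_cfg)
  if (!is.null(cascade$model)) {
    s_train <- radiomic_score(cascade$model, train)
    s_test <- radiomic_score(cascade$model, test)
  } else {
    s_train <- rep(0, nrow(train)) # constant, uninformative score
    s_test <- rep(0, nrow(test))
  }
  rep_train <- diagnostic_metrics(s_train, train$label,
                                  optimal_cutoff(s_train, train$label))
  rep_test <- diagnostic_metrics(s_test, test$label,
                                 optimal_cutoff(s_test, test$label))
  result <- structure(
    list(features = feats, split = split, cascade = cascade,
         model = cascade$model,
         scores = list(train = s_train, test = s_test),
         report_train = rep_train, report_test = rep_test,
         config_hash = rlang::hash(config), seeds = seeds,
         config = config),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- result$config_hash
  write.csv(result$features, file.path(dir, "features.csv"),
            row.names = FALSE)
  sel <- list(config_hash = h,
              stages = as.list(result$cascade$stages),
              icc = as.list(result$cascade$icc$icc),
              p_raw = as.list(result$cascade$screen$p_raw),
              p_adjusted = as.list(result$cascade$screen$p_adjusted),
              eliminated = result$cascade$redundancy$eliminated)
  jsonlite::write_json(sel, file.path(dir, "selection_report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(result$model)) {
    m <- result$model
    jsonlite::write_json(
      list(config_hash = h, intercept = m$intercept,
           coefficients = as.list(m$coefficients),
           standardization = m$standardization, lambda = m$lambda),
      file.path(dir, "score_model.json"), auto_unbox = TRUE, digits = NA)
  }
  rep_json <- function(r) {
    list(auc = r$auc, auc_ci = r$auc_ci, auc_p = r$auc_p, cutoff = r$cutoff,
         sensitivity = r$sensitivity, sensitivity_ci = r$sensitivity_ci,
         specificity = r$specificity, specificity_ci = r$specificity_ci,
         pos_lr = r$pos_lr, pos_lr_ci = r$pos_lr_ci, neg_lr = r$neg_lr,
         neg_lr_ci = r$neg_lr_ci, counts = as.list(r$counts))
  }
  jsonlite::write_json(
    list(config_hash = h, training = rep_json(result$report_train),
         testing = rep_json(result$report_test)),
    file.path(dir, "diagnostic_report.json"), auto_unbox = TRUE,
    digits = NA)
  n_feat <- length(feature_names(result$features))
  log_lines <- c(
    sprintf("config_hash: %s", h),
    sprintf("seed.%s: %d", names(result$seeds), result$seeds),
    sprintf("lesions: %d", nrow(result$features)),
    sprintf("features_total: %d", n_feat),
    sprintf("features_per_sequence: %d", n_feat %/% 2L),
    sprintf("stage_retained.%s: %d", names(result$cascade$stages),
            result$cascade$stages))
  writeLines(log_lines, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", nrow(x$features), " lesions, ",
      length(feature_names(x$features)), " features\n", sep = "")
  cat("cascade retained:",
      paste(names(x$cascade$stages), x$cascade$stages, sep = "=",
            collapse = " "), "\n")
  cat(sprintf("training AUC %.3f / testing AUC %.3f\n",
              x$report_train$auc, x$report_test$auc))
  invisible(x)
}
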