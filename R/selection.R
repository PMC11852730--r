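#' Feature-selection cascade configuration
#'
#' Thresholds of the four-stage reduction: ICC stability gate (> 0.85),
#' Mann-Whitney univariate screen with Benjamini-Hochberg correction
#' (adjusted p < 0.05), Spearman redundancy pruning (|rho| > 0.9), and
#' LASSO logistic regression with cross-validated lambda.
#'
#' @param icc_threshold ICC retention threshold (strict >; default 0.85).
#' @param alpha adjusted-p significance level (default 0.05).
#' @param spearman_threshold absolute correlation above which a pair is
#'   redundant (default 0.9).
#' @param cv_folds cross-validation folds for the LASSO (default 10).
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param bh_scope `"joint"` (default): one BH correction across both
#'   sequences' features; `"per_sequence"` adjusts T2 and ADC separately.
#' @param seed integer seed for fold assignment.
#' @return A `selection_config` list.
#' @export
selection_config <- function(icc_threshold = 0.85, alpha = 0.05,
                             spearman_threshold = 0.9, cv_folds = 10,
                             lambda_rule = c("min", "1se"),
                             bh_scope = c("joint", "per_sequence"),
                             seed = 1) {
  stop_if_not(icc_threshold > 0 && icc_threshold < 1,
              "`icc_threshold` must be in (0,1)")
  stop_if_not(alpha > 0 && alpha <= 1, "`alpha` must be in (0,1]")
  stop_if_not(spearman_threshold > 0 && spearman_threshold < 1,
              "`spearman_threshold` must be in (0,1)")
  stop_if_not(cv_folds >= 2, "need at least 2 folds")
  structure(list(icc_threshold = icc_threshold, alpha = alpha,
                 spearman_threshold = spearman_threshold,
                 cv_folds = as.integer(cv_folds),
                 lambda_rule = match.arg(lambda_rule),
                 bh_scope = match.arg(bh_scope),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Intraclass correlation ICC(A,1)
#'
#' Two-way mixed-effects, absolute-agreement, single-measure ICC between
#' two ratings of the same subjects (McGraw & Wong's ICC(A,1)), the
#' conventional variant for intra-observer feature stability.
#'
#' @param x,y numeric vectors: the two measurements per subject.
#' @return ICC estimate; 0 (with a warning) for zero-variance input.
#' @export
icc_a1 <- function(x, y) {
  n <- length(x)
  stop_if_not(n == length(y), "ratings must have equal length")
  stop_if_not(n >= 3, "ICC needs at least 3 subjects")
  if (pop_sd(c(x, y)) == 0) {
    warning("zero-variance feature; ICC reported as 0")
    return(0)
  }
  k <- 2
  m <- cbind(x, y)
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k / n * (msc - mse)
  if (denom <= 0) return(0)
  (msr - mse) / denom
}

#' ICC stability gate
#'
#' Computes ICC(A,1) per feature between the original and re-segmented
#' feature tables (same lesions, same feature names) and retains features
#' with ICC strictly above the threshold.
#'
#' @param features_seg1,features_seg2 feature tables from
#'   [extract_cohort()] over the re-segmentation subset.
#' @param cfg a [selection_config].
#' @return List with `retained` (feature names) and `icc` (named vector).
#' @export
icc_stability_filter <- function(features_seg1, features_seg2,
                                 cfg = selection_config()) {
  stop_if_not(identical(features_seg1$lesion_id, features_seg2$lesion_id),
              "tables must cover the same lesions in the same order")
  fn <- feature_names(features_seg1)
  stop_if_not(identical(fn, feature_names(features_seg2)),
              "tables must share feature names")
  stop_if_not(nrow(features_seg1) >= 3, "ICC needs at least 3 lesions")
  icc <- vapply(fn, function(f) {
    suppressWarnings(icc_a1(features_seg1[[f]], features_seg2[[f]]))
  }, 0)
  list(retained = fn[icc > cfg$icc_threshold], icc = icc)
}

#' Mann-Whitney univariate screen with Benjamini-Hochberg correction
#'
#' Two-sided Mann-Whitney U test per feature (exact enumeration when both
#' groups have at most 8 lesions and no ties; normal approximation with
#' tie correction otherwise), BH adjustment jointly across all tested
#' features (both sequences pooled by default), retention at adjusted
#' p < alpha.
#'
#' @param table a feature table with a `label` column (`WT`/`MT`).
#' @param cfg a [selection_config].
#' @param features feature subset to test (default all feature columns).
#' @return List with `retained`, `p_raw`, `p_adjusted` (named vectors).
#' @export
univariate_screen <- function(table, cfg = selection_config(),
                              features = feature_names(table)) {
  lab <- table$label
  stop_if_not(length(unique(lab)) == 2, "both classes must be present")
  g1 <- lab == "WT"
  n1 <- sum(g1)
  n2 <- sum(!g1)
  p_raw <- vapply(features, function(f) {
    x <- table[[f]][g1]
    y <- table[[f]][!g1]
    exact <- n1 <= 8 && n2 <= 8 && !anyDuplicated(c(x, y))
    suppressWarnings(wilcox.test(x, y, exact = exact,
                                 correct = !exact)$p.value)
  }, 0)
  p_raw[is.na(p_raw)] <- 1 # zero-variance feature: no evidence
  p_adj <- if (cfg$bh_scope == "joint") {
    p.adjust(p_raw, method = "BH")
  } else {
    seqs <- sub("\\|.*$", "", features)
    out <- p_raw
    for (s in unique(seqs)) {
      out[seqs == s] <- p.adjust(p_raw[seqs == s], method = "BH")
    }
    out
  }
  # alpha = 1 is the documented degenerate setting that disables the screen
  keep <- if (cfg$alpha >= 1) rep(TRUE, length(features)) else
    p_adj < cfg$alpha
  list(retained = features[keep], p_raw = p_raw, p_adjusted = p_adj)
}

#' Spearman redundancy pruning
#'
#' Computes all pairwise Spearman correlations among the given features;
#' pairs with |rho| above the threshold are processed in decreasing |rho|
#' order, and within each pair whose members both still survive, the
#' feature with the larger univariate p-value is eliminated (ties break to
#' the lexicographically later name). Deterministic.
#'
#' @param table a feature table.
#' @param pvalues named vector of univariate p-values for the features.
#' @param cfg a [selection_config].
#' @param features features to prune (default: names of `pvalues`).
#' @return List with `retained` and `eliminated` (data.frame of pair, rho,
#'   dropped member).
#' @export
drop_redundant <- function(table, pvalues, cfg = selection_config(),
                           features = names(pvalues)) {
  if (length(features) < 2) {
    return(list(retained = features,
                eliminated = data.frame(feature_a = character(),
                                        feature_b = character(),
                                        rho = numeric(),
                                        dropped = character())))
  }
  x <- as.matrix(table[, features, drop = FALSE])
  rho <- suppressWarnings(cor(x, method = "spearman"))
  rho[is.na(rho)] <- 0
  ut <- which(upper.tri(rho) & abs(rho) > cfg$spearman_threshold,
              arr.ind = TRUE)
  if (nrow(ut) > 0) {
    ord <- order(-abs(rho[ut]), features[ut[, 1]], features[ut[, 2]])
    ut <- ut[ord, , drop = FALSE]
  }
  alive <- setNames(rep(TRUE, length(features)), features)
  elim <- list()
  for (r in seq_len(nrow(ut))) {
    a <- features[ut[r, 1]]
    b <- features[ut[r, 2]]
    if (!alive[a] || !alive[b]) next
    pa <- pvalues[a]
    pb <- pvalues[b]
    drop <- if (pa > pb) a
            else if (pb > pa) b
            else max(a, b) # tie: lexicographically later name
    alive[drop] <- FALSE
    elim[[length(elim) + 1]] <- data.frame(feature_a = a, feature_b = b,
                                           rho = rho[ut[r, 1], ut[r, 2]],
                                           dropped = drop,
                                           stringsAsFactors = FALSE)
  }
  list(retained = features[alive[features]],
       eliminated = if (length(elim)) do.call(rbind, elim) else
         data.frame(feature_a = character(), feature_b = character(),
                    rho = numeric(), dropped = character()))
}

# stratified fold ids, seeded
stratified_foldid <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Fit the LASSO Radiomic Score model
#'
#' Features are z-standardized with training means/SDs (stored in the
#' model so test rows are standardized with training parameters only);
#' an L1-penalized logistic regression (WT encoded 1, so scores are higher
#' for WT) is fit over a lambda path and lambda is chosen minimizing the
#' mean cross-validated binomial deviance over seeded, class-stratified
#' folds. Only features with nonzero coefficients enter the model.
#'
#' @param train a feature table (training rows).
#' @param cfg a [selection_config].
#' @param features candidate features (default all feature columns).
#' @return A `score_model`: `intercept`, `coefficients` (named),
#'   `standardization` (data.frame feature/mean/sd), `lambda`.
#' @export
fit_lasso_score <- function(train, cfg = selection_config(),
                            features = feature_names(train)) {
  lab <- train$label
  y <- as.integer(lab == "WT")
  stop_if_not(min(table(lab)) >= cfg$cv_folds,
              "need at least `cv_folds` rows per class")
  stop_if_not(length(features) >= 2,
              "LASSO needs at least 2 candidate features")
  x <- as.matrix(train[, features, drop = FALSE])
  mu <- colMeans(x)
  sdev <- apply(x, 2, pop_sd)
  stop_if_not(all(sdev > 0), "zero-variance feature among candidates")
  xs <- scale(x, center = mu, scale = sdev)
  foldid <- stratified_foldid(lab, cfg$cv_folds, cfg$seed)
  cvfit <- glmnet::cv.glmnet(xs, y, family = "binomial",
                             type.measure = "deviance", foldid = foldid,
                             standardize = FALSE, alpha = 1)
  lambda <- if (cfg$lambda_rule == "min") cvfit$lambda.min else
    cvfit$lambda.1se
  co <- as.matrix(stats::coef(cvfit, s = lambda))[, 1]
  nz <- co[-1][co[-1] != 0]
  stop_if_not(length(nz) > 0,
              "no nonzero coefficients at the selected lambda; inspect the ",
              "lambda path (cv.glmnet object) and consider lambda_rule")
  structure(list(intercept = unname(co[1]),
                 coefficients = nz,
                 standardization = data.frame(
                   feature = names(nz), mean = mu[names(nz)],
                   sd = sdev[names(nz)], row.names = NULL,
                   stringsAsFactors = FALSE),
                 lambda = lambda,
                 cv = data.frame(lambda = cvfit$lambda, cvm = cvfit$cvm,
                                 cvsd = cvfit$cvsd)),
            class = "score_model")
}

#' Construct a Radiomic Score model from explicit parameters
#'
#' Useful for worked examples and for applying externally reported coefficients:
#' the score is `I + sum_y C_y * V_y` with `V_y` the standardized feature
#' value.
#'
#' @param intercept model intercept I.
#' @param coefficients named numeric vector of coefficients C_y.
#' @param means,sds training means and SDs per feature (default 0/1:
#'   coefficients apply to already-standardized values).
#' @return A `score_model`.
#' @export
score_model <- function(intercept, coefficients, means = NULL, sds = NULL) {
  fn <- names(coefficients)
  stop_if_not(!is.null(fn) && all(nzchar(fn)), "coefficients must be named")
  means <- means %||% setNames(rep(0, length(fn)), fn)
  sds <- sds %||% setNames(rep(1, length(fn)), fn)
  stop_if_not(all(sds > 0), "standardization SDs must be positive")
  structure(list(intercept = intercept,
                 coefficients = coefficients,
                 standardization = data.frame(feature = fn,
                                              mean = unname(means[fn]),
                                              sd = unname(sds[fn]),
                                              row.names = NULL,
                                              stringsAsFactors = FALSE),
                 lambda = NA_real_),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat("<score_model> intercept ", signif(x$intercept, 4), ", ",
      length(x$coefficients), " feature(s)\n", sep = "")
  for (f in names(x$coefficients)) {
    cat("  ", f, ": ", signif(x$coefficients[[f]], 4), "\n", sep = "")
  }
  invisible(x)
}

#' Evaluate the Radiomic Score
#'
#' `score = I + sum_y C_y * V_y`, with `V_y` the feature value
#' standardized by the model's stored training mean/SD.
#'
#' @param model a `score_model`.
#' @param features named numeric vector, or a feature table (data.frame);
#'   must contain every model feature.
#' @return Numeric score (one per row for a table).
#' @export
radiomic_score <- function(model, features) {
  fn <- names(model$coefficients)
  if (is.data.frame(features)) {
    missing <- setdiff(fn, colnames(features))
    stop_if_not(length(missing) == 0,
                "missing feature(s): ", paste(missing, collapse = ", "))
    x <- as.matrix(features[, fn, drop = FALSE])
  } else {
    missing <- setdiff(fn, names(features))
    stop_if_not(length(missing) == 0,
                "missing feature(s): ", paste(missing, collapse = ", "))
    x <- matrix(features[fn], nrow = 1, dimnames = list(NULL, fn))
  }
  st <- model$standardization
  v <- scale(x, center = setNames(st$mean, st$feature)[fn],
             scale = setNames(st$sd, st$feature)[fn])
  as.numeric(model$intercept + v %*% model$coefficients[fn])
}

#' Run the full feature-reduction cascade on a training table
#'
#' ICC gate (over the re-segmentation subset) -> Mann-Whitney + BH screen
#' -> Spearman pruning -> LASSO score model. Each stage's retained set is
#' a subset of the previous stage's.
#'
#' @param train training feature table.
#' @param reseg1,reseg2 feature tables of the stability subset under the
#'   original and repeated segmentation (NULL skips the ICC gate).
#' @param cfg a [selection_config].
#' @return List with per-stage results (`icc`, `screen`, `redundancy`,
#'   `model`) and `stages` (named retained counts). `model` is NULL when
#'   nothing survives to, or within, the LASSO.
#' @export
run_selection_cascade <- function(train, reseg1 = NULL, reseg2 = NULL,
                                  cfg = selection_config()) {
  fn <- feature_names(train)
  icc_res <- NULL
  if (!is.null(reseg1)) {
    icc_res <- icc_stability_filter(reseg1, reseg2, cfg)
    fn <- intersect(fn, icc_res$retained)
  }
  scr <- univariate_screen(train, cfg, features = fn)
  red <- drop_redundant(train, scr$p_raw[scr$retained], cfg,
                        features = scr$retained)
  model <- NULL
  if (length(red$retained) >= 2) {
    model <- tryCatch(
      fit_lasso_score(train, cfg, features = red$retained),
      error = function(e) NULL)
  }
  list(icc = icc_res, screen = scr, redundancy = red, model = model,
       stages = c(input = length(feature_names(train)),
                  icc = length(fn),
                  screen = length(scr$retained),
                  redundancy = length(red$retained),
                  lasso = if (is.null(model)) 0L else
                    length(model$coefficients)))
}
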