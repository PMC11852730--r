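#' Class-stratified train/test split
#'
#' Per class, `ceil(n/4)` lesions are sampled (without replacement, under
#' the seed) into the test set — the "one-third of the training set"
#' allocation that sends 66 WT + 40 MT to 79 training and 27 testing
#' lesions.
#'
#' @param labels character vector of class labels.
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, seed = 1) {
  tab <- table(labels)
  stop_if_not(length(tab) >= 2 && all(tab >= 2),
              "each class needs at least 2 members")
  with_seed(seed, {
    test <- integer(0)
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      test <- c(test, sort(sample(idx, ceiling(length(idx) / 4))))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

#' AUC with DeLong confidence interval
#'
#' AUC by the Mann-Whitney estimator (ties count 1/2) for the convention
#' that scores are higher in WT; if that gives AUC < 0.5 the orientation
#' is flipped (reported in `direction`). The 95% CI and the p-value
#' against AUC = 0.5 use the DeLong variance estimate.
#'
#' @param scores numeric scores.
#' @param labels class labels (`WT`/`MT`).
#' @return List: `auc`, `ci` (length 2), `p`, `direction` (`"WT-high"` or
#'   `"MT-high"`), `se`.
#' @export
roc_auc_ci <- function(scores, labels) {
  x <- scores[labels == "WT"]
  y <- scores[labels == "MT"]
  stop_if_not(length(x) > 0 && length(y) > 0, "both classes must be present")
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  direction <- "WT-high"
  if (auc < 0.5) {
    psi <- 1 - psi
    auc <- 1 - auc
    direction <- "MT-high"
  }
  v10 <- rowMeans(psi)
  v01 <- colMeans(psi)
  vr <- if (length(x) > 1) var(v10) / length(x) else 0
  vc <- if (length(y) > 1) var(v01) / length(y) else 0
  se <- sqrt(vr + vc)
  ci <- pmin(pmax(auc + c(-1, 1) * qnorm(0.975) * se, 0), 1)
  p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se) else
    as.numeric(auc == 0.5)
  list(auc = auc, ci = ci, p = p, direction = direction, se = se)
}

#' Optimal score cut-off by Youden's J
#'
#' Sweeps the midpoints of consecutive sorted unique scores and maximizes
#' J = Se + Sp - 1, with MT called at scores below the threshold (scores
#' are higher in WT). Ties resolve to the candidate nearest the overall
#' score median.
#'
#' @param scores numeric scores.
#' @param labels class labels (`WT`/`MT`).
#' @return List: `threshold`, `direction` (`"<"`: MT below), `youden_j`.
#' @export
optimal_cutoff <- function(scores, labels) {
  stop_if_not(length(unique(labels)) == 2, "both classes must be present")
  u <- sort(unique(scores))
  cand <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else u
  mt <- scores[labels == "MT"]
  wt <- scores[labels == "WT"]
  j <- vapply(cand, function(t) mean(mt < t) + mean(wt >= t) - 1, 0)
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.min(abs(cand[best] - median(scores)))]
  list(threshold = cand[pick], direction = "<", youden_j = j[pick])
}

log_lr_ci <- function(lr, tp, fn, fp, tn, positive = TRUE) {
  # log-method CI (Simel); 0.5 continuity correction if any cell is empty,
  # and a one-sided interval when the point estimate itself is degenerate
  degenerate <- !is.finite(lr) || lr == 0
  if (degenerate) {
    cc <- 0.5
    tp <- tp + cc; fn <- fn + cc; fp <- fp + cc; tn <- tn + cc
    lr_c <- if (positive) (tp / (tp + fn)) / (fp / (fp + tn)) else
      (fn / (tp + fn)) / (tn / (fp + tn))
  } else {
    lr_c <- lr
  }
  se <- if (positive) {
    sqrt(1 / tp - 1 / (tp + fn) + 1 / fp - 1 / (fp + tn))
  } else {
    sqrt(1 / fn - 1 / (tp + fn) + 1 / tn - 1 / (fp + tn))
  }
  ci <- exp(log(lr_c) + c(-1, 1) * qnorm(0.975) * se)
  if (degenerate && (!is.finite(lr))) ci[2] <- Inf
  if (degenerate && identical(lr, 0)) ci[1] <- 0
  ci
}

#' Diagnostic performance report at a cut-off
#'
#' MT is the positive (detected) class, called at scores below the
#' threshold. Sensitivity and specificity (percent) carry Clopper-Pearson
#' exact 95% CIs; likelihood ratios carry log-method CIs (continuity
#' corrected when a cell is empty; an LR with a zero denominator is
#' reported infinite).
#'
#' @param scores numeric scores.
#' @param labels class labels (`WT`/`MT`).
#' @param cutoff list from [optimal_cutoff()] (or a number).
#' @return A `diagnostic_report` list.
#' @export
diagnostic_metrics <- function(scores, labels, cutoff) {
  thr <- if (is.list(cutoff)) cutoff$threshold else cutoff
  pred_mt <- scores < thr
  is_mt <- labels == "MT"
  tp <- sum(pred_mt & is_mt)
  fn <- sum(!pred_mt & is_mt)
  fp <- sum(pred_mt & !is_mt)
  tn <- sum(!pred_mt & !is_mt)
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  se_ci <- as.numeric(binom.test(tp, tp + fn)$conf.int)
  sp_ci <- as.numeric(binom.test(tn, tn + fp)$conf.int)
  pos_lr <- if (sp < 1) se / (1 - sp) else Inf
  neg_lr <- if (sp > 0) (1 - se) / sp else Inf
  roc <- roc_auc_ci(scores, labels)
  structure(list(auc = roc$auc, auc_ci = roc$ci, auc_p = roc$p,
                 cutoff = thr, direction = "<",
                 sensitivity = 100 * se, sensitivity_ci = 100 * se_ci,
                 specificity = 100 * sp, specificity_ci = 100 * sp_ci,
                 pos_lr = pos_lr,
                 pos_lr_ci = log_lr_ci(pos_lr, tp, fn, fp, tn, TRUE),
                 neg_lr = neg_lr,
                 neg_lr_ci = log_lr_ci(neg_lr, tp, fn, fp, tn, FALSE),
                 counts = c(tp = tp, fn = fn, fp = fp, tn = tn)),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  fmt <- function(v, ci) sprintf("%.2f (%.2f-%.2f)", v, ci[1], ci[2])
  cat("Cut-off  < ", signif(x$cutoff, 4), " calls MT\n",
      "Se%  ", fmt(x$sensitivity, x$sensitivity_ci), "\n",
      "Sp%  ", fmt(x$specificity, x$specificity_ci), "\n",
      "+LR  ", fmt(x$pos_lr, x$pos_lr_ci), "\n",
      "-LR  ", fmt(x$neg_lr, x$neg_lr_ci), "\n",
      "AUC  ", sprintf("%.3f (%.3f-%.3f), p = %.4g", x$auc, x$auc_ci[1],
                       x$auc_ci[2], x$auc_p), "\n", sep = "")
  invisible(x)
}
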