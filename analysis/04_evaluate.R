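#!/usr/bin/env Rscript

# Stage 4: diagnostic evaluation of the Radiomic Score.
#
# Scores the training and held-out test lesions with the fitted model,
# picks the Youden-optimal cut-off per set (malignant called below the
# threshold; scores are higher for Warthin-like lesions), and reports
# AUC with DeLong 95% CI, sensitivity/specificity with Clopper-Pearson
# CIs, and likelihood ratios with log-method CIs. ROC points go to CSV.

suppressPackageStartupMessages(library(paromics))

features <- read.csv(file.path("results", "features.csv"),
                     check.names = FALSE, stringsAsFactors = FALSE)
mj <- jsonlite::read_json(file.path("results", "score_model.json"),
                          simplifyVector = TRUE)
sel <- jsonlite::read_json(file.path("results", "selection_report.json"),
                           simplifyVector = TRUE)
model <- score_model(mj$intercept, unlist(mj$coefficients),
                     means = setNames(mj$standardization$mean,
                                      mj$standardization$feature),
                     sds = setNames(mj$standardization$sd,
                                    mj$standardization$feature))

train <- features[sel$split$train, ]
test <- features[sel$split$test, ]
s_train <- radiomic_score(model, train)
s_test <- radiomic_score(model, test)

report <- function(scores, labels, set) {
  rep_ <- diagnostic_metrics(scores, labels, optimal_cutoff(scores, labels))
  cat("\n==", set, "set ==\n")
  print(rep_)
  rep_
}
r_train <- report(s_train, train$label, "training")
r_test <- report(s_test, test$label, "testing")

roc_points <- function(scores, labels) {
  thr <- sort(unique(scores))
  do.call(rbind, lapply(thr, function(t) {
    data.frame(threshold = t,
               sensitivity = mean(scores[labels == "MT"] < t),
               one_minus_specificity = mean(scores[labels == "WT"] < t))
  }))
}
write.csv(rbind(cbind(set = "training", roc_points(s_train, train$label)),
                cbind(set = "testing", roc_points(s_test, test$label))),
          file.path("results", "roc_points.csv"), row.names = FALSE)

fmt <- function(v, ci) sprintf("%.2f (%.2f-%.2f)", v, ci[1], ci[2])
tab <- data.frame(
  set = c("training", "testing"),
  cutoff = sprintf("<%.3f", c(r_train$cutoff, r_test$cutoff)),
  se = c(fmt(r_train$sensitivity, r_train$sensitivity_ci),
         fmt(r_test$sensitivity, r_test$sensitivity_ci)),
  sp = c(fmt(r_train$specificity, r_train$specificity_ci),
         fmt(r_test$specificity, r_test$specificity_ci)),
  pos_lr = c(fmt(r_train$pos_lr, r_train$pos_lr_ci),
             fmt(r_test$pos_lr, r_test$pos_lr_ci)),
  neg_lr = c(fmt(r_train$neg_lr, r_train$neg_lr_ci),
             fmt(r_test$neg_lr, r_test$neg_lr_ci)),
  auc = c(sprintf("%.3f (%.3f-%.3f)", r_train$auc, r_train$auc_ci[1],
                  r_train$auc_ci[2]),
          sprintf("%.3f (%.3f-%.3f)", r_test$auc, r_test$auc_ci[1],
                  r_test$auc_ci[2])))
write.csv(tab, file.path("results", "diagnostic_table.csv"),
          row.names = FALSE)
cat("\nWrote results/roc_points.csv and results/diagnostic_table.csv\n")
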