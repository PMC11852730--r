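#!/usr/bin/env Rscript

# Stage 3: feature-reduction cascade and Radiomic Score fit.
#
# On the training split only (one-third of each class held out by the
# ceil(n/4) rule): ICC(A,1) stability gate at 0.85 over the re-segmented
# subset, Mann-Whitney screen with Benjamini-Hochberg correction at
# adjusted p < 0.05, Spearman redundancy pruning at |rho| > 0.9 (larger
# univariate p eliminated), and a LASSO logistic model at the 10-fold
# cross-validated minimum-deviance lambda. The surviving coefficients
# define the Radiomic Score.

suppressPackageStartupMessages(library(paromics))

features <- read.csv(file.path("results", "features.csv"),
                     check.names = FALSE, stringsAsFactors = FALSE)
reseg1 <- read.csv(file.path("results", "features_stability_seg1.csv"),
                   check.names = FALSE, stringsAsFactors = FALSE)
reseg2 <- read.csv(file.path("results", "features_stability_seg2.csv"),
                   check.names = FALSE, stringsAsFactors = FALSE)

seed <- 20260923L
split <- stratified_split(features$label, seed = seed)
train <- features[split$train, ]
cascade <- run_selection_cascade(train, reseg1, reseg2,
                                 selection_config(seed = seed))

cat("Cascade retention:\n")
print(cascade$stages)
if (!is.null(cascade$model)) {
  cat("\nRadiomic Score model:\n")
  print(cascade$model)
}

# artifacts are text-only: JSON for the model and report
model <- cascade$model
jsonlite::write_json(
  list(intercept = model$intercept,
       coefficients = as.list(model$coefficients),
       standardization = model$standardization,
       lambda = model$lambda),
  file.path("results", "score_model.json"), auto_unbox = TRUE, digits = NA)
jsonlite::write_json(
  list(stages = as.list(cascade$stages),
       icc = as.list(cascade$icc$icc),
       p_adjusted = as.list(cascade$screen$p_adjusted),
       eliminated = cascade$redundancy$eliminated,
       split = split),
  file.path("results", "selection_report.json"), auto_unbox = TRUE,
  digits = NA)
cat("\nWrote results/score_model.json and results/selection_report.json\n")
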