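test_that("stratified split reproduces the ceil(n/4) allocation", {
  labels <- c(rep("WT", 66), rep("MT", 40))
  sp <- stratified_split(labels, seed = 3)
  expect_length(sp$train, 79)
  expect_length(sp$test, 27)
  expect_equal(sum(labels[sp$train] == "WT"), 49)
  expect_equal(sum(labels[sp$train] == "MT"), 30)
  expect_equal(sum(labels[sp$test] == "WT"), 17)
  expect_equal(sum(labels[sp$test] == "MT"), 10)
  expect_equal(sort(c(sp$train, sp$test)), 1:106)
  # 4 + 4 -> 1 + 1 test
  sp2 <- stratified_split(c(rep("WT", 4), rep("MT", 4)), seed = 1)
  expect_length(sp2$test, 2)
  # determinism
  expect_identical(stratified_split(labels, seed = 9),
                   stratified_split(labels, seed = 9))
  expect_error(stratified_split(c("WT", "WT", "MT"), 1), "at least 2")
})

test_that("AUC follows the Mann-Whitney pair-counting estimator", {
  scores <- c(3, 2, 1, 2)
  labels <- c("WT", "WT", "MT", "MT")
  r <- roc_auc_ci(scores, labels)
  expect_equal(r$auc, 0.875) # (1 + 1 + 1 + 0.5) / 4
  # perfect separation
  expect_equal(roc_auc_ci(c(5, 6, 1, 2), labels)$auc, 1)
  # uninformative
  flat <- roc_auc_ci(rep(1, 4), labels)
  expect_equal(flat$auc, 0.5)
  expect_equal(flat$ci, c(0.5, 0.5))
})

test_that("AUC equals brute-force pair counting on random inputs", {
  withr::with_seed(101, {
    for (rep in 1:20) {
      n1 <- sample(2:25, 1)
      n2 <- sample(2:25, 1)
      s <- c(rnorm(n1), rnorm(n2, 0.5))
      if (runif(1) < 0.3) s <- round(s) # force ties
      lab <- c(rep("WT", n1), rep("MT", n2))
      got <- roc_auc_ci(s, lab)
      x <- s[1:n1]
      y <- s[-(1:n1)]
      cnt <- 0
      for (i in 1:n1) for (j in 1:n2) {
        cnt <- cnt + (x[i] > y[j]) + 0.5 * (x[i] == y[j])
      }
      want <- cnt / (n1 * n2)
      expect_equal(got$auc, max(want, 1 - want), tolerance = 1e-12)
    }
  })
})

test_that("DeLong CI and p agree with pROC", {
  skip_if_not_installed("pROC")
  withr::with_seed(103, {
    s <- c(rnorm(30, 1), rnorm(20))
    lab <- c(rep("WT", 30), rep("MT", 20))
  })
  got <- roc_auc_ci(s, lab)
  ref <- pROC::roc(response = lab, predictor = s, levels = c("MT", "WT"),
                   direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
  expect_equal(got$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(got$ci[1], ci[1], tolerance = 1e-9)
  expect_equal(got$ci[2], ci[3], tolerance = 1e-9)
})

test_that("Youden cut-off lands at the documented thresholds", {
  # clear separation: midpoint between the classes
  r <- optimal_cutoff(c(1, 2, 3, -2, -1),
                      c("WT", "WT", "WT", "MT", "MT"))
  expect_equal(r$threshold, 0)
  expect_equal(r$youden_j, 1)
  expect_equal(r$direction, "<")
  # identical distributions: J = 0, threshold near the median
  r2 <- optimal_cutoff(c(1, 2, 1, 2), c("WT", "WT", "MT", "MT"))
  expect_equal(r2$youden_j, 0)
  expect_equal(r2$threshold, 1.5)
})

test_that("Youden J is invariant under strictly monotone transforms", {
  withr::with_seed(107, {
    s <- rnorm(40)
    lab <- sample(c("WT", "MT"), 40, replace = TRUE, prob = c(0.6, 0.4))
  })
  j1 <- optimal_cutoff(s, lab)$youden_j
  j2 <- optimal_cutoff(exp(s), lab)$youden_j
  j3 <- optimal_cutoff(atan(s) * 3 + 2, lab)$youden_j
  expect_equal(j1, j2, tolerance = 1e-12)
  expect_equal(j1, j3, tolerance = 1e-12)
})

test_that("likelihood-ratio arithmetic matches reference worked examples", {
  # 23/31 sensitivity, 26/32 specificity: Se 74.19, Sp 81.25
  scores <- c(rep(-1, 23), rep(1, 8),   # MT: 23 below cut-off
              rep(-1, 6), rep(1, 26))   # WT: 26 at/above
  labels <- c(rep("MT", 31), rep("WT", 32))
  rep_ <- diagnostic_metrics(scores, labels, list(threshold = 0))
  expect_equal(round(rep_$sensitivity, 2), 74.19)
  expect_equal(rep_$specificity, 81.25)
  expect_equal(round(rep_$pos_lr, 2), 3.96)
  expect_equal(round(rep_$neg_lr, 2), 0.32)
  # 21/31 sensitivity with the same specificity: +LR 3.61
  scores2 <- c(rep(-1, 21), rep(1, 10), rep(-1, 6), rep(1, 26))
  rep2 <- diagnostic_metrics(scores2, labels, list(threshold = 0))
  expect_equal(round(rep2$sensitivity, 2), 67.74)
  expect_equal(round(rep2$pos_lr, 2), 3.61)
})

test_that("perfect classifier yields exact Clopper-Pearson bounds", {
  scores <- c(rep(-1, 10), rep(1, 10))
  labels <- c(rep("MT", 10), rep("WT", 10))
  r <- diagnostic_metrics(scores, labels, list(threshold = 0))
  expect_equal(r$sensitivity, 100)
  expect_equal(r$specificity, 100)
  expect_equal(r$sensitivity_ci[1], 100 * 0.025^(1 / 10), tolerance = 1e-6)
  expect_true(is.infinite(r$pos_lr))
  expect_true(is.infinite(r$pos_lr_ci[2]))
})

test_that("report arithmetic is self-consistent", {
  withr::with_seed(109, {
    for (rep in 1:10) {
      s <- rnorm(30)
      lab <- c(rep("WT", 18), rep("MT", 12))
      r <- diagnostic_metrics(s, lab, optimal_cutoff(s, lab))
      se <- r$sensitivity / 100
      sp <- r$specificity / 100
      if (is.finite(r$pos_lr)) {
        expect_equal(r$pos_lr * (1 - sp), se, tolerance = 1e-12)
      }
      if (is.finite(r$neg_lr)) {
        expect_equal(r$neg_lr * sp, 1 - se, tolerance = 1e-12)
      }
      expect_gte(r$auc, 0.5)
    }
  })
})
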