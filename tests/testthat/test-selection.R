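# The selection cascade operates on plain feature tables, so these tests
# fabricate tables directly instead of running image extraction.

fake_table <- function(n_wt, n_mt, feats) {
  df <- data.frame(lesion_id = sprintf("L%03d", seq_len(n_wt + n_mt)),
                   patient_id = sprintf("P%03d", seq_len(n_wt + n_mt)),
                   label = c(rep("WT", n_wt), rep("MT", n_mt)),
                   stringsAsFactors = FALSE, check.names = FALSE)
  cbind(df, as.data.frame(feats, check.names = FALSE))
}

test_that("ICC(A,1) matches a two-way ANOVA oracle on a worked table", {
  x <- c(1, 2, 3, 4)
  y <- c(1, 2, 3, 6)
  got <- icc_a1(x, y)
  # independent oracle: mean squares from aov() on the long-format table
  d <- data.frame(score = c(x, y),
                  subj = factor(rep(1:4, 2)),
                  rater = factor(rep(1:2, each = 4)))
  ms <- anova(aov(score ~ subj + rater, data = d))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- 4; k <- 2
  want <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(icc_a1(x, x), 1, tolerance = 1e-12)
})

test_that("ICC gate keeps reproducible features and drops noise", {
  withr::with_seed(31, {
    n <- 30
    stable <- rnorm(n, 10, 3)
    t1 <- fake_table(15, 15, list(`T2|original|firstorder|Mean` = stable,
                                  `T2|original|glcm|Contrast` = rnorm(n)))
    t2 <- t1
    t2$`T2|original|firstorder|Mean` <- stable + rnorm(n, 0, 0.1)
    t2$`T2|original|glcm|Contrast` <- rnorm(n)
  })
  res <- icc_stability_filter(t1, t2)
  expect_true("T2|original|firstorder|Mean" %in% res$retained)
  expect_false("T2|original|glcm|Contrast" %in% res$retained)
  expect_lt(res$icc[["T2|original|glcm|Contrast"]], 0.5)
  # identical tables: everything non-constant retained at ICC 1
  res2 <- icc_stability_filter(t1, t1)
  expect_setequal(res2$retained, feature_names(t1))
  # zero-variance feature reports ICC 0 with a warning
  expect_warning(icc_a1(rep(1, 5), rep(1, 5)), "zero-variance")
})

test_that("Mann-Whitney screen reproduces exact enumeration and BH", {
  tab <- fake_table(2, 2, list(f1 = c(1, 2, 3, 4)))
  scr <- univariate_screen(tab, selection_config(alpha = 0.5))
  expect_equal(unname(scr$p_raw["f1"]), 1 / 3, tolerance = 1e-12)
  # BH step-up on (0.01, 0.02, 0.03, 0.04) gives 0.04 everywhere
  expect_equal(unname(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH")),
               rep(0.04, 4))
  # identical feature across classes is retained with adjusted p = 1? no:
  tab2 <- fake_table(5, 5, list(flat = rep(2, 10),
                                good = c(rep(0, 5), rep(10, 5))))
  scr2 <- univariate_screen(tab2)
  expect_equal(unname(scr2$p_adjusted["flat"]), 1)
  expect_false("flat" %in% scr2$retained)
  expect_true("good" %in% scr2$retained)
  one_class <- fake_table(4, 0, list(f = rnorm(4)))
  expect_error(univariate_screen(one_class), "both classes")
})

test_that("BH adjustment is monotone and never below the raw p", {
  withr::with_seed(17, p <- runif(40)^2)
  adj <- p.adjust(p, "BH")
  expect_true(all(adj >= p - 1e-15))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-15))
})

test_that("redundancy pruning drops the higher-p member of each pair", {
  withr::with_seed(41, {
    base <- rnorm(60)
    tab <- fake_table(30, 30, list(a = base, b = base, # duplicated column
                                   c = -base + rnorm(60, 0, 0.05),
                                   d = rnorm(60)))
  })
  pv <- c(a = 0.001, b = 0.01, c = 0.04, d = 0.2)
  res <- drop_redundant(tab, pv)
  expect_true("a" %in% res$retained)   # smallest p of the correlated trio
  expect_false("b" %in% res$retained)
  expect_false("c" %in% res$retained)  # |rho| ~ 0.95 negative, larger p
  expect_true("d" %in% res$retained)
  expect_true(all(res$eliminated$dropped %in% c("b", "c")))
  # independent features all survive
  withr::with_seed(42, {
    ind <- fake_table(50, 50, lapply(setNames(1:6, paste0("g", 1:6)),
                                     function(i) rnorm(100)))
  })
  pv2 <- setNames(runif(6), paste0("g", 1:6))
  expect_length(drop_redundant(ind, pv2)$retained, 6)
})

test_that("LASSO finds a planted separator among noise and is seeded", {
  withr::with_seed(51, {
    n <- 80
    lab <- c(rep("WT", 40), rep("MT", 40))
    signal <- ifelse(lab == "WT", 1, -1) * 2 + rnorm(n, 0, 0.5)
    feats <- c(list(signal = signal),
               lapply(setNames(1:50, paste0("noise", 1:50)),
                      function(i) rnorm(n)))
    tab <- fake_table(40, 40, feats)
  })
  m <- fit_lasso_score(tab, selection_config(seed = 5))
  expect_true("signal" %in% names(m$coefficients))
  noise_nonzero <- sum(grepl("^noise", names(m$coefficients)))
  expect_lte(noise_nonzero, 5) # >= 90% of the 50 noise features are zero
  m2 <- fit_lasso_score(tab, selection_config(seed = 5))
  expect_identical(m$coefficients, m2$coefficients)
  expect_identical(m$lambda, m2$lambda)
  # WT is encoded 1: the WT-positive feature gets a positive weight
  expect_gt(m$coefficients[["signal"]], 0)
})

test_that("effect-free tables are heavily penalized by the CV deviance", {
  small_sets <- withr::with_seed(61, {
    vapply(1:15, function(r) {
      feats <- lapply(setNames(1:20, paste0("f", 1:20)),
                      function(i) rnorm(40))
      tab <- fake_table(20, 20, feats)
      m <- tryCatch(fit_lasso_score(tab, selection_config(seed = r)),
                    error = function(e) NULL)
      if (is.null(m)) 0L else length(m$coefficients)
    }, 0L)
  })
  expect_gte(mean(small_sets <= 3), 0.8)
})

test_that("the Radiomic Score evaluates its linear form exactly", {
  cf <- c(`T2|log-sigma-3mm|glszm|GrayLevelVariance` = -0.765,
          `ADC|wavelet-HLL|firstorder|RootMeanSquared` = 0.24,
          `T2|wavelet-LLH|glrlm|HighGrayLevelRunEmphasis` = 1.654)
  m <- score_model(intercept = -0.895, coefficients = cf)
  zero <- setNames(rep(0, 3), names(cf))
  expect_equal(radiomic_score(m, zero), -0.895)
  v1 <- setNames(c(1, 0, 0), names(cf))
  expect_equal(radiomic_score(m, v1), -0.895 - 0.765)
  # linearity with a single coefficient
  m2 <- score_model(0, c(f = 2))
  expect_equal(radiomic_score(m2, c(f = 3)), 6)
  expect_error(radiomic_score(m, c(bogus = 1)), "missing feature")
  # standardization is applied from stored training parameters
  m3 <- score_model(0, c(f = 1), means = c(f = 10), sds = c(f = 2))
  expect_equal(radiomic_score(m3, c(f = 14)), 2)
})

test_that("cascade stages are nested and leakage-guarded", {
  withr::with_seed(71, {
    n <- 60
    lab_sig <- ifelse(seq_len(n) <= 30, 1, -1)
    feats <- list(s1 = lab_sig + rnorm(n, 0, 0.7),
                  s2 = lab_sig + rnorm(n, 0, 0.7),
                  s3 = rnorm(n), s4 = rnorm(n),
                  s5 = lab_sig + rnorm(n, 0, 0.4))
    feats$s6 <- feats$s5 + rnorm(n, 0, 0.01) # redundant twin
    tab <- fake_table(30, 30, feats)
  })
  res <- run_selection_cascade(tab, cfg = selection_config(seed = 2))
  st <- res$stages
  expect_true(st["icc"] <= st["input"])
  expect_true(st["screen"] <= st["icc"])
  expect_true(st["redundancy"] <= st["screen"])
  expect_true(st["lasso"] <= st["redundancy"])
  expect_true(all(res$redundancy$retained %in% res$screen$retained))
  # model standardization comes from training rows only (by construction):
  # the stored means match the training columns
  m <- res$model
  expect_equal(m$standardization$mean,
               unname(colMeans(tab[names(m$coefficients)])))
})
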