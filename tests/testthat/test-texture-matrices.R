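as_levels <- function(v, dims) {
  lev <- array(as.integer(v), dim = dims)
  attr(lev, "nlevels") <- max(lev)
  lev
}

test_that("GLCM worked example: alternating columns, single direction", {
  # 2x2 in-plane grid with values [[1,2],[1,2]]; pairs along +y only
  lev <- as_levels(c(1, 1, 2, 2), c(2, 2, 1)) # arr[x, y]: column y constant
  off <- matrix(c(0L, 1L, 0L), nrow = 1)
  f <- glcm_features(lev, offsets = off)
  # both pairs are (1,2); symmetrized p(1,2) = p(2,1) = 0.5
  expect_equal(unname(f["JointEnergy"]), 0.5)
  expect_equal(unname(f["Contrast"]), 1)
  expect_equal(unname(f["MaximumProbability"]), 0.5)
})

test_that("GLCM degenerate cases follow the documented conventions", {
  lev <- as_levels(rep(1, 27), c(3, 3, 3))
  f <- glcm_features(lev)
  expect_equal(unname(f["JointEnergy"]), 1)
  expect_equal(unname(f["Contrast"]), 0)
  expect_equal(unname(f["Correlation"]), 1)
  expect_equal(unname(f["MCC"]), 1)
  expect_true(all(is.finite(f)))
  one <- as_levels(1, c(1, 1, 1))
  expect_error(glcm_features(one), "at least 2")
})

test_that("GLRLM worked examples match run enumeration", {
  # lines (column-major): (1,1,2), (2,2,3), (3,3,3); runs along +x
  lev <- as_levels(c(1, 1, 2, 2, 2, 3, 3, 3, 3), c(3, 3, 1))
  off <- matrix(c(1L, 0L, 0L), nrow = 1)
  f <- glrlm_features(lev, offsets = off)
  # runs: (1,2),(2,1),(2,2),(3,1),(3,3) -> HGLRE = (1+4+4+9+9)/5
  expect_equal(unname(f["HighGrayLevelRunEmphasis"]), 5.4)
  expect_equal(unname(f["RunPercentage"]), 5 / 9)
  # constant 1x1x3 ROI, axial direction: one run of length 3
  czy <- as_levels(rep(1, 3), c(1, 1, 3))
  fz <- glrlm_features(czy, offsets = matrix(c(0L, 0L, 1L), nrow = 1))
  expect_equal(unname(fz["HighGrayLevelRunEmphasis"]), 1)
  expect_equal(unname(fz["LongRunEmphasis"]), 9)
})

test_that("GLSZM worked examples match zone enumeration", {
  lev <- as_levels(c(1, 2, 1, 3), c(2, 2, 1)) # [[1,1],[2,3]] layout
  f <- glszm_features(lev)
  # zones: (1, size 2), (2, 1), (3, 1); mean level 2
  expect_equal(unname(f["GrayLevelVariance"]), 2 / 3)
  expect_equal(unname(f["ZonePercentage"]), 3 / 4)
  # all-distinct levels: every zone size 1 -> SmallAreaEmphasis = 1
  lev2 <- as_levels(1:8, c(2, 2, 2))
  expect_equal(unname(glszm_features(lev2)["SmallAreaEmphasis"]), 1)
  # constant ROI: a single zone, zero variance
  lev3 <- as_levels(rep(1, 27), c(3, 3, 3))
  expect_equal(unname(glszm_features(lev3)["GrayLevelVariance"]), 0)
})

test_that("GLDM dependence counts match neighbor enumeration", {
  lev <- as_levels(rep(1, 9), c(3, 3, 1))
  P <- paromics:::cpp_gldm_counts(as.integer(lev), c(3L, 3L, 1L), 1L, 0L)
  # 2D constant 3x3: corners dep 4 (x4), edges dep 6 (x4), centre dep 9
  expect_equal(P[1, 4], 4)
  expect_equal(P[1, 6], 4)
  expect_equal(P[1, 9], 1)
  one <- as_levels(1, c(1, 1, 1))
  f <- gldm_features(one)
  expect_equal(unname(f["SmallDependenceEmphasis"]), 1)
})

test_that("NGTDM matches hand neighbor-mean enumeration", {
  lev <- as_levels(c(1, 2, 2, 2), c(2, 2, 1)) # [[1,2],[2,2]]
  m <- paromics:::cpp_ngtdm(as.integer(lev), c(2L, 2L, 1L), 2L)
  # voxel of level 1 sees neighbors {2,2,2}; each 2 sees one 1
  expect_equal(m[1, 1], 1)   # n_1
  expect_equal(m[1, 2], 1)   # s_1 = |1 - 2|
  expect_equal(m[2, 1], 3)   # n_2
  # each level-2 voxel neighbors {1,2,2}: s_2 = 3 * |2 - 5/3| = 1
  expect_equal(m[2, 2], 1, tolerance = 1e-12)
  # constant ROI conventions
  cst <- as_levels(rep(1, 27), c(3, 3, 3))
  f <- ngtdm_features(cst)
  expect_equal(unname(f["Busyness"]), 0)
  expect_equal(unname(f["Strength"]), 0)
  expect_equal(unname(f["Coarseness"]), 1e6)
})

test_that("all five families equal the brute-force oracle on random grids", {
  withr::with_seed(123, {
    for (rep in 1:12) {
      lev <- random_level_grid(c(6, 6, 6), nlev = sample(2:5, 1),
                               mask_frac = sample(c(1, 0.8, 0.6), 1))
      if (sum(lev > 0) < 8) next
      attr(lev, "nlevels") <- max(lev)
      imp <- all_feature_impls(lev)
      ora <- all_feature_oracles(lev)
      for (fam in names(imp)) {
        expect_equal(imp[[fam]], ora[[fam]], tolerance = 1e-9,
                     info = paste("family", fam, "rep", rep))
      }
    }
  })
})

test_that("texture features are invariant to W-multiple intensity shifts", {
  withr::with_seed(21, {
    v <- array(runif(216, 0, 150), dim = c(6, 6, 6))
  })
  msk <- segmentation_mask(array(TRUE, dim = c(6, 6, 6)), c(1, 1, 1))
  cfg <- preprocess_config()
  l1 <- discretize_roi(volume_image(v, c(1, 1, 1)), msk, cfg)
  l2 <- discretize_roi(volume_image(v + 3 * cfg$bin_width, c(1, 1, 1)),
                       msk, cfg)
  expect_identical(as.vector(l1), as.vector(l2))
  expect_equal(glcm_features(l1), glcm_features(l2))
  expect_equal(glszm_features(l1), glszm_features(l2))
})
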