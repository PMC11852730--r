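flat_vol <- function(value = 200, dims = c(12, 12, 8), spacing = c(1, 1, 1)) {
  volume_image(array(value, dim = dims), spacing)
}

box_mask <- function(dims, spacing = c(1, 1, 1), inset = 2) {
  m <- array(FALSE, dim = dims)
  m[(1 + inset):(dims[1] - inset), (1 + inset):(dims[2] - inset),
    (1 + inset):(dims[3] - inset)] <- TRUE
  segmentation_mask(m, spacing)
}

test_that("bias correction is the identity on an unbiased image", {
  img <- flat_vol(200)
  msk <- box_mask(dim(img$voxels))
  out <- bias_field_correct(img, msk)
  expect_lt(max(abs(out$voxels - img$voxels)) / 200, 1e-6)
})

test_that("bias correction recovers a planted exponential field", {
  dims <- c(24, 24, 12)
  xn <- (seq_len(dims[1]) - 1) / (dims[1] - 1)
  field <- exp(outer(outer(0.4 * xn, rep(1, dims[2])), rep(1, dims[3])))
  img <- volume_image(200 * field, c(1, 1, 1))
  msk <- box_mask(dims)
  out <- bias_field_correct(img, msk)
  # the corrected ROI is flat again (the in-mask mean, not the unbiased
  # 200, is what the corrector preserves)
  err <- out$voxels[msk$voxels] / mean(out$voxels[msk$voxels]) - 1
  expect_lt(sqrt(mean(err^2)), 0.02)
  # in-mask mean preserved
  expect_lt(abs(mean(out$voxels[msk$voxels]) -
                  mean(img$voxels[msk$voxels])) /
              mean(img$voxels[msk$voxels]), 0.01)
})

test_that("bias correction rejects non-positive voxels, naming the count", {
  img <- flat_vol(200)
  img$voxels[6, 6, 4] <- 0
  msk <- box_mask(dim(img$voxels))
  expect_error(bias_field_correct(img, msk), "1 non-positive voxel")
})

test_that("z-score normalization has the advertised mean and spread", {
  withr::with_seed(3, {
    img <- volume_image(array(rnorm(1000, 50, 7), dim = c(10, 10, 10)),
                        c(1, 1, 1))
  })
  out <- normalize_intensity(img)
  expect_lt(abs(mean(out$voxels)), 1e-9)
  expect_equal(sqrt(mean((out$voxels - mean(out$voxels))^2)), 100,
               tolerance = 1e-9)
  # two-point image: population SD 5, so [0, 10] maps to [-100, 100]
  two <- volume_image(array(c(0, 10), dim = c(2, 1, 1)), c(1, 1, 1))
  expect_equal(as.numeric(normalize_intensity(two)$voxels), c(-100, 100))
  expect_error(normalize_intensity(flat_vol(5)), "constant image")
})

test_that("outlier removal excludes the right voxels", {
  # constant ROI: nothing removed
  img <- flat_vol(10)
  msk <- box_mask(dim(img$voxels))
  expect_equal(sum(remove_outlier_voxels(img, msk)$voxels),
               sum(msk$voxels))
  # one +10-sigma voxel among 100 zeros: exactly that voxel removed
  v <- array(0, dim = c(101, 1, 1))
  v[101, 1, 1] <- 10
  img2 <- volume_image(v, c(1, 1, 1))
  msk2 <- segmentation_mask(array(TRUE, dim = c(101, 1, 1)), c(1, 1, 1))
  out2 <- remove_outlier_voxels(img2, msk2)
  expect_equal(which(!out2$voxels), 101L)
  # standard-normal ROI: removed fraction ~ 2*pnorm(-3) = 0.27%
  withr::with_seed(11, {
    big <- volume_image(array(rnorm(1e5), dim = c(100, 100, 10)),
                        c(1, 1, 1))
  })
  mall <- segmentation_mask(array(TRUE, dim = c(100, 100, 10)), c(1, 1, 1))
  frac <- 1 - sum(remove_outlier_voxels(big, mall)$voxels) / 1e5
  expect_lt(abs(frac - 0.0027), 0.001)
})

test_that("isotropic resampling has the contracted geometry", {
  # already isotropic: identity within interpolation tolerance
  withr::with_seed(5, {
    img <- volume_image(array(rnorm(1000), dim = c(10, 10, 10)), c(1, 1, 1))
  })
  msk <- box_mask(c(10, 10, 10))
  out <- resample_isotropic(img, msk)
  expect_equal(dim(out$img$voxels), c(10L, 10L, 10L))
  expect_lt(max(abs(out$img$voxels - img$voxels)), 1e-3)
  # dims follow round(dim * spacing / target)
  img2 <- volume_image(array(1:500, dim = c(10, 10, 5)) + 0,
                       c(2, 2, 3.6))
  msk2 <- box_mask(c(10, 10, 5), spacing = c(2, 2, 3.6), inset = 1)
  out2 <- resample_isotropic(img2, msk2)
  expect_equal(dim(out2$img$voxels), c(20L, 20L, 18L))
  expect_equal(out2$img$spacing_mm, c(1, 1, 1))
  # 15 mm sphere: resampled voxel volume within 5% of the analytic volume
  sph <- sphere_mask(7.5, c(0.7, 0.7, 3))
  vimg <- volume_image(array(100, dim = dim(sph$voxels)), c(0.7, 0.7, 3))
  out3 <- resample_isotropic(vimg, sph)
  vol <- sum(out3$mask$voxels) * 1
  expect_lt(abs(vol - 4 / 3 * pi * 7.5^3) / (4 / 3 * pi * 7.5^3), 0.05)
})

test_that("discretization follows the fixed-bin-width contract", {
  v <- array(c(0, 25, 50, 10), dim = c(4, 1, 1))
  img <- volume_image(v, c(1, 1, 1))
  msk <- segmentation_mask(array(c(TRUE, TRUE, TRUE, FALSE),
                                 dim = c(4, 1, 1)), c(1, 1, 1))
  lev <- discretize_roi(img, msk)
  expect_equal(lev[1:3], c(1L, 2L, 3L))
  expect_equal(lev[4], 0L) # outside mask
  img2 <- volume_image(array(c(0, 24.99, 1, 1), dim = c(4, 1, 1)),
                       c(1, 1, 1))
  expect_equal(discretize_roi(img2, msk)[1:2], c(1L, 1L))
  # constant ROI: single level
  expect_equal(unique(as.vector(
    discretize_roi(flat_vol(7, c(4, 1, 1)), msk)[1:3])), 1L)
  # invariant under adding a multiple of W
  withr::with_seed(8, {
    v3 <- array(runif(64, 0, 200), dim = c(4, 4, 4))
  })
  m3 <- segmentation_mask(array(TRUE, dim = c(4, 4, 4)), c(1, 1, 1))
  l1 <- discretize_roi(volume_image(v3, c(1, 1, 1)), m3)
  l2 <- discretize_roi(volume_image(v3 + 75, c(1, 1, 1)), m3)
  expect_identical(as.vector(l1), as.vector(l2))
})
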