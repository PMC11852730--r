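test_that("LoG kills constants and is linear", {
  img <- volume_image(array(42, dim = c(16, 16, 16)), c(1, 1, 1))
  out <- log_filter(img, 2)
  expect_lt(max(abs(out$voxels)) / 42, 1e-6)
  withr::with_seed(2, {
    a <- volume_image(array(rnorm(16^3), dim = c(16, 16, 16)), c(1, 1, 1))
  })
  r1 <- log_filter(a, 2)$voxels
  a3 <- volume_image(3 * a$voxels, a$spacing_mm)
  expect_lt(max(abs(log_filter(a3, 2)$voxels - 3 * r1)), 1e-6 * max(abs(r1)))
})

test_that("LoG impulse response matches the analytic kernel", {
  n <- 33
  img <- volume_image(array(0, dim = c(n, n, n)), c(1, 1, 1))
  ctr <- 17
  img$voxels[ctr, ctr, ctr] <- 1
  sig <- 2
  out <- log_filter(img, sig)$voxels
  idx <- (ctr - 4):(ctr + 4)
  g <- expand.grid(x = idx, y = idx, z = idx)
  r2 <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2
  analytic <- sig^2 * (r2 - 3 * sig^2) / sig^4 *
    exp(-r2 / (2 * sig^2)) / (2 * pi * sig^2)^1.5
  got <- mapply(function(x, y, z) out[x, y, z], g$x, g$y, g$z)
  expect_lt(max(abs(got - analytic)), 0.05 * max(abs(analytic)))
})

test_that("LoG scale sweep peaks near r/sqrt(3) on a spherical blob", {
  n <- 41
  sp <- c(1, 1, 1)
  ctr <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  r2 <- (g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2
  blob <- volume_image(array(as.numeric(r2 <= 6^2), dim = c(n, n, n)), sp)
  sigmas <- seq(1.5, 6, by = 0.5)
  resp <- vapply(sigmas, function(s) {
    log_filter(blob, s)$voxels[ctr, ctr, ctr]
  }, 0)
  best <- sigmas[which.min(resp)]
  expect_gt(best, 2.4) # 6/sqrt(3) = 3.46
  expect_lt(best, 4.6)
})

test_that("LoG rejects undersampled sigma", {
  img <- volume_image(array(1, dim = c(8, 8, 8)), c(3, 3, 3))
  expect_error(log_filter(img, 1), "undersampled")
})

test_that("wavelet decomposition has 8 same-shape sub-bands with DC in LLL", {
  withr::with_seed(4, {
    img <- volume_image(array(rnorm(10 * 12 * 14), dim = c(10, 12, 14)),
                        c(1, 1, 1))
  })
  wb <- wavelet_subbands(img)
  expect_named(wb, c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))
  for (b in wb) expect_equal(dim(b$voxels), c(10L, 12L, 14L))
  flat <- volume_image(array(5, dim = c(10, 10, 10)), c(1, 1, 1))
  wf <- wavelet_subbands(flat)
  for (nm in names(wf)[-1]) {
    expect_lt(max(abs(wf[[nm]]$voxels)), 1e-10)
  }
  # low-pass taps sum to sqrt(2): LLL of a constant is c * 2^(3/2)
  expect_equal(unique(round(as.vector(wf$LLL$voxels), 9)),
               round(5 * 2^1.5, 9))
})

test_that("sub-band filtering agrees with naive separable convolution", {
  withr::with_seed(6, {
    img <- volume_image(array(rnorm(8^3), dim = c(8, 8, 8)), c(1, 1, 1))
  })
  taps <- paromics:::.wavelet_taps$coif1
  wb <- wavelet_subbands(img)
  ref_lhh <- oracle_conv_axis(
    oracle_conv_axis(oracle_conv_axis(img$voxels, taps$lo, 1), taps$hi, 2),
    taps$hi, 3)
  expect_lt(max(abs(wb$LHH$voxels - ref_lhh)), 1e-6)
  ref_hll <- oracle_conv_axis(
    oracle_conv_axis(oracle_conv_axis(img$voxels, taps$hi, 1), taps$lo, 2),
    taps$lo, 3)
  expect_lt(max(abs(wb$HLL$voxels - ref_hll)), 1e-6)
})

test_that("filter bank yields 11 labeled images and rejects tiny inputs", {
  withr::with_seed(7, {
    img <- volume_image(array(rnorm(12^3), dim = c(12, 12, 12)), c(1, 1, 1))
  })
  fb <- apply_filter_bank(img)
  expect_length(fb, 11)
  expect_named(fb, c("original", paste0("wavelet-", c("LLL", "LLH", "LHL",
                                                      "LHH", "HLL", "HLH",
                                                      "HHL", "HHH")),
                     "log-sigma-3mm", "log-sigma-5mm"))
  small <- volume_image(array(1, dim = c(4, 4, 4)), c(1, 1, 1))
  expect_error(wavelet_subbands(small), "filter length")
})
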