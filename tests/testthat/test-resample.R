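test_that("windowed-sinc kernels are 1 at zero and 0 at nonzero integers", {
  for (mth in c("HWS", "CWS", "WWS", "LWS", "BWS")) {
    expect_equal(kernel_weight(mth, 0), 1, label = mth)
    expect_equal(kernel_weight(mth, c(-3, -2, -1, 1, 2, 3)), rep(0, 6),
                 tolerance = 1e-12, label = mth)
    expect_equal(kernel_weight(mth, 4), 0, label = paste(mth, "outside"))
  }
  # window endpoint values, m = 3: Welch 1-(x/m)^2 -> 0, Hamming -> 0.08
  expect_equal(1 - (3 / 3)^2, 0)
  expect_equal(0.54 + 0.46 * cos(pi), 0.08)
  expect_error(kernel_weight("Linear", 0), "windowed-sinc")
})

test_that("target grid arithmetic matches round(n * d / nuir)", {
  v <- image_volume(array(0, c(512, 512, 2)), c(0.39, 0.39, 1.25))
  expect_equal(target_grid(v, 0.98)$shape, c(204, 204, 2))
  expect_equal(target_grid(v, 0.39)$shape, c(512, 512, 2))
  v1 <- image_volume(array(0, c(1, 1, 1)), c(0.39, 0.39, 1.25))
  expect_equal(target_grid(v1, 5)$shape[1], 1)   # minimum clamp
  expect_error(target_grid(v, -1), "positive")
})

test_that("identity resampling reproduces the input", {
  set.seed(21)
  vol <- image_volume(array(rnorm(20 * 18 * 3, 0, 50), c(20, 18, 3)),
                      spacing = c(0.5, 0.5, 1.25))
  expect_identical(resample_volume(vol, 0.5, "NN")$voxels, vol$voxels)
  for (mth in c("Linear", "BSpline"))
    expect_lt(max(abs(resample_volume(vol, 0.5, mth)$voxels - vol$voxels)),
              1e-9, label = mth)
})

test_that("every method preserves constants to 1e-9", {
  vol <- image_volume(array(42.5, c(17, 19, 2)), c(0.6, 0.6, 1.25))
  for (mth in setdiff(interpolation_methods(), "LabelGaussian")) {
    for (nuir in c(0.39, 0.98)) {
      out <- resample_volume(vol, nuir, mth)
      expect_lt(max(abs(out$voxels - 42.5)), 1e-9,
                label = sprintf("%s at %.2f", mth, nuir))
    }
  }
})

test_that("linear interpolation hits the hand-computed midpoint", {
  # two-sample stripe 0, 10 at 1 mm; at 0.5 mm the second sample sits
  # exactly halfway between the sources -> 5
  vol <- image_volume(array(rep(c(0, 10), each = 1), c(2, 1, 1)),
                      spacing = c(1, 1, 1))
  out <- resample_volume(vol, 0.5, "Linear")
  expect_equal(dim(out$voxels)[1], 4)
  expect_equal(out$voxels[2, 1, 1], 5)
  expect_equal(out$voxels[1, 1, 1], 0)
})

test_that("separable resampler agrees with a direct 2-D reference", {
  set.seed(31)
  for (mth in c("Linear", "NN", "Gaussian", "HWS", "CWS", "WWS", "LWS",
                "BWS")) {
    for (ratio in c(0.61, 1.7)) {
      n <- sample(40:64, 2)
      mat <- matrix(rnorm(prod(n), 0, 100), n[1], n[2])
      vol <- image_volume(array(mat, c(n, 1)), c(1, 1, 1))
      got <- resample_volume(vol, ratio, mth)$voxels[, , 1]
      ref <- oracle_resample_2d(mat, 1, ratio, mth)
      rms <- sqrt(mean((got - ref)^2))
      expect_lt(rms, 1e-4, label = sprintf("%s ratio %.2f", mth, ratio))
    }
  }
})

test_that("windowed-sinc kernels are lowpass with a sharp transition", {
  # |H(f)| of the tabulated kernel: close to 1 in the passband, strongly
  # attenuated beyond the source Nyquist, monotone families intact
  f <- seq(0, 2, by = 0.02)
  x <- seq(-3, 3, by = 1e-3)
  for (mth in c("HWS", "CWS", "WWS", "LWS", "BWS")) {
    k <- kernel_weight(mth, x)
    H <- vapply(f, function(ff) abs(sum(k * cos(2 * pi * ff * x)) * 1e-3), 0)
    expect_gt(min(H[f <= 0.25]), 0.8, label = paste(mth, "passband"))
    expect_lt(max(H[f >= 1]), 0.12, label = paste(mth, "stopband"))
  }
})

test_that("Gaussian resampling smooths more as the target spacing grows", {
  # the Gaussian interpolator's width scales with the output spacing, so
  # white-noise variance decays monotonically with coarser grids
  set.seed(41)
  vol <- image_volume(array(rnorm(64 * 64 * 1, 0, 100), c(64, 64, 1)),
                      spacing = c(1, 1, 1))
  v <- vapply(c(1.2, 1.6, 2.0, 2.6), function(s)
    stats::var(as.vector(resample_volume(vol, s, "Gaussian")$voxels)), 0)
  expect_true(all(diff(v) < 0))
})

test_that("mask resampling never invents labels", {
  set.seed(51)
  labels <- array(sample(c(0L, 2L, 5L), 16 * 16 * 2, replace = TRUE),
                  c(16, 16, 2))
  mask <- roi_mask(labels, c(1, 1, 1.25))
  expect_identical(resample_mask(mask, 1, "NN")$labels, labels)
  for (nuir in c(0.7, 1.9)) {
    for (mth in c("NN", "LabelGaussian")) {
      out <- resample_mask(mask, nuir, mth)
      expect_true(all(out$labels %in% labels),
                  label = sprintf("%s at %.1f", mth, nuir))
    }
  }
  expect_error(resample_volume(mask_to_vol <- image_volume(
    array(0, c(4, 4, 1)), c(1, 1, 1)), 2, "LabelGaussian"), "mask-only")
})

test_that("LabelGaussian keeps a downsampled cube connected", {
  labels <- array(0L, c(20, 20, 2))
  labels[5:16, 5:16, ] <- 3L
  mask <- roi_mask(labels, c(1, 1, 1.25))
  out <- resample_mask(mask, 2, "LabelGaussian")
  lev <- array(NA_integer_, dim(out$labels))
  lev[out$labels == 3L] <- 1L
  zones <- oracle_glszm(lev)
  expect_equal(nrow(zones), 1)          # one connected component survives
  expect_setequal(unique(as.vector(out$labels)), c(0L, 3L))
})
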