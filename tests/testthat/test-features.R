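test_that("fixed-bin-width discretization follows the floor formula", {
  d <- discretize(c(-10, 0, 24, 25, 60), 25)
  expect_equal(d$levels, c(1L, 2L, 2L, 3L, 4L))
  expect_equal(d$ng, 4L)
  expect_equal(discretize(rep(7, 5))$levels, rep(1L, 5))
  expect_equal(discretize(rep(7, 5))$ng, 1L)
  for (seed in 1:5) {
    set.seed(seed)
    expect_equal(min(discretize(rnorm(50, 0, 300))$levels), 1L)
  }
  expect_error(discretize(numeric(0)), "empty")
})

test_that("first-order statistics match hand arithmetic", {
  v <- c(1, 2, 3, 4)
  fo <- first_order_features(v, discretize(v, 1))
  expect_equal(fo[["Mean"]], 2.5)
  expect_equal(fo[["Variance"]], 1.25)      # population 1/n
  expect_equal(fo[["Range"]], 3)
  expect_equal(fo[["Energy"]], 30)
  expect_equal(fo[["RootMeanSquared"]], sqrt(30 / 4))
  # two equally-filled levels -> 1 bit of entropy
  fo2 <- first_order_features(c(0, 0, 25, 25))
  expect_equal(fo2[["Entropy"]], 1)
  expect_equal(fo2[["Uniformity"]], 0.5)
})

test_that("degenerate constant ROI takes the documented conventions", {
  fo <- first_order_features(rep(5, 30))
  expect_equal(fo[["Variance"]], 0)
  expect_equal(fo[["Entropy"]], 0)
  expect_equal(fo[["Uniformity"]], 1)
  expect_equal(fo[["Skewness"]], 0)
  expect_equal(fo[["Kurtosis"]], 0)
  expect_equal(fo[["Mean"]], 5)
  expect_equal(fo[["Median"]], 5)
})

test_that("GLCM on the 2x2 slab matches the enumerated co-occurrences", {
  lev <- array(NA_integer_, c(2, 2, 1))
  lev[1, 1, 1] <- 1L; lev[1, 2, 1] <- 1L
  lev[2, 1, 1] <- 1L; lev[2, 2, 1] <- 2L
  counts <- radstab:::glcm_counts_cpp(lev, 2L)
  P <- counts[, , 2] / sum(counts[, , 2])   # direction (0, 1, 0)
  expect_equal(P, matrix(c(0.5, 0.25, 0.25, 0), 2, 2))
  expect_equal(sum(P^2), 0.375)             # JointEnergy
})

test_that("constant and random GLCMs satisfy their structural laws", {
  lev <- array(1L, c(3, 3, 3))
  f <- glcm_features(radstab:::glcm_counts_cpp(lev, 1L))
  expect_equal(f[["MaximumProbability"]], 1)
  expect_equal(f[["JointEntropy"]], 0)
  expect_equal(f[["Correlation"]], 1)       # single-level convention
  for (seed in 1:5) {
    set.seed(seed)
    lev <- random_level_array(c(5, 4, 3), 4)
    counts <- radstab:::glcm_counts_cpp(lev, 4L)
    for (d in 1:13)
      expect_equal(counts[, , d], t(counts[, , d]))   # symmetry
  }
})

test_that("run-length matrices count runs and conserve voxel mass", {
  lev <- array(c(1L, 1L, 1L), c(3, 1, 1))
  counts <- radstab:::glrlm_counts_cpp(lev, 1L)
  expect_equal(counts[1, 3, 1], 1)          # one x-run of length 3
  expect_equal(sum(counts[, , 1]), 1)
  # single-direction long-run emphasis of that run: (1 * 3^2) / 1 = 9
  lre_x <- sum(counts[1, , 1] * (1:3)^2) / sum(counts[, , 1])
  expect_equal(lre_x, 9)
  for (seed in 1:5) {
    set.seed(seed)
    lev <- random_level_array(c(5, 5, 3), 5)
    counts <- radstab:::glrlm_counts_cpp(lev, 5L)
    np <- sum(!is.na(lev))
    for (d in 1:13) {
      lens <- seq_len(dim(counts)[2])
      expect_equal(sum(sweep(counts[, , d, drop = FALSE], 2, lens, `*`)),
                   np)                      # runs partition the ROI
    }
  }
})

test_that("size zones are 26-connected components of equal level", {
  lev <- array(2L, c(3, 3, 3))
  zones <- radstab:::glszm_zones_cpp(lev)
  expect_equal(nrow(zones), 1)
  expect_equal(zones[1, ], c(2L, 27L))
  # two isolated single-voxel islands of level 2 in a level-1 sea
  lev <- array(1L, c(5, 5, 1))
  lev[1, 1, 1] <- 2L; lev[5, 5, 1] <- 2L
  zones <- radstab:::glszm_zones_cpp(lev)
  expect_equal(sum(zones[, 1] == 2 & zones[, 2] == 1), 2)
  for (seed in 1:5) {
    set.seed(seed)
    lev <- random_level_array(c(5, 4, 4), 3)
    zones <- radstab:::glszm_zones_cpp(lev)
    expect_equal(sum(zones[, 2]), sum(!is.na(lev)))  # zones partition ROI
  }
})

test_that("dependence counts follow the 26-neighbourhood definition", {
  lev <- array(1L, c(3, 3, 3))
  counts <- radstab:::gldm_counts_cpp(lev, 1L, 0L)
  expect_equal(counts[1, 27], 1)            # centre voxel: 26 equal deps
  expect_equal(sum(counts), 27)             # every voxel counted once
  lev1 <- array(NA_integer_, c(3, 3, 3)); lev1[2, 2, 2] <- 1L
  counts1 <- radstab:::gldm_counts_cpp(lev1, 1L, 0L)
  expect_equal(counts1[1, 1], 1)            # lone voxel: dependence 0
})

test_that("NGTDM statistics behave at the degenerate and textured limits", {
  lev <- array(1L, c(4, 4, 2))
  st <- radstab:::ngtdm_stats_cpp(lev, 1L)
  expect_equal(st$s, 0)
  f <- ngtdm_features(st)
  expect_equal(f[["Coarseness"]], 1e6)      # capped
  expect_equal(f[["Contrast"]], 0)
  # two-level checkerboard: both levels see unlike neighbours
  lev <- array(0L, c(4, 4, 2))
  lev[] <- ((slice.index(lev, 1) + slice.index(lev, 2) +
             slice.index(lev, 3)) %% 2) + 1L
  st <- radstab:::ngtdm_stats_cpp(lev, 2L)
  expect_true(all(st$s > 0))
  expect_equal(sum(st$n) / sum(st$n), 1)
  expect_equal(sum(st$n), 32)               # every voxel has neighbours
})

test_that("extraction returns 91 finite features and obeys invariances", {
  roi <- tiny_roi()
  fv <- extract_features(roi$volume, roi$mask, 1L)
  expect_length(fv, 91)
  expect_identical(names(fv), feature_catalog()$name)
  expect_true(all(is.finite(fv)))

  # constant ROI still yields 91 finite values
  cvol <- image_volume(array(100, dim(roi$volume$voxels)),
                       roi$volume$spacing)
  fc <- extract_features(cvol, roi$mask, 1L)
  expect_true(all(is.finite(fc)))

  # translation invariance: move the ROI inside a larger volume
  big <- array(0, c(14, 14, 8))
  big[4:11, 3:10, 2:5] <- roi$volume$voxels
  blab <- array(0L, c(14, 14, 8))
  blab[4:11, 3:10, 2:5] <- roi$mask$labels
  ft <- extract_features(image_volume(big, roi$volume$spacing),
                         roi_mask(blab, roi$volume$spacing), 1L)
  expect_equal(ft, fv, tolerance = 1e-12)

  # adding a constant shifts location features, not texture features
  shifted <- image_volume(roi$volume$voxels + 50, roi$volume$spacing)
  fs <- extract_features(shifted, roi$mask, 1L)
  expect_equal(fs[["firstorder_Mean"]], fv[["firstorder_Mean"]] + 50)
  expect_equal(fs[["firstorder_Minimum"]], fv[["firstorder_Minimum"]] + 50)
  texture <- feature_catalog()$name[feature_catalog()$family != "firstorder"]
  expect_equal(fs[texture], fv[texture], tolerance = 1e-9)
  expect_error(extract_features(roi$volume, roi$mask, 9L), "empty ROI")
})
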