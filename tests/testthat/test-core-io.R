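test_that("volume constructors enforce their invariants", {
  expect_error(image_volume(array(1, c(2, 2)), c(1, 1, 1)), "3-D")
  expect_error(image_volume(array(NA_real_, c(2, 2, 2)), c(1, 1, 1)),
               "finite")
  expect_error(image_volume(array(1, c(2, 2, 2)), c(1, -1, 1)), "positive")
  v <- image_volume(array(0, c(2, 2, 2)), c(0.5, 0.5, 1.25))
  expect_s3_class(v, "image_volume")
  expect_error(scan_meta("a", "m", 2.5, 1.25), "0, 2")
  expect_error(roi_mask(array(-1L, c(2, 2, 2)), c(1, 1, 1)), "non-negative")
})

test_that("NIfTI write/read round-trips voxels and spacing bit-exactly", {
  set.seed(11)
  vol <- image_volume(array(rnorm(4 * 5 * 3, 0, 100), c(4, 5, 3)),
                      spacing = c(0.39, 0.39, 1.25))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(back$volume$voxels, vol$voxels)
  expect_equal(back$volume$spacing, vol$spacing, tolerance = 1e-6)

  labels <- array(0L, c(4, 5, 3)); labels[2:3, 2:4, ] <- 7L
  mpath <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(roi_mask(labels, vol$spacing), mpath)
  expect_identical(read_mask(mpath)$labels, labels)
})

test_that("reading a DICOM series applies the HU rescale and orders slices", {
  dir <- withr::local_tempdir()
  # stored value 1024 with slope 1, intercept -1024 must decode to 0 HU
  px1 <- matrix(1024L, 6, 4)
  px2 <- matrix(2048L, 6, 4)
  # write out of spatial order on purpose
  write_test_dicom_slice(file.path(dir, "b.dcm"), px2, c(0, 0, 1.25), "1.2.3",
                         pixel_spacing = c(0.7, 0.5))
  write_test_dicom_slice(file.path(dir, "a.dcm"), px1, c(0, 0, 0), "1.2.3",
                         pixel_spacing = c(0.7, 0.5))
  got <- read_volume(dir)
  expect_equal(dim(got$volume$voxels), c(6, 4, 2))
  expect_true(all(got$volume$voxels[, , 1] == 0))      # slice at z=0 first
  expect_true(all(got$volume$voxels[, , 2] == 1024))
  expect_equal(got$volume$spacing, c(0.7, 0.5, 1.25))
  expect_equal(got$meta$scanner_model, "TestModel")
})

test_that("DICOM reader rejects interleaved series and ragged spacing", {
  dir <- withr::local_tempdir()
  px <- matrix(0L, 4, 4)
  write_test_dicom_slice(file.path(dir, "a.dcm"), px, c(0, 0, 0), "1.2.3")
  write_test_dicom_slice(file.path(dir, "b.dcm"), px, c(0, 0, 1.25), "9.9.9")
  expect_error(read_volume(dir), "more than one")

  dir2 <- withr::local_tempdir()
  write_test_dicom_slice(file.path(dir2, "a.dcm"), px, c(0, 0, 0), "1.2.3")
  write_test_dicom_slice(file.path(dir2, "b.dcm"), px, c(0, 0, 1.25), "1.2.3")
  write_test_dicom_slice(file.path(dir2, "c.dcm"), px, c(0, 0, 2.9), "1.2.3")
  expect_error(read_volume(dir2), "inconsistent inter-slice spacing")
})

test_that("feature-table CSV round-trips at full precision", {
  tab <- random_feature_table(n_scans = 14, n_rois = 10)
  expect_equal(nrow(tab), 140)           # 14 scans x 10 ROIs
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  feats <- feature_catalog()$name
  expect_identical(names(back), names(tab))
  expect_identical(as.matrix(back[feats]), as.matrix(tab[feats]))
  expect_identical(back$scan_id, tab$scan_id)

  # empty table -> header only
  epath <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(empty_feature_table(), epath)
  expect_length(readLines(epath), 1L)
  expect_equal(nrow(read_feature_table(epath)), 0L)
})

test_that("feature-table validation rejects broken contracts", {
  tab <- random_feature_table()
  bad <- tab; bad$glcm_Contrast <- NULL
  expect_error(validate_feature_table(bad), "91")
  bad <- tab; bad$batch[1] <- NA
  expect_error(validate_feature_table(bad), "batch")
  bad <- tab; bad$glcm_Contrast[2] <- Inf
  expect_error(validate_feature_table(bad), "non-finite")
})
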