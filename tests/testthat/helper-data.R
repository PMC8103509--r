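# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

# The default synthetic study dataset: 2 scanner models x 7 spacings.
default_dataset_cached <- function() {
  if (is.null(.fixture_env$dataset))
    .fixture_env$dataset <- make_dataset(base_seed = 101L)
  .fixture_env$dataset
}

scene_cached <- function() {
  if (is.null(.fixture_env$scene))
    .fixture_env$scene <- render_scene()
  .fixture_env$scene
}

# A small volume + 1-label mask for single-ROI tests.
tiny_roi <- function(seed = 7, dims = c(8, 8, 4), label = 1L) {
  set.seed(seed)
  vol <- image_volume(array(stats::rnorm(prod(dims), 0, 60), dims),
                      spacing = c(1, 1, 1.25))
  labels <- array(0L, dims)
  labels[2:7, 2:7, 1:4] <- label
  list(volume = vol, mask = roi_mask(labels, vol$spacing))
}

# A feature table with random values, n_scans x n_rois rows.
random_feature_table <- function(n_scans = 2, n_rois = 10, seed = 1) {
  set.seed(seed)
  cat91 <- feature_catalog()$name
  ids <- sprintf("S%02d", seq_len(n_scans))
  grid <- expand.grid(roi_label = seq_len(n_rois), scan_id = ids,
                      stringsAsFactors = FALSE)
  tab <- data.frame(scan_id = grid$scan_id,
                    roi_label = as.integer(grid$roi_label),
                    batch = grid$scan_id, stringsAsFactors = FALSE)
  for (f in cat91) tab[[f]] <- stats::rnorm(nrow(tab))
  validate_feature_table(tab)
}

# ---- synthetic DICOM writer (explicit VR little endian) --------------------
# Independent byte-level writer used to exercise the package's reader.

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2,
                                endian = "little")
dcm_elem <- function(group, element, vr, bytes) {
  if (length(bytes) %% 2 == 1)
    bytes <- c(bytes, as.raw(if (vr %in% c("UI", "OB")) 0 else 32))
  head <- c(dcm_u16(group), dcm_u16(element), charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    len <- writeBin(length(bytes), raw(), size = 4, endian = "little")
    c(head, as.raw(c(0, 0)), len, bytes)
  } else {
    c(head, dcm_u16(length(bytes)), bytes)
  }
}
dcm_str <- function(group, element, vr, s)
  dcm_elem(group, element, vr, charToRaw(s))

# One CT-like slice. `pixels` is a Columns x Rows integer matrix of stored
# values (x = column index, to match the reader's convention).
write_test_dicom_slice <- function(path, pixels, ipp, series_uid,
                                   pixel_spacing = c(1, 1),
                                   slice_thickness = 1.25,
                                   slope = 1, intercept = -1024) {
  cols <- nrow(pixels); rows <- ncol(pixels)
  pix_raw <- writeBin(as.integer(as.vector(pixels)), raw(), size = 2,
                      endian = "little")
  body <- c(
    dcm_str(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1"),
    dcm_str(0x0008, 0x1090, "LO", "TestModel"),
    dcm_str(0x0018, 0x0050, "DS", format(slice_thickness)),
    dcm_str(0x0020, 0x000E, "UI", series_uid),
    dcm_str(0x0020, 0x0032, "DS", paste(ipp, collapse = "\\")),
    dcm_str(0x0020, 0x0037, "DS", "1\\0\\0\\0\\1\\0"),
    dcm_elem(0x0028, 0x0010, "US", dcm_u16(rows)),
    dcm_elem(0x0028, 0x0011, "US", dcm_u16(cols)),
    dcm_str(0x0028, 0x0030, "DS",
            paste(pixel_spacing[2], pixel_spacing[1], sep = "\\")),
    dcm_elem(0x0028, 0x0100, "US", dcm_u16(16)),
    dcm_elem(0x0028, 0x0103, "US", dcm_u16(0)),
    dcm_str(0x0028, 0x1052, "DS", format(intercept)),
    dcm_str(0x0028, 0x1053, "DS", format(slope)),
    dcm_elem(0x7FE0, 0x0010, "OW", pix_raw))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}
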