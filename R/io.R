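#' Read a CT volume from disk
#'
#' Reads either a NIfTI file (`.nii` / `.nii.gz`) or a directory containing
#' exactly one uncompressed DICOM series (explicit VR, little endian).
#' DICOM stored values are converted to HU via the rescale slope/intercept
#' and slices are ordered by their position along the slice normal.
#'
#' @param path path to a NIfTI file or a DICOM series directory.
#' @return A list with elements `volume` ([image_volume]) and `meta`
#'   ([scan_meta]).
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) return(read_dicom_series(path))
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!grepl("\\.nii(\\.gz)?$", path))
    stop("unrecognised volume format: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  spacing <- attr(img, "pixdim")[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  vol <- image_volume(array(as.numeric(img), dim = dim(img)[1:3]),
                      spacing = spacing, origin = origin)
  meta <- scan_meta(scan_id = sub("\\.nii(\\.gz)?$", "", basename(path)),
                    scanner_model = "unknown",
                    in_plane_spacing_mm = spacing[1],
                    slice_thickness_mm = spacing[3])
  list(volume = vol, meta = meta)
}

#' Write an image volume to NIfTI
#'
#' Voxels are stored as 64-bit floats so that a write/read round trip is
#' bit-exact. Spacing goes into `pixdim`; the origin into the sform
#' translation.
#'
#' @param vol an [image_volume].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  arr <- vol$voxels
  attr(arr, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(arr, datatype = "double")
  xf <- diag(4)
  diag(xf)[1:3] <- vol$spacing
  xf[1:3, 4] <- vol$origin
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an ROI mask to NIfTI
#'
#' @param mask a [roi_mask].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  arr <- array(as.integer(mask$labels), dim(mask$labels))
  attr(arr, "pixdim") <- mask$spacing
  img <- RNifti::asNifti(arr, datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ROI mask from NIfTI
#'
#' @param path path to a NIfTI label image.
#' @return A [roi_mask].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  roi_mask(array(as.integer(img), dim = dim(img)[1:3]),
           spacing = attr(img, "pixdim")[1:3])
}

# ---- minimal DICOM series reader -------------------------------------------
# Explicit VR little endian, uncompressed 16-bit pixel data. Enough for CT
# series; anything else raises a format error rather than guessing.

dicom_tag <- function(group, element) sprintf("%04X,%04X", group, element)

parse_dicom_file <- function(path) {
  n <- file.info(path)$size
  raw <- readBin(path, "raw", n)
  if (n < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path, call. = FALSE)
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  pos <- 133L
  out <- list()
  u16 <- function(i) readBin(raw[i:(i + 1L)], "integer", size = 2,
                             signed = FALSE, endian = "little")
  u32 <- function(i) readBin(raw[i:(i + 3L)], "double", size = 4,
                             endian = "little") # placeholder, replaced below
  u32 <- function(i) {
    b <- as.integer(raw[i:(i + 3L)])
    b[1] + b[2] * 256 + b[3] * 65536 + b[4] * 16777216
  }
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (vr %in% long_vrs) {
      len <- u32(pos + 8L); data_at <- pos + 12L
    } else {
      len <- u16(pos + 6L); data_at <- pos + 8L
    }
    if (len == 4294967295)
      stop("undefined-length DICOM element unsupported: ", path, call. = FALSE)
    if (data_at + len - 1L > n)
      stop("truncated DICOM element in ", path, call. = FALSE)
    bytes <- if (len > 0) raw[data_at:(data_at + len - 1L)] else raw(0)
    key <- dicom_tag(group, element)
    out[[key]] <- switch(vr,
      US = readBin(bytes, "integer", n = len / 2, size = 2,
                   signed = FALSE, endian = "little"),
      SS = readBin(bytes, "integer", n = len / 2, size = 2,
                   signed = TRUE, endian = "little"),
      UL = u32(data_at),
      DS = , IS = as.numeric(strsplit(trimws(rawToChar(bytes)), "\\\\")[[1]]),
      OW = , OB = bytes,
      trimws(gsub("\\x00", "", rawToChar(bytes), useBytes = TRUE)))
    pos <- data_at + len
  }
  ts <- out[["0002,0010"]]
  if (!is.null(ts) && ts != "1.2.840.10008.1.2.1")
    stop("unsupported DICOM transfer syntax: ", ts, call. = FALSE)
  out
}

get_or <- function(lst, key, default) if (is.null(lst[[key]])) default else lst[[key]]

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!file.info(files)$isdir]
  if (length(files) == 0) stop("empty DICOM directory: ", dir, call. = FALSE)
  slices <- lapply(files, parse_dicom_file)

  uids <- vapply(slices, function(s) get_or(s, "0020,000E", ""), "")
  if (length(unique(uids)) > 1L)
    stop("directory contains more than one DICOM series", call. = FALSE)

  first <- slices[[1]]
  rows <- first[["0028,0010"]]; cols <- first[["0028,0011"]]
  ps <- first[["0028,0030"]]              # (row spacing, column spacing)
  if (is.null(rows) || is.null(cols) || is.null(ps))
    stop("DICOM series lacks image geometry tags", call. = FALSE)
  orient <- get_or(first, "0020,0037", c(1, 0, 0, 0, 1, 0))
  normal <- c(orient[2] * orient[6] - orient[3] * orient[5],
              orient[3] * orient[4] - orient[1] * orient[6],
              orient[1] * orient[5] - orient[2] * orient[4])

  pos_along <- vapply(slices, function(s)
    sum(get_or(s, "0020,0032", c(0, 0, 0)) * normal), 0)
  ord <- order(pos_along)
  slices <- slices[ord]; pos_along <- pos_along[ord]

  nz <- length(slices)
  if (nz > 1) {
    dzs <- diff(pos_along)
    if (max(dzs) - min(dzs) > 1e-3)
      stop("inconsistent inter-slice spacing in DICOM series", call. = FALSE)
    dz <- mean(dzs)
  } else {
    dz <- get_or(first, "0018,0050", 1)
  }

  vox <- array(0, dim = c(cols, rows, nz))
  for (k in seq_len(nz)) {
    s <- slices[[k]]
    bits <- get_or(s, "0028,0100", 16L)
    if (bits != 16L) stop("only 16-bit DICOM pixel data supported", call. = FALSE)
    signed <- get_or(s, "0028,0103", 0L) == 1L
    pix <- readBin(s[["7FE0,0010"]], "integer", n = rows * cols, size = 2,
                   signed = signed, endian = "little")
    slope <- get_or(s, "0028,1053", 1)
    icept <- get_or(s, "0028,1052", 0)
    vox[, , k] <- matrix(slope * pix + icept, nrow = cols)  # columns vary fastest
  }

  origin <- get_or(slices[[1]], "0020,0032", c(0, 0, 0))
  spacing <- c(ps[2], ps[1], dz)          # dx = column spacing, dy = row spacing
  vol <- image_volume(vox, spacing = spacing, origin = origin)
  meta <- scan_meta(
    scan_id = get_or(first, "0020,000E", basename(dir)),
    scanner_model = get_or(first, "0008,1090", "unknown"),
    in_plane_spacing_mm = spacing[1],
    slice_thickness_mm = get_or(first, "0018,0050", dz))
  list(volume = vol, meta = meta)
}

# ---- feature tables ---------------------------------------------------------

#' Write a feature table to CSV
#'
#' Columns are `scan_id`, `roi_label`, `batch`, then the 91 catalog features
#' in canonical order. Numeric values are serialized with 17 significant
#' digits so that a write/read round trip is lossless.
#'
#' @param table a feature-table `data.frame` (see [extract_feature_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  validate_feature_table(table)
  out <- table
  num <- vapply(out, is.numeric, TRUE) & names(out) != "roi_label"
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @return A feature-table `data.frame`.
#' @export
read_feature_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) > 0) validate_feature_table(tab)
  tab
}

#' Validate a feature table
#'
#' A feature table is rectangular by construction as a `data.frame`; this
#' checks the contract on top: the id columns are present, the feature
#' columns are exactly the 91-entry catalog in canonical order, every row
#' carries a batch label, and all feature values are finite.
#'
#' @param table a `data.frame`.
#' @return `table`, invisibly.
#' @export
validate_feature_table <- function(table) {
  idc <- c("scan_id", "roi_label", "batch")
  if (!all(idc %in% names(table)))
    stop("feature table must have scan_id, roi_label and batch columns",
         call. = FALSE)
  feats <- setdiff(names(table), idc)
  if (!identical(feats, feature_catalog()$name))
    stop("feature columns do not match the 91-entry catalog in canonical order",
         call. = FALSE)
  if (nrow(table) > 0) {
    if (anyNA(table$batch) || any(table$batch == ""))
      stop("every row needs a batch label", call. = FALSE)
    vals <- as.matrix(table[feats])
    if (!all(is.finite(vals)))
      stop("feature table contains non-finite values", call. = FALSE)
  }
  invisible(table)
}

#' Skeleton of an empty feature table
#'
#' @return A zero-row `data.frame` with the canonical columns.
#' @export
empty_feature_table <- function() {
  cols <- c(list(scan_id = character(0), roi_label = integer(0),
                 batch = character(0)),
            stats::setNames(rep(list(numeric(0)), 91), feature_catalog()$name))
  as.data.frame(cols, check.names = FALSE)
}
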