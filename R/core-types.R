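#' Construct an image volume
#'
#' A 3-D grid of Hounsfield-unit intensities with physical metadata. The
#' array axes are (x, y, z); voxel `(i, j, k)` (1-based) has its centre at
#' `origin + ((i-1) * dx, (j-1) * dy, (k-1) * dz)` in mm (voxel-centre
#' convention). Values are stored as double end-to-end; texture features are
#' sensitive to integer truncation.
#'
#' @param voxels 3-D numeric array of HU values; all finite.
#' @param spacing numeric length-3, voxel spacing `(dx, dy, dz)` in mm; all
#'   strictly positive.
#' @param origin numeric length-3, world position of the centre of voxel
#'   `(1, 1, 1)` in mm.
#' @return An object of class `image_volume` with fields `voxels`, `spacing`
#'   and `origin`.
#' @export
image_volume <- function(voxels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array", call. = FALSE)
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels)))
    stop("`voxels` must contain finite values only", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite numbers", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite numbers", call. = FALSE)
  structure(list(voxels = voxels, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s voxels, spacing %s mm, HU range [%.1f, %.1f]\n",
              paste(dim(x$voxels), collapse = " x "),
              paste(format(x$spacing, digits = 4), collapse = " x "),
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Construct an ROI label mask
#'
#' An integer label volume on the same grid as a paired [image_volume()].
#' Label 0 is background; labels 1..10 index the phantom layers. Each
#' nonzero label should cover at least 27 voxels so that 3-D texture
#' neighbourhoods are defined.
#'
#' @param labels 3-D integer array of labels in `0..10`.
#' @param spacing,origin grid metadata, as in [image_volume()].
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels, spacing, origin = c(0, 0, 0)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("`labels` must be a 3-D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L))
    stop("labels must be non-negative integers", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers", call. = FALSE)
  structure(list(labels = labels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  labs <- sort(unique(as.vector(x$labels)))
  cat(sprintf("<roi_mask> %s voxels, labels {%s}\n",
              paste(dim(x$labels), collapse = " x "),
              paste(labs, collapse = ", ")))
  invisible(x)
}

#' Scan acquisition metadata
#'
#' @param scan_id character scan identifier.
#' @param scanner_model character scanner model tag.
#' @param in_plane_spacing_mm in-plane pixel spacing in mm, in `(0, 2]`.
#' @param slice_thickness_mm slice thickness in mm, positive.
#' @param seed optional integer noise seed recorded for provenance.
#' @return An object of class `scan_meta`.
#' @export
scan_meta <- function(scan_id, scanner_model, in_plane_spacing_mm,
                      slice_thickness_mm, seed = NULL) {
  if (!(in_plane_spacing_mm > 0 && in_plane_spacing_mm <= 2))
    stop("`in_plane_spacing_mm` must lie in (0, 2]", call. = FALSE)
  if (slice_thickness_mm <= 0)
    stop("`slice_thickness_mm` must be positive", call. = FALSE)
  structure(list(scan_id = as.character(scan_id),
                 scanner_model = as.character(scanner_model),
                 in_plane_spacing_mm = as.numeric(in_plane_spacing_mm),
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "scan_meta")
}

# Check that a mask and a volume share one grid.
check_aligned <- function(vol, mask) {
  stopifnot(inherits(vol, "image_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(vol$voxels), dim(mask$labels)))
    stop("mask and volume have different shapes", call. = FALSE)
  invisible(TRUE)
}
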