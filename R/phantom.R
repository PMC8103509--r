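# Digital stand-in for a stacked multi-layer CT texture phantom: one fixed
# continuous "scene" rendered once on a fine master grid, then "acquired" by
# a virtual scanner (PSF blur + box averaging over the detector footprint +
# additive noise) at any requested in-plane pixel spacing.

#' Default texture layer specifications
#'
#' Ten layers spanning roughly -900 to +700 HU with a mix of fine and
#' coarse spatial-frequency content: correlated-noise "cork" layers, pure
#' noise, speckle, blobs, a near-uniform gradient layer, ridges, a
#' checkerboard, a honeycomb and a lattice. Diversity of spatial frequency
#' is what makes in-plane-resolution effects visible in texture features.
#'
#' @return A list of 10 layer specs (`layer_index`, `base_hu`,
#'   `amplitude_hu`, `texture_kind`, `correlation_length_mm`).
#' @export
default_layers <- function() {
  mk <- function(i, base, amp, kind, len)
    list(layer_index = i, base_hu = base, amplitude_hu = amp,
         texture_kind = kind, correlation_length_mm = len)
  list(
    mk(1L, -900, 60, "fine-cork", 0.4),
    mk(2L, -700, 100, "coarse-cork", 2.0),
    mk(3L, -450, 150, "blob-cluster", 1.5),
    mk(4L, -250, 120, "speckle", 0.3),
    mk(5L, -100, 80, "uniform-noise", 0.1),
    mk(6L, 0, 30, "gradient", 1.0),
    mk(7L, 150, 100, "ridged", 1.2),
    mk(8L, 300, 120, "checkerboard", 1.5),
    mk(9L, 500, 130, "honeycomb", 1.2),
    mk(10L, 700, 80, "lattice", 1.5))
}

#' Default phantom specification
#'
#' @param scene_spacing_mm master-grid in-plane spacing in mm. Must be at
#'   most one third of the finest acquisition spacing.
#' @param layer_extent_mm in-plane side length and thickness of one layer
#'   slab, in mm. The thickness must be a multiple of the slice thickness.
#' @param border_mm air border around the slabs in-plane.
#' @param slice_thickness_mm through-plane spacing of the scene (and of
#'   every acquisition).
#' @param master_seed integer seed that fixes the rendered scene.
#' @param layers list of layer specs, see [default_layers()].
#' @return A phantom spec list.
#' @export
phantom_spec <- function(scene_spacing_mm = 0.1,
                         layer_extent_mm = c(24, 24, 3.75),
                         border_mm = 2,
                         slice_thickness_mm = 1.25,
                         master_seed = 20210413L,
                         layers = default_layers()) {
  if (length(layers) != 10L) stop("a phantom has 10 layers", call. = FALSE)
  stopifnot(scene_spacing_mm > 0, border_mm >= 0)
  nz_layer <- layer_extent_mm[3] / slice_thickness_mm
  if (abs(nz_layer - round(nz_layer)) > 1e-9)
    stop("layer thickness must be a multiple of the slice thickness",
         call. = FALSE)
  list(scene_spacing_mm = scene_spacing_mm,
       layer_extent_mm = layer_extent_mm,
       border_mm = border_mm,
       slice_thickness_mm = slice_thickness_mm,
       master_seed = as.integer(master_seed),
       layers = layers)
}

#' Default virtual scanner profiles
#'
#' Two scanner models that differ in in-plane PSF width and noise level.
#' The noise standard deviation of an acquisition is
#' `noise_sd_hu + noise_sd_slope / spacing`, so scans with smaller pixels
#' are noisier, as in real CT. The profiles are synthetic stand-ins for two
#' scanner models of one vendor; they are not physical estimates.
#'
#' @return A named list of two profiles.
#' @export
default_scanner_profiles <- function() {
  list(
    `Discovery-STE` = list(model_name = "Discovery-STE",
                           psf_fwhm_mm = 0.6,
                           noise_sd_hu = 3, noise_sd_slope = 2),
    `LightSpeed-Pro-32` = list(model_name = "LightSpeed-Pro-32",
                               psf_fwhm_mm = 0.8,
                               noise_sd_hu = 5, noise_sd_slope = 3))
}

#' The seven in-plane pixel spacings of the study design
#'
#' @return Numeric vector of 7 spacings in mm.
#' @export
study_spacings <- function() c(0.39, 0.49, 0.59, 0.68, 0.78, 0.88, 0.98)

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Separable edge-clamped blur/shift accumulation down the rows of a matrix.
shift_blur_rows <- function(M, weights) {
  r <- (length(weights) - 1L) %/% 2L
  n <- nrow(M)
  out <- matrix(0, n, ncol(M))
  for (s in -r:r) {
    idx <- pmin(pmax(seq_len(n) + s, 1L), n)
    out <- out + weights[s + r + 1L] * M[idx, , drop = FALSE]
  }
  out
}

gaussian_blur_inplane <- function(arr, sigma_px) {
  if (sigma_px <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-0.5 * ((-r:r) / sigma_px)^2)
  k <- k / sum(k)
  d <- dim(arr)
  arr <- array(shift_blur_rows(matrix(arr, d[1], d[2] * d[3]), k), d)
  a <- aperm(arr, c(2, 1, 3))
  a <- array(shift_blur_rows(matrix(a, d[2], d[1] * d[3]), k),
             c(d[2], d[1], d[3]))
  aperm(a, c(2, 1, 3))
}

# Correlated standard-normal field: white noise smoothed at the given
# correlation length and re-standardized.
correlated_field <- function(nx, ny, nslice, corr_px) {
  z <- array(stats::rnorm(nx * ny * nslice), c(nx, ny, nslice))
  if (corr_px > 0.5) z <- gaussian_blur_inplane(z, corr_px)
  (z - mean(z)) / stats::sd(z)
}

# One layer's texture field (deviation from base_hu) on the master grid.
# x, y are world coordinates (mm) of the master-pixel centres, centred on 0.
render_layer_field <- function(layer, x, y, nslice) {
  nx <- length(x); ny <- length(y)
  L <- layer$correlation_length_mm
  a <- layer$amplitude_hu
  px <- x[2] - x[1]
  xg <- matrix(x, nx, ny)
  yg <- matrix(y, nx, ny, byrow = TRUE)
  per_slice <- function(f) array(rep(f, nslice), c(nx, ny, nslice))
  switch(layer$texture_kind,
    "uniform-noise" = array(stats::runif(nx * ny * nslice, -a, a),
                            c(nx, ny, nslice)),
    "speckle" = {
      u <- array(stats::runif(nx * ny * nslice), c(nx, ny, nslice))
      a * ((u > 0.95) - (u < 0.05))
    },
    "fine-cork" = ,
    "coarse-cork" = {
      z <- correlated_field(nx, ny, nslice, L / px)
      pmin(pmax((a / 2.5) * z, -a), a)
    },
    "blob-cluster" = {
      z <- correlated_field(nx, ny, nslice, L / px)
      a * ifelse(z > 0.8, 1, -0.2)
    },
    "gradient" = per_slice(a * (2 * (xg - min(x)) / (max(x) - min(x)) - 1)),
    "ridged" = per_slice(a * sin(pi * xg / L)),
    "checkerboard" = per_slice(
      a * sign(sin(pi * xg / L) * sin(pi * yg / L) + 1e-12)),
    "honeycomb" = {
      k <- 2 * pi / (3 * L)
      h <- cos(k * xg) + cos(k * (xg / 2 + yg * sqrt(3) / 2)) +
           cos(k * (xg / 2 - yg * sqrt(3) / 2))
      per_slice(a * ifelse(h < -1, 1, -0.3))
    },
    "lattice" = {
      p <- 2 * L; w <- 0.5
      on_line <- (((xg - min(x)) %% p) < w) | (((yg - min(y)) %% p) < w)
      per_slice(a * ifelse(on_line, 1, -0.2))
    },
    stop("unknown texture kind: ", layer$texture_kind, call. = FALSE))
}

#' Render the phantom scene on the master grid
#'
#' Builds the fixed continuous scene: ten stacked texture slabs surrounded
#' by an air border at -1000 HU, with a 10-label ROI mask covering the
#' central region of each layer. The scene is a pure function of the spec
#' (texture noise is drawn under `master_seed`); it is rendered once and
#' reused for every virtual acquisition, because the physical phantom is a
#' single object.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `volume` ([image_volume]) and `mask` ([roi_mask]) on
#'   the master grid.
#' @export
render_scene <- function(spec = phantom_spec()) {
  px <- spec$scene_spacing_mm
  ext <- spec$layer_extent_mm
  nz_layer <- as.integer(round(ext[3] / spec$slice_thickness_mm))
  n_in <- as.integer(round(ext[1] / px))
  n_border <- as.integer(round(spec$border_mm / px))
  n <- n_in + 2L * n_border
  nz <- 10L * nz_layer
  half <- n * px / 2
  x <- (seq_len(n) - 0.5) * px - half

  vox <- array(-1000, c(n, n, nz))
  labels <- array(0L, c(n, n, nz))
  in_idx <- (n_border + 1L):(n_border + n_in)
  # ROI margin chosen so the ROI boundary avoids the high-contrast lattice
  # lines of layer 10 (period 3 mm, lines at [0, 0.5) mm): boundary voxels
  # then sit in homogeneous material on every acquisition grid
  roi_margin_mm <- 4.75
  n_m <- as.integer(round(roi_margin_mm / px))
  roi_idx <- (n_border + n_m + 1L):(n_border + n_in - n_m)

  with_seed(spec$master_seed, {
    for (li in seq_along(spec$layers)) {
      layer <- spec$layers[[li]]
      zs <- ((li - 1L) * nz_layer + 1L):(li * nz_layer)
      field <- render_layer_field(layer, x[in_idx], x[in_idx], nz_layer)
      vox[in_idx, in_idx, zs] <- layer$base_hu + field
      labels[roi_idx, roi_idx, zs] <- layer$layer_index
    }
  })
  vox <- pmin(pmax(vox, -1000), 800)
  spacing <- c(px, px, spec$slice_thickness_mm)
  list(volume = image_volume(vox, spacing),
       mask = roi_mask(labels, spacing))
}

# Box-averaging weight matrix: output cells of width d_out partition the
# same physical extent as input cells of width d_in; the weight of input
# cell i in output cell j is their overlap length.
box_weights <- function(n_in, d_in, n_out, d_out) {
  ein <- (0:n_in) * d_in
  eout <- (0:n_out) * (n_in * d_in / n_out) # exact cover of the extent
  W <- matrix(0, n_out, n_in)
  for (j in seq_len(n_out)) {
    lo <- eout[j]; hi <- eout[j + 1]
    i0 <- max(1L, floor(lo / d_in) + 1L)
    i1 <- min(n_in, ceiling(hi / d_in))
    for (i in i0:i1)
      W[j, i] <- max(0, min(hi, ein[i + 1]) - max(lo, ein[i]))
  }
  W / rowSums(W)
}

#' Acquire one virtual scan of the scene
#'
#' Acquisition model: (1) blur the scene in-plane with the scanner's
#' Gaussian PSF, (2) box-average the blurred scene over each output voxel's
#' physical footprint, (3) add zero-mean Gaussian noise with standard
#' deviation `noise_sd_hu + noise_sd_slope / in_plane_spacing_mm` under the
#' given seed. The ROI mask follows by majority vote of master-grid labels
#' within each output voxel. Box averaging conserves the scene mean, so for
#' a noise-free acquisition the in-ROI mean HU is invariant to the pixel
#' spacing.
#'
#' @param scene output of [render_scene()].
#' @param profile a scanner profile, see [default_scanner_profiles()].
#' @param in_plane_spacing_mm requested pixel spacing; must be at least 3
#'   master-grid pixels.
#' @param seed integer noise seed.
#' @param scan_id identifier recorded in the metadata.
#' @return A list with `volume`, `mask` and `meta`.
#' @export
acquire_scan <- function(scene, profile, in_plane_spacing_mm, seed,
                         scan_id = NULL) {
  vol <- scene$volume
  px <- vol$spacing[1]
  if (in_plane_spacing_mm < 3 * px)
    stop("acquisition spacing must be at least 3 master-grid pixels",
         call. = FALSE)
  d <- dim(vol$voxels)
  sigma_px <- (profile$psf_fwhm_mm / (2 * sqrt(2 * log(2)))) / px
  blurred <- gaussian_blur_inplane(vol$voxels, sigma_px)

  n_out <- max(1L, as.integer(round(d[1] * px / in_plane_spacing_mm)))
  s_eff <- d[1] * px / n_out          # realized spacing covers the extent
  Wx <- box_weights(d[1], px, n_out, s_eff)
  arr <- apply_along_x(array(blurred, d), Wx)
  arr <- apply_along_y(arr, Wx)

  sd_hu <- profile$noise_sd_hu +
    profile$noise_sd_slope / in_plane_spacing_mm
  arr <- with_seed(seed,
    arr + array(stats::rnorm(length(arr), 0, sd_hu), dim(arr)))

  origin <- vol$origin - px / 2 + s_eff / 2
  origin[3] <- vol$origin[3]
  spacing <- c(s_eff, s_eff, vol$spacing[3])

  labs <- sort(unique(as.vector(scene$mask$labels)))
  best <- array(-Inf, dim(arr))
  winner <- array(0L, dim(arr))
  for (l in labs) {
    ind <- array(as.double(scene$mask$labels == l), d)
    frac <- apply_along_y(apply_along_x(ind, Wx), Wx)
    take <- frac > best
    winner[take] <- l
    best[take] <- frac[take]
  }

  if (is.null(scan_id))
    scan_id <- sprintf("%s-%.2fmm", profile$model_name, in_plane_spacing_mm)
  list(volume = image_volume(arr, spacing, origin),
       mask = roi_mask(winner, spacing, origin),
       meta = scan_meta(scan_id, profile$model_name, in_plane_spacing_mm,
                        vol$spacing[3], seed))
}

#' Generate the full synthetic dataset
#'
#' Renders the scene once and acquires it with each scanner profile at each
#' in-plane spacing: by default 2 models x 7 spacings = 14 scans, every one
#' an image of the same underlying object, with independently seeded noise
#' per scan.
#'
#' @param spec a [phantom_spec()].
#' @param profiles scanner profiles, see [default_scanner_profiles()].
#' @param spacings in-plane spacings in mm, see [study_spacings()].
#' @param base_seed integer; per-scan noise seeds are derived from it.
#' @return A list of scans, each a list with `volume`, `mask`, `meta`.
#' @export
make_dataset <- function(spec = phantom_spec(),
                         profiles = default_scanner_profiles(),
                         spacings = study_spacings(),
                         base_seed = 1L) {
  scene <- render_scene(spec)
  scans <- list()
  k <- 0L
  for (p in seq_along(profiles)) {
    for (s in seq_along(spacings)) {
      k <- k + 1L
      id <- sprintf("SYN-%d-%03d", p, s)
      scans[[k]] <- acquire_scan(scene, profiles[[p]], spacings[s],
                                 seed = as.integer(base_seed) + 1000L * k,
                                 scan_id = id)
    }
  }
  scans
}
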