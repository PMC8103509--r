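#' Interpolation methods
#'
#' The ten in-plane interpolation methods available for resampling to a new
#' unified in-plane resolution: nearest neighbour (`NN`), `Linear`, cubic
#' `BSpline`, `Gaussian`, `LabelGaussian` (masks only), and five
#' windowed-sinc kernels — Hamming (`HWS`), Cosine (`CWS`), Welch (`WWS`),
#' Lanczos (`LWS`) and Blackman (`BWS`).
#'
#' @export
interpolation_methods <- function() {
  c("NN", "Linear", "BSpline", "Gaussian", "LabelGaussian",
    "HWS", "CWS", "WWS", "LWS", "BWS")
}

sinc_methods <- function() c("HWS", "CWS", "WWS", "LWS", "BWS")

normalized_sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Windowed-sinc kernel weight
#'
#' Evaluates `k(x) = w(x) * sinc(x)` for the five windowed-sinc
#' interpolators, where `sinc(x) = sin(pi x) / (pi x)` and `w` is the window
#' (Hamming, Cosine, Welch, Lanczos or Blackman) of half-width `m` source
#' pixels. Outside `|x| <= m` the kernel is identically zero. All kernels
#' satisfy `k(0) = 1` and `k(n) = 0` at nonzero integers `|n| <= m`.
#'
#' @param method one of `"HWS"`, `"CWS"`, `"WWS"`, `"LWS"`, `"BWS"`.
#' @param x numeric vector of offsets in source-pixel units.
#' @param m window half-width in source pixels (default 3).
#' @return Kernel weights, same length as `x`.
#' @export
kernel_weight <- function(method, x, m = 3L) {
  if (!method %in% sinc_methods())
    stop("`kernel_weight` is defined for windowed-sinc methods only, got ",
         method, call. = FALSE)
  if (m < 1) stop("window half-width `m` must be >= 1", call. = FALSE)
  w <- switch(method,
    HWS = 0.54 + 0.46 * cos(pi * x / m),
    CWS = cos(pi * x / (2 * m)),
    WWS = 1 - (x / m)^2,
    LWS = normalized_sinc(x / m),
    BWS = 0.42 + 0.5 * cos(pi * x / m) + 0.08 * cos(2 * pi * x / m))
  ifelse(abs(x) <= m, w * normalized_sinc(x), 0)
}

# Cubic B-spline basis
bspline3 <- function(u) {
  a <- abs(u)
  ifelse(a < 1, 2 / 3 - a^2 + a^3 / 2,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

# Cubic B-spline interpolation coefficients along the rows of a matrix
# (recursive prefilter, mirror boundary; Unser's causal/anticausal scheme).
bspline_prefilter <- function(mat) {
  n <- nrow(mat)
  if (n == 1L) return(mat)
  z <- sqrt(3) - 2
  c0 <- mat * 6
  # causal init: geometric sum over the mirror-extended signal, carried far
  # enough that the truncation error is below machine precision
  horizon <- 60L
  mirror_idx <- function(k) {            # 1-based reflection without repeat
    if (n == 1L) return(1L)
    p <- (k - 1L) %% (2L * n - 2L)
    if (p >= n) p <- 2L * n - 2L - p
    p + 1L
  }
  init <- c0[1, , drop = FALSE]
  zk <- 1
  for (k in 2:horizon) {
    zk <- zk * z
    init <- init + zk * c0[mirror_idx(k), , drop = FALSE]
  }
  c0[1, ] <- init
  for (i in 2:n) c0[i, ] <- c0[i, ] + z * c0[i - 1, ]
  c0[n, ] <- (z / (z^2 - 1)) * (c0[n, ] + z * c0[n - 1, ])
  for (i in (n - 1):1) c0[i, ] <- z * (c0[i + 1, ] - c0[i, ])
  c0
}

#' Target grid for in-plane resampling
#'
#' Computes the output grid when a volume is resampled to a new unified
#' in-plane resolution. Per in-plane axis the output length is
#' `round(n_in * d_in / nuir_mm)`, clamped to at least 1 voxel; the
#' through-plane axis and the origin are preserved (voxel-centre
#' convention).
#'
#' @param vol an [image_volume].
#' @param nuir_mm target in-plane spacing in mm.
#' @return A list with `shape`, `spacing` and `origin` of the output grid.
#' @export
target_grid <- function(vol, nuir_mm) {
  stopifnot(inherits(vol, "image_volume"))
  if (!is.finite(nuir_mm) || nuir_mm <= 0)
    stop("`nuir_mm` must be positive", call. = FALSE)
  d <- dim(vol$voxels)
  n_out <- pmax(1L, as.integer(round(d[1:2] * vol$spacing[1:2] / nuir_mm)))
  list(shape = c(n_out, d[3]),
       spacing = c(nuir_mm, nuir_mm, vol$spacing[3]),
       origin = vol$origin)
}

# Row-stochastic weight matrix mapping n_in samples at spacing d_in to n_out
# samples at spacing d_out along one axis (shared origin, voxel-centre
# convention). Out-of-support taps are clamped to the edge sample, and each
# row is normalized so constants are preserved exactly.
axis_weights <- function(n_in, d_in, n_out, d_out, method,
                         m = 3L, sigma_factor = 0.8) {
  t <- (seq_len(n_out) - 1) * d_out / d_in   # output centres in source units
  W <- matrix(0, n_out, n_in)
  clamp <- function(i) pmin(pmax(i, 0L), n_in - 1L)
  # B-spline coefficients assume a mirror boundary (the prefilter's
  # convention); every other kernel clamps out-of-support taps to the edge
  reflect <- function(i) {
    if (n_in == 1L) return(rep(0L, length(i)))
    p <- i %% (2L * n_in - 2L)
    ifelse(p >= n_in, 2L * n_in - 2L - p, p)
  }
  add <- function(j, idx, w, boundary = clamp) {
    idx <- boundary(idx)
    for (q in seq_along(idx)) W[j, idx[q] + 1L] <<- W[j, idx[q] + 1L] + w[q]
  }
  for (j in seq_len(n_out)) {
    tj <- t[j]
    if (method == "NN") {
      add(j, as.integer(floor(tj + 0.5)), 1)
    } else if (method == "Linear") {
      i0 <- floor(tj); f <- tj - i0
      add(j, as.integer(c(i0, i0 + 1)), c(1 - f, f))
    } else if (method == "BSpline") {
      i0 <- floor(tj)
      idx <- as.integer((i0 - 1):(i0 + 2))
      add(j, idx, bspline3(tj - idx), boundary = reflect)
    } else if (method == "Gaussian") {
      sigma <- sigma_factor * d_out / d_in   # in source-pixel units
      r <- max(1, ceiling(3 * sigma))
      idx <- as.integer(floor(tj - r):ceiling(tj + r))
      add(j, idx, exp(-0.5 * ((tj - idx) / sigma)^2))
    } else if (method %in% sinc_methods()) {
      idx <- as.integer(ceiling(tj - m):floor(tj + m))
      add(j, idx, kernel_weight(method, tj - idx, m))
    } else {
      stop("unknown interpolation method: ", method, call. = FALSE)
    }
  }
  W / rowSums(W)
}

apply_along_x <- function(arr, W) {
  d <- dim(arr)
  out <- W %*% matrix(arr, d[1], d[2] * d[3])
  array(out, c(nrow(W), d[2], d[3]))
}

apply_along_y <- function(arr, W) {
  a <- aperm(arr, c(2, 1, 3))
  a <- apply_along_x(a, W)
  aperm(a, c(2, 1, 3))
}

#' Resample a volume in-plane
#'
#' Resamples the two in-plane axes of a volume to a new unified in-plane
#' resolution with the requested interpolation method; the through-plane
#' axis (slice direction) is left untouched. Kernels are evaluated
#' separably (x then y) with per-sample weight normalization, so constants
#' are preserved to machine precision; out-of-support samples are clamped
#' to the edge. Cubic B-spline resampling applies the standard recursive
#' interpolation prefilter, so it reproduces the input exactly on an
#' identity grid.
#'
#' @param vol an [image_volume].
#' @param nuir_mm target in-plane spacing in mm.
#' @param method one of [interpolation_methods()] except `"LabelGaussian"`,
#'   which is defined for masks only.
#' @param m windowed-sinc half-width in source pixels.
#' @param sigma_factor Gaussian interpolator sigma as a fraction of the
#'   output spacing.
#' @return The resampled [image_volume].
#' @export
resample_volume <- function(vol, nuir_mm, method, m = 3L, sigma_factor = 0.8) {
  stopifnot(inherits(vol, "image_volume"))
  if (method == "LabelGaussian")
    stop("LabelGaussian is a mask-only interpolator; use resample_mask()",
         call. = FALSE)
  if (!method %in% interpolation_methods())
    stop("unknown interpolation method: ", method, call. = FALSE)
  grid <- target_grid(vol, nuir_mm)
  d <- dim(vol$voxels)
  arr <- vol$voxels
  Wx <- axis_weights(d[1], vol$spacing[1], grid$shape[1], nuir_mm, method,
                     m, sigma_factor)
  Wy <- axis_weights(d[2], vol$spacing[2], grid$shape[2], nuir_mm, method,
                     m, sigma_factor)
  if (method == "BSpline") {
    arr <- array(bspline_prefilter(matrix(arr, d[1], d[2] * d[3])), d)
    arr <- apply_along_x(arr, Wx)
    da <- dim(arr)
    a <- aperm(arr, c(2, 1, 3))
    a <- array(bspline_prefilter(matrix(a, da[2], da[1] * da[3])),
               c(da[2], da[1], da[3]))
    arr <- aperm(array(Wy %*% matrix(a, da[2], da[1] * da[3]),
                       c(nrow(Wy), da[1], da[3])), c(2, 1, 3))
  } else {
    arr <- apply_along_x(arr, Wx)
    arr <- apply_along_y(arr, Wy)
  }
  image_volume(arr, spacing = grid$spacing, origin = grid$origin)
}

#' Resample an ROI mask in-plane
#'
#' Label images must never blend labels, so only two interpolators are
#' admissible: nearest neighbour (the default throughout the pipeline) and
#' `LabelGaussian`, which smooths each label's indicator with the Gaussian
#' interpolator and assigns each output voxel the label of largest smoothed
#' indicator (ties go to the smaller label). The output label set is always
#' a subset of the input label set.
#'
#' @param mask a [roi_mask].
#' @param nuir_mm target in-plane spacing in mm.
#' @param method `"NN"` or `"LabelGaussian"`.
#' @param sigma_factor Gaussian sigma as a fraction of the output spacing.
#' @return The resampled [roi_mask].
#' @export
resample_mask <- function(mask, nuir_mm, method = c("NN", "LabelGaussian"),
                          sigma_factor = 0.8) {
  stopifnot(inherits(mask, "roi_mask"))
  method <- match.arg(method)
  vol <- image_volume(array(as.double(mask$labels), dim(mask$labels)),
                      mask$spacing, mask$origin)
  grid <- target_grid(vol, nuir_mm)
  if (method == "NN") {
    out <- resample_volume(vol, nuir_mm, "NN")
    return(roi_mask(array(as.integer(round(out$voxels)), dim(out$voxels)),
                    grid$spacing, grid$origin))
  }
  labs <- sort(unique(as.vector(mask$labels)))
  best <- array(-Inf, grid$shape)
  winner <- array(labs[1], grid$shape)
  for (l in labs) {
    ind <- image_volume(array(as.double(mask$labels == l), dim(mask$labels)),
                        mask$spacing, mask$origin)
    sm <- resample_volume(ind, nuir_mm, "Gaussian",
                          sigma_factor = sigma_factor)$voxels
    take <- sm > best
    winner[take] <- l
    best[take] <- sm[take]
  }
  roi_mask(array(as.integer(winner), grid$shape), grid$spacing, grid$origin)
}
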