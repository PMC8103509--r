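# From-scratch extraction of the 91-feature catalog from one (volume, ROI)
# pair: fixed-bin-width discretization, 18 first-order statistics, and the
# five texture-matrix families. GLCM and GLRLM are accumulated per 3-D
# direction (13 unique directions at Chebyshev distance 1) and features are
# averaged over directions; GLSZM, GLDM and NGTDM are computed once in 3-D
# with 26-connectivity. All variances are population (1/n) moments.
# Degenerate ROIs (e.g. constant intensity) take documented limit values so
# every ROI yields 91 finite numbers.

#' Fixed-bin-width gray-level discretization
#'
#' Bins HU values into levels with `level(x) = floor(x / W) - floor(min / W)
#' + 1`, so level 1 is always attained and the number of levels `Ng` adapts
#' to the ROI's dynamic range. The default bin width of 25 HU follows
#' standard radiomics practice for unfiltered CT.
#'
#' @param values numeric vector of in-ROI HU values; nonempty.
#' @param bin_width bin width W in HU, positive.
#' @return A list with `levels` (integer, same length as `values`) and `ng`.
#' @export
discretize <- function(values, bin_width = 25) {
  if (length(values) == 0) stop("empty ROI", call. = FALSE)
  if (bin_width <= 0) stop("bin width must be positive", call. = FALSE)
  lev <- as.integer(floor(values / bin_width) -
                    floor(min(values) / bin_width) + 1)
  list(levels = lev, ng = max(lev))
}

xlog2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' First-order intensity features
#'
#' The 18 first-order statistics of the catalog, computed from the raw HU
#' values; `Entropy` and `Uniformity` use the discretized histogram,
#' `TotalEnergy` weights `Energy` by the voxel volume. Skewness and
#' kurtosis of a zero-variance ROI are 0 by convention (kurtosis is not
#' excess-corrected).
#'
#' @param values in-ROI HU values.
#' @param disc output of [discretize()] on the same values.
#' @param voxel_volume voxel volume in mm^3.
#' @return Named numeric vector of 18 features.
#' @export
first_order_features <- function(values, disc = discretize(values),
                                 voxel_volume = 1) {
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  q <- stats::quantile(values, c(0.10, 0.25, 0.50, 0.75, 0.90),
                       names = FALSE, type = 7)
  robust <- values[values >= q[1] & values <= q[5]]
  p <- tabulate(disc$levels, disc$ng) / n
  energy <- sum(values^2)
  c(`10Percentile` = q[1],
    `90Percentile` = q[5],
    Energy = energy,
    Entropy = xlog2(p),
    InterquartileRange = q[4] - q[2],
    Kurtosis = if (m2 > 0) mean((values - mu)^4) / m2^2 else 0,
    Maximum = max(values),
    Mean = mu,
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    Median = q[3],
    Minimum = min(values),
    Range = max(values) - min(values),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(values^2)),
    Skewness = if (m2 > 0) mean((values - mu)^3) / m2^1.5 else 0,
    TotalEnergy = voxel_volume * energy,
    Uniformity = sum(p^2),
    Variance = m2)
}

# Features of one normalized symmetric GLCM (ng x ng, sums to 1).
glcm_features_single <- function(P, ng) {
  i <- seq_len(ng)
  px <- rowSums(P)
  py <- colSums(P)
  mu <- sum(i * px)
  sig2 <- sum((i - mu)^2 * px)
  I <- matrix(i, ng, ng)
  J <- matrix(i, ng, ng, byrow = TRUE)
  # p_{x-y}(k), k = 0..ng-1 and p_{x+y}(k), k = 2..2ng
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(I - J) == k]), 0)
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(I + J) == k]), 0)
  da <- sum(k_diff * p_diff)
  hx <- xlog2(px)
  hy <- xlog2(py)
  hxy <- xlog2(P)
  pxpy <- outer(px, py)
  pos <- P > 0 & pxpy > 0
  hxy1 <- -sum(P[pos] * log2(pxpy[pos]))
  hxy2 <- xlog2(pxpy)
  autoc <- sum(I * J * P)
  c(Autocorrelation = autoc,
    ClusterProminence = sum((I + J - 2 * mu)^4 * P),
    ClusterShade = sum((I + J - 2 * mu)^3 * P),
    ClusterTendency = sum((I + J - 2 * mu)^2 * P),
    Contrast = sum((I - J)^2 * P),
    Correlation = if (sig2 > 0) (autoc - mu^2) / sig2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = xlog2(p_diff),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    Id = sum(P / (1 + abs(I - J))),
    Idm = sum(P / (1 + (I - J)^2)),
    Idmn = sum(P / (1 + (I - J)^2 / ng^2)),
    Idn = sum(P / (1 + abs(I - J) / ng)),
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = sum(P[I != J] / (I - J)[I != J]^2),
    JointAverage = mu,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MaximumProbability = max(P),
    SumEntropy = xlog2(p_sum),
    SumSquares = sig2)
}

#' GLCM features averaged over the 13 directions
#'
#' @param counts symmetric co-occurrence counts, an `ng x ng x 13` array as
#'   produced by the internal accumulator.
#' @return Named vector of 22 features.
#' @export
glcm_features <- function(counts) {
  ng <- dim(counts)[1]
  per_dir <- vapply(seq_len(dim(counts)[3]), function(d) {
    C <- counts[, , d, drop = FALSE]
    dim(C) <- c(ng, ng)
    s <- sum(C)
    if (s == 0) return(rep(NA_real_, 22))
    glcm_features_single(C / s, ng)
  }, numeric(22))
  rowMeans(per_dir, na.rm = TRUE)
}

# Shared level/size-style features for GLRLM (size = run length) and GLSZM
# (size = zone size); `kind` switches the names.
level_size_features <- function(M, np, kind = c("run", "zone")) {
  kind <- match.arg(kind)
  ng <- nrow(M)
  nl <- ncol(M)
  i <- seq_len(ng)
  l <- seq_len(nl)
  nr <- sum(M)
  ri <- rowSums(M)
  rl <- colSums(M)
  p <- M / nr
  mu_i <- sum(i * rowSums(p))
  mu_l <- sum(l * colSums(p))
  I <- matrix(i, ng, nl)
  L <- matrix(l, ng, nl, byrow = TRUE)
  vals <- c(
    GrayLevelNonUniformity = sum(ri^2) / nr,
    GrayLevelNonUniformityNormalized = sum(ri^2) / nr^2,
    GrayLevelVariance = sum(p * (I - mu_i)^2),
    High = sum(M * I^2) / nr,
    Long = sum(M * L^2) / nr,
    LongHigh = sum(M * I^2 * L^2) / nr,
    LongLow = sum(M * L^2 / I^2) / nr,
    Low = sum(M / I^2) / nr,
    Entropy = xlog2(p),
    SizeNonUniformity = sum(rl^2) / nr,
    SizeNonUniformityNormalized = sum(rl^2) / nr^2,
    Percentage = nr / np,
    SizeVariance = sum(p * (L - mu_l)^2),
    Short = sum(M / L^2) / nr,
    ShortHigh = sum(M * I^2 / L^2) / nr,
    ShortLow = sum(M / (I^2 * L^2)) / nr)
  names(vals) <- if (kind == "run") c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
    "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
    "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
    "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
    "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
    "ShortRunLowGrayLevelEmphasis")
  else c(
    "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
    "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
    "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
    "LowGrayLevelZoneEmphasis", "ZoneEntropy", "SizeZoneNonUniformity",
    "SizeZoneNonUniformityNormalized", "ZonePercentage", "ZoneVariance",
    "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
    "SmallAreaLowGrayLevelEmphasis")
  vals
}

#' GLRLM features averaged over the 13 directions
#'
#' @param counts run-length counts, `ng x maxlen x 13`.
#' @param np number of ROI voxels (each direction's run lengths sum to it).
#' @return Named vector of 16 features in canonical (alphabetical) order.
#' @export
glrlm_features <- function(counts, np) {
  ng <- dim(counts)[1]
  per_dir <- vapply(seq_len(dim(counts)[3]), function(d) {
    M <- counts[, , d, drop = FALSE]
    dim(M) <- dim(counts)[1:2]
    level_size_features(M, np, "run")
  }, numeric(16))
  out <- rowMeans(per_dir)
  out[order(names(out))]
}

#' GLSZM features
#'
#' @param zones two-column matrix (level, size), one row per 26-connected
#'   zone.
#' @param ng number of gray levels.
#' @param np number of ROI voxels.
#' @return Named vector of 16 features in canonical order.
#' @export
glszm_features <- function(zones, ng, np) {
  maxs <- max(zones[, 2])
  M <- matrix(0, ng, maxs)
  for (r in seq_len(nrow(zones)))
    M[zones[r, 1], zones[r, 2]] <- M[zones[r, 1], zones[r, 2]] + 1
  out <- level_size_features(M, np, "zone")
  out[order(names(out))]
}

#' GLDM features
#'
#' @param counts dependence counts `ng x 27`; column `d` holds dependence
#'   `d - 1`.
#' @return Named vector of 14 features in canonical order.
#' @export
gldm_features <- function(counts) {
  ng <- nrow(counts)
  nd <- ncol(counts)
  i <- seq_len(ng)
  j <- seq_len(nd)   # shifted dependence (dependence + 1), as is standard
  nz <- sum(counts)
  p <- counts / nz
  I <- matrix(i, ng, nd)
  J <- matrix(j, ng, nd, byrow = TRUE)
  mu_i <- sum(I * p)
  mu_j <- sum(J * p)
  ri <- rowSums(counts)
  rj <- colSums(counts)
  out <- c(
    DependenceEntropy = xlog2(p),
    DependenceNonUniformity = sum(rj^2) / nz,
    DependenceNonUniformityNormalized = sum(rj^2) / nz^2,
    DependenceVariance = sum(p * (J - mu_j)^2),
    GrayLevelNonUniformity = sum(ri^2) / nz,
    GrayLevelVariance = sum(p * (I - mu_i)^2),
    HighGrayLevelEmphasis = sum(counts * I^2) / nz,
    LargeDependenceEmphasis = sum(counts * J^2) / nz,
    LargeDependenceHighGrayLevelEmphasis = sum(counts * I^2 * J^2) / nz,
    LargeDependenceLowGrayLevelEmphasis = sum(counts * J^2 / I^2) / nz,
    LowGrayLevelEmphasis = sum(counts / I^2) / nz,
    SmallDependenceEmphasis = sum(counts / J^2) / nz,
    SmallDependenceHighGrayLevelEmphasis = sum(counts * I^2 / J^2) / nz,
    SmallDependenceLowGrayLevelEmphasis = sum(counts / (I^2 * J^2)) / nz)
  out
}

#' NGTDM features
#'
#' @param stats list with per-level counts `n` and absolute-difference sums
#'   `s` (voxels with no in-ROI neighbour excluded).
#' @return Named vector of the 5 features. `Coarseness` is capped at `1e6`
#'   when the normalizing sum is zero (constant ROI).
#' @export
ngtdm_features <- function(stats) {
  n <- stats$n
  s <- stats$s
  N <- sum(n)
  p <- n / N
  i <- seq_along(n)
  act <- p > 0
  ngp <- sum(act)
  ps <- sum(p * s)
  ia <- i[act]; pa <- p[act]; sa <- s[act]
  pairs_i <- outer(ia, ia, function(a, b) (a - b)^2)
  busy_den <- sum(abs(outer(ia * pa, ia * pa, `-`)))
  comp <- sum(abs(outer(ia, ia, `-`)) *
              (outer(pa * sa, pa * sa, `+`)) / outer(pa, pa, `+`)) / N
  strength_num <- sum(outer(pa, pa, `+`) * pairs_i)
  c(Busyness = if (busy_den > 0) ps / busy_den else 0,
    Coarseness = if (ps > 0) min(1 / ps, 1e6) else 1e6,
    Complexity = comp,
    Contrast = if (ngp > 1)
      sum(outer(pa, pa) * pairs_i) / (ngp * (ngp - 1)) * sum(sa) / N
      else 0,
    Strength = if (sum(sa) > 0) strength_num / sum(sa) else 0)
}

# Level array (NA outside the ROI) on the ROI's bounding box.
roi_level_array <- function(vol, mask, roi_label, bin_width) {
  check_aligned(vol, mask)
  inroi <- mask$labels == roi_label
  if (!any(inroi)) stop("empty ROI for label ", roi_label, call. = FALSE)
  w <- which(inroi, arr.ind = TRUE)
  rng <- apply(w, 2, range)
  sub <- vol$voxels[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                    rng[1, 3]:rng[2, 3], drop = FALSE]
  insub <- inroi[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                 rng[1, 3]:rng[2, 3], drop = FALSE]
  vals <- sub[insub]
  disc <- discretize(vals, bin_width)
  lev <- array(NA_integer_, dim(sub))
  lev[insub] <- disc$levels
  list(values = vals, levels = lev, ng = disc$ng)
}

#' Extract the 91-feature vector for one ROI
#'
#' Runs the full catalog on the voxels of `mask == roi_label`: fixed-bin
#' discretization, first-order statistics, and the five texture families.
#' No resegmentation, outlier clipping or image filtering is applied.
#'
#' @param vol an [image_volume].
#' @param mask a [roi_mask] on the same grid.
#' @param roi_label the ROI label to extract.
#' @param bin_width discretization bin width in HU.
#' @return Named numeric vector of the 91 catalog features, all finite.
#' @export
extract_features <- function(vol, mask, roi_label, bin_width = 25) {
  roi <- roi_level_array(vol, mask, roi_label, bin_width)
  np <- length(roi$values)
  fo <- first_order_features(roi$values,
                             list(levels = roi$levels[!is.na(roi$levels)],
                                  ng = roi$ng),
                             voxel_volume = prod(vol$spacing))
  glcm <- glcm_features(glcm_counts_cpp(roi$levels, roi$ng))
  glrlm <- glrlm_features(glrlm_counts_cpp(roi$levels, roi$ng), np)
  glszm <- glszm_features(glszm_zones_cpp(roi$levels), roi$ng, np)
  gldm <- gldm_features(gldm_counts_cpp(roi$levels, roi$ng, 0L))
  ngtdm <- ngtdm_features(ngtdm_stats_cpp(roi$levels, roi$ng))
  out <- c(stats::setNames(fo, paste0("firstorder_", names(fo))),
           stats::setNames(glcm, paste0("glcm_", names(glcm))),
           stats::setNames(glrlm, paste0("glrlm_", names(glrlm))),
           stats::setNames(glszm, paste0("glszm_", names(glszm))),
           stats::setNames(gldm, paste0("gldm_", names(gldm))),
           stats::setNames(ngtdm, paste0("ngtdm_", names(ngtdm))))
  out <- out[feature_catalog()$name]
  if (anyNA(out) || any(!is.finite(out)))
    stop("non-finite feature value produced", call. = FALSE)
  out
}

#' Extract a feature table from a list of scans
#'
#' One row per (scan, ROI); the scan id serves as the batch label.
#'
#' @param scans list of scans, each with `volume`, `mask`, `meta` (as
#'   produced by [make_dataset()]).
#' @param bin_width discretization bin width in HU.
#' @param roi_labels integer labels to extract (default: all nonzero labels
#'   of each scan's mask).
#' @return A feature-table `data.frame` with columns `scan_id`, `roi_label`,
#'   `batch`, then the 91 features in canonical order.
#' @export
extract_feature_table <- function(scans, bin_width = 25, roi_labels = NULL) {
  rows <- list()
  for (scan in scans) {
    labs <- roi_labels
    if (is.null(labs))
      labs <- setdiff(sort(unique(as.vector(scan$mask$labels))), 0L)
    for (l in labs) {
      fv <- extract_features(scan$volume, scan$mask, l, bin_width)
      rows[[length(rows) + 1L]] <- c(
        list(scan_id = scan$meta$scan_id, roi_label = as.integer(l),
             batch = scan$meta$scan_id),
        as.list(fv))
    }
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  validate_feature_table(out)
  out
}
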