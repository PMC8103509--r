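# Agreement analysis: Lin's concordance correlation coefficient per
# feature over ROI-matched scan pairs, the strict CCC > 0.9 cutoff, the
# all-pairs intersection of concordant sets, and greedy Spearman
# de-duplication of the surviving features.

#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with
#' population (1/n) moments, as in Lin's original estimator. The value lies
#' in `[-1, 1]`: 1 is perfect agreement, -1 perfect inverse agreement, 0 no
#' agreement. Two identical constant vectors have no variance and no mean
#' gap; that 0/0 case is 1 by convention.
#'
#' @param x,y paired numeric vectors of equal length `n >= 2`.
#' @return The CCC, a single number.
#' @export
lins_ccc <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  denom <- mean((x - mx)^2) + mean((y - my)^2) + (mx - my)^2
  if (denom == 0) return(1)
  2 * sxy / denom
}

#' Per-feature concordance of one scan pair
#'
#' For each catalog feature present in the table, computes the CCC over the
#' ROI-matched values of the two scans and flags the feature concordant iff
#' CCC is strictly greater than the cutoff.
#'
#' @param table a feature table containing both scans.
#' @param pair character vector of two scan ids.
#' @param cutoff concordance cutoff (strict inequality), default 0.9.
#' @return A list with `pair`, the named `ccc` vector, the `concordant`
#'   feature names, their `count` and `percentage` (of 91).
#' @export
pairwise_concordance <- function(table, pair, cutoff = 0.9) {
  stopifnot(length(pair) == 2)
  a <- table[table$scan_id == pair[1], , drop = FALSE]
  b <- table[table$scan_id == pair[2], , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0)
    stop("scan missing from table: ", paste(pair, collapse = ", "),
         call. = FALSE)
  if (!identical(sort(a$roi_label), sort(b$roi_label)))
    stop("ROI labels of the two scans do not match", call. = FALSE)
  a <- a[order(a$roi_label), , drop = FALSE]
  b <- b[order(b$roi_label), , drop = FALSE]
  feats <- intersect(feature_catalog()$name, names(table))
  ccc <- vapply(feats, function(f) lins_ccc(a[[f]], b[[f]]), 0)
  concordant <- feats[ccc > cutoff]
  list(pair = pair, ccc = ccc, concordant = concordant,
       count = length(concordant),
       percentage = length(concordant) / 91 * 100)
}

#' Intersection of concordant feature sets across all pairs
#'
#' @param results list of [pairwise_concordance()] results (at least one).
#' @return Character vector of features concordant in every pair.
#' @export
all_pairs_intersection <- function(results) {
  if (length(results) == 0) stop("no pairwise results", call. = FALSE)
  Reduce(intersect, lapply(results, `[[`, "concordant"))
}

#' Greedy Spearman de-duplication
#'
#' Walks the features in canonical catalog order and keeps a feature iff
#' its absolute Spearman correlation with every already-kept feature is at
#' most the threshold (strictly greater means "highly correlated" and the
#' later feature is dropped). A constant feature has undefined rank
#' correlation; it is treated as correlated with nothing and kept. The
#' greedy order makes the surviving set deterministic.
#'
#' @param table a feature table (all rows are used).
#' @param features candidate feature names (subset of the table columns).
#' @param threshold Spearman threshold, default 0.90.
#' @return A list with `kept` and `dropped` character vectors.
#' @export
spearman_dedup <- function(table, features, threshold = 0.90) {
  if (nrow(table) < 3) stop("need at least 3 rows", call. = FALSE)
  features <- intersect(feature_catalog()$name, features) # canonical order
  kept <- character(0)
  dropped <- character(0)
  for (f in features) {
    v <- table[[f]]
    high <- FALSE
    for (k in kept) {
      rho <- suppressWarnings(
        stats::cor(v, table[[k]], method = "spearman"))
      if (!is.na(rho) && abs(rho) > threshold) {
        high <- TRUE
        break
      }
    }
    if (high) dropped <- c(dropped, f) else kept <- c(kept, f)
  }
  list(kept = kept, dropped = dropped)
}
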