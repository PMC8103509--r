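# Parametric empirical-Bayes batch harmonization for feature tables.
# Location/scale model: Y_ijg = alpha_g + X beta_g + gamma_ig + delta_ig
# eps_ijg, with normal prior on the additive batch effects gamma and
# inverse-gamma prior on the squared multiplicative effects delta^2.
# Posterior estimates (gamma*, delta*) are obtained by iterating the coupled
# EB equations; harmonized values are
#   Y* = sigma_g * (Z - gamma*_ig) / delta*_ig + alpha_g + X beta_g
# with Z the standardized residual. Batches here are scans; phantom ROIs
# carry no biological covariates, so X is empty by default.

#' Near-zero-variance filter
#'
#' Removes features whose most frequent value (exact equality after
#' rounding to 12 significant digits) occurs in at least `threshold` of the
#' rows. Such features carry (almost) no within-batch variance and must be
#' removed before ComBat standardization.
#'
#' @param table a feature table with at least 2 rows.
#' @param threshold modal-value fraction at or above which a feature is
#'   removed (default 0.95, i.e. "the same value in 95% or more of the data
#'   points").
#' @return A list with `table` (the filtered table) and `report` (a list
#'   with `removed`, `retained` and the per-feature `modal_fraction`).
#' @export
nzv_filter <- function(table, threshold = 0.95) {
  if (nrow(table) < 2) stop("nzv_filter needs at least 2 rows", call. = FALSE)
  feats <- intersect(feature_catalog()$name, names(table))
  frac <- vapply(feats, function(f) {
    v <- signif(table[[f]], 12)
    max(table(v)) / length(v)
  }, 0)
  removed <- feats[frac >= threshold]
  retained <- setdiff(feats, removed)
  out <- table[, c("scan_id", "roi_label", "batch", retained), drop = FALSE]
  list(table = out,
       report = list(removed = removed, retained = retained,
                     modal_fraction = frac))
}

# EB posterior updates (Johnson 2007 parametric priors).
eb_postmean <- function(g_hat, g_bar, n, d_star, t2)
  (t2 * n * g_hat + d_star * g_bar) / (t2 * n + d_star)
eb_postvar <- function(sum2, n, a, b) (0.5 * sum2 + b) / (n / 2 + a - 1)

#' Fit a ComBat model to a feature table
#'
#' Least-squares feature-wise fit of the location/scale batch model,
#' followed by parametric empirical-Bayes shrinkage of the per-batch
#' additive and multiplicative effects. Prior hyperparameters come from
#' method-of-moments estimates across features; the coupled posterior
#' equations are iterated to a relative tolerance of `conv`. Features with
#' zero pooled variance cannot be standardized; they are flagged and passed
#' through unharmonized by [combat_apply()]. With a single batch there is
#' no batch effect to estimate and the fitted model is the identity.
#'
#' @param table a feature table (already NZV-filtered).
#' @param batch_col column holding the batch label (default `"batch"`).
#' @param covariates optional numeric matrix of per-row covariates.
#' @param conv relative convergence tolerance of the EB iteration.
#' @param max_iter iteration cap.
#' @return An object of class `combat_model`.
#' @export
combat_fit <- function(table, batch_col = "batch", covariates = NULL,
                       conv = 1e-4, max_iter = 500L) {
  feats <- intersect(feature_catalog()$name, names(table))
  Y <- as.matrix(table[, feats, drop = FALSE])
  batch <- factor(table[[batch_col]])
  nb <- nlevels(batch)
  ni <- as.vector(table(batch))
  N <- nrow(Y)
  if (any(ni < 2)) stop("every batch needs at least 2 rows", call. = FALSE)

  if (nb == 1L) {
    # one batch: no batch effect is estimable, the model is the identity
    grand <- colMeans(Y)
    return(structure(list(
      features = feats, flagged = character(0),
      batch_levels = levels(batch), n_per_batch = ni,
      alpha = grand, beta = NULL,
      var_pooled = apply(Y, 2, function(v) mean((v - mean(v))^2)),
      covariate_names = character(0), conv = conv,
      gamma_star = matrix(0, 1, length(feats),
                          dimnames = list(levels(batch), feats)),
      delta_star = matrix(1, 1, length(feats),
                          dimnames = list(levels(batch), feats)),
      identity = TRUE), class = "combat_model"))
  }

  Xb <- stats::model.matrix(~ 0 + batch)
  Xc <- NULL
  if (!is.null(covariates)) {
    Xc <- as.matrix(covariates)
    keep <- apply(Xc, 2, function(v) stats::sd(v) > 0)
    Xc <- Xc[, keep, drop = FALSE]
    if (ncol(Xc) == 0) Xc <- NULL
  }
  X <- if (is.null(Xc)) Xb else cbind(Xb, Xc)
  B <- solve(crossprod(X), crossprod(X, Y))

  grand <- as.vector((ni / N) %*% B[seq_len(nb), , drop = FALSE])
  fitted <- X %*% B
  var_pooled <- colMeans((Y - fitted)^2)  # population (1/N) pooled variance
  ok <- var_pooled > 0

  stand_mean <- matrix(grand, N, length(feats), byrow = TRUE)
  if (!is.null(Xc))
    stand_mean <- stand_mean +
      Xc %*% B[(nb + 1):nrow(B), , drop = FALSE]

  model <- structure(list(
    features = feats, flagged = feats[!ok],
    batch_levels = levels(batch), n_per_batch = ni,
    alpha = stats::setNames(grand, feats),
    beta = if (is.null(Xc)) NULL else B[(nb + 1):nrow(B), , drop = FALSE],
    var_pooled = var_pooled,
    covariate_names = if (is.null(Xc)) character(0) else colnames(Xc),
    conv = conv), class = "combat_model")

  Z <- (Y[, ok, drop = FALSE] - stand_mean[, ok, drop = FALSE]) /
    matrix(sqrt(var_pooled[ok]), N, sum(ok), byrow = TRUE)

  gamma_hat <- apply(Z, 2, function(col) tapply(col, batch, mean))
  delta_hat <- apply(Z, 2, function(col) tapply(col, batch, stats::var))
  gamma_hat <- matrix(gamma_hat, nb, sum(ok),
                      dimnames = list(levels(batch), feats[ok]))
  delta_hat <- matrix(delta_hat, nb, sum(ok),
                      dimnames = list(levels(batch), feats[ok]))

  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, stats::var)
  m <- rowMeans(delta_hat)
  s2 <- apply(delta_hat, 1, stats::var)
  a_prior <- (2 * s2 + m^2) / s2
  b_prior <- (m * s2 + m^3) / s2

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_len(nb)) {
    rows <- batch == levels(batch)[i]
    Zi <- Z[rows, , drop = FALSE]
    n <- ni[i]
    g_old <- gamma_hat[i, ]
    d_old <- delta_hat[i, ]
    if (!is.finite(a_prior[i]) || !is.finite(b_prior[i]) ||
        !is.finite(t2[i]) || t2[i] <= 0) {
      # degenerate prior (e.g. zero spread across features): no shrinkage
      gamma_star[i, ] <- g_old
      delta_star[i, ] <- d_old
      next
    }
    for (iter in seq_len(max_iter)) {
      g_new <- eb_postmean(gamma_hat[i, ], gamma_bar[i], n, d_old, t2[i])
      sum2 <- colSums((Zi - matrix(g_new, n, ncol(Zi), byrow = TRUE))^2)
      d_new <- eb_postvar(sum2, n, a_prior[i], b_prior[i])
      change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                    abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
      g_old <- g_new
      d_old <- d_new
      if (change < conv) break
    }
    gamma_star[i, ] <- g_old
    delta_star[i, ] <- d_old
  }

  gs <- matrix(0, nb, length(feats), dimnames = list(levels(batch), feats))
  ds <- matrix(1, nb, length(feats), dimnames = list(levels(batch), feats))
  gs[, feats[ok]] <- gamma_star
  ds[, feats[ok]] <- delta_star
  model$gamma_star <- gs
  model$delta_star <- ds
  model$gamma_hat <- gamma_hat
  model$delta_hat <- delta_hat
  model$identity <- FALSE
  model
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("<combat_model> %d features, %d batches (%s)\n",
              length(x$features), length(x$batch_levels),
              paste(x$batch_levels, collapse = ", ")))
  if (length(x$flagged))
    cat("  flagged (zero pooled variance, passed through):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Apply a fitted ComBat model
#'
#' Transforms each value to
#' `sigma_g * (Z - gamma*_ig) / delta*_ig + alpha_g + X beta_g`. Row order
#' and batch labels are preserved; features flagged at fit time pass
#' through unchanged.
#'
#' @param model a [combat_fit()] result.
#' @param table a feature table with the model's features and batches.
#' @param batch_col column holding the batch label.
#' @param covariates covariate matrix matching the fit (if any).
#' @return The harmonized feature table.
#' @export
combat_apply <- function(model, table, batch_col = "batch",
                         covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  feats <- model$features
  if (!all(feats %in% names(table)))
    stop("table lacks features the model was fitted on", call. = FALSE)
  batch <- as.character(table[[batch_col]])
  if (!all(batch %in% model$batch_levels))
    stop("unseen batch label in table", call. = FALSE)
  if (model$identity) return(table)

  Y <- as.matrix(table[, feats, drop = FALSE])
  N <- nrow(Y)
  stand_mean <- matrix(model$alpha, N, length(feats), byrow = TRUE)
  if (!is.null(model$beta)) {
    Xc <- as.matrix(covariates)[, model$covariate_names, drop = FALSE]
    stand_mean <- stand_mean + Xc %*% model$beta
  }
  sig <- matrix(sqrt(model$var_pooled), N, length(feats), byrow = TRUE)
  ok <- !(feats %in% model$flagged)

  Z <- (Y - stand_mean) / sig
  g <- model$gamma_star[batch, , drop = FALSE]
  d <- model$delta_star[batch, , drop = FALSE]
  Yc <- sig * (Z - g) / sqrt(d) + stand_mean
  Y[, ok] <- Yc[, ok]
  out <- table
  out[, feats] <- Y
  out
}

#' NZV-filter and ComBat-harmonize one table in a single call
#'
#' Convenience wrapper used by the pairwise pipeline: applies the
#' near-zero-variance filter, fits and applies parametric ComBat on the
#' retained features, and reassembles a full-width table in which removed
#' features keep their original (unharmonized) values, so that concordance
#' stays computable for all 91 features.
#'
#' @inheritParams combat_fit
#' @param nzv_threshold threshold of [nzv_filter()].
#' @return A list with `table` (full 91-column harmonized table) and
#'   `nzv` (the filter report).
#' @export
harmonize_table <- function(table, batch_col = "batch",
                            nzv_threshold = 0.95, conv = 1e-4) {
  flt <- nzv_filter(table, nzv_threshold)
  out <- table
  if (length(flt$report$retained) > 0) {
    model <- combat_fit(flt$table, batch_col = batch_col, conv = conv)
    harm <- combat_apply(model, flt$table, batch_col = batch_col)
    out[, flt$report$retained] <- harm[, flt$report$retained]
  }
  list(table = out, nzv = flt$report)
}
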