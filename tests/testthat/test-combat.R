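# Simulated tables with injected batch effects on the real 91-column layout.
simulate_batch_table <- function(n_per_batch = 10, gamma = 0, delta = 1,
                                 seed = 1, affected = feature_catalog()$name) {
  set.seed(seed)
  tab <- random_feature_table(n_scans = 2, n_rois = n_per_batch, seed = seed)
  b2 <- tab$batch == "S02"
  for (f in affected)
    tab[[f]][b2] <- gamma + delta * tab[[f]][b2]
  tab
}

test_that("near-zero-variance filter applies the 95% modal rule", {
  tab <- random_feature_table(n_scans = 2, n_rois = 10)   # 20 rows
  f1 <- feature_catalog()$name[1]
  f2 <- feature_catalog()$name[2]
  tab[[f1]][1:19] <- 3.14                 # 19/20 = 0.95 -> removed
  tab[[f2]][1:18] <- 2.71                 # 18/20 = 0.90 -> retained
  res <- nzv_filter(tab)
  expect_true(f1 %in% res$report$removed)
  expect_true(f2 %in% res$report$retained)
  expect_setequal(c(res$report$removed, res$report$retained),
                  feature_catalog()$name)
  expect_false(f1 %in% names(res$table))
  expect_error(nzv_filter(tab[1, ]), "2 rows")
})

test_that("harmonization removes an injected additive shift", {
  tab <- simulate_batch_table(n_per_batch = 10, gamma = 5, seed = 42)
  model <- combat_fit(tab)
  harm <- combat_apply(model, tab)
  f <- feature_catalog()$name
  gaps_before <- vapply(f, function(x)
    abs(mean(tab[[x]][tab$batch == "S01"]) -
        mean(tab[[x]][tab$batch == "S02"])), 0)
  gaps_after <- vapply(f, function(x)
    abs(mean(harm[[x]][harm$batch == "S01"]) -
        mean(harm[[x]][harm$batch == "S02"])), 0)
  # EB shrinkage leaves a sampling-scale residue at n = 10 per batch; the
  # bulk of features close to within 0.2 and the shift (5 units) is all
  # but removed on average (behaviour identical to the published ComBat)
  expect_lt(stats::median(gaps_after), 0.2)
  expect_gte(mean(1 - gaps_after / gaps_before), 0.9)
  expect_true(all(model$delta_star > 0))
})

test_that("single-batch harmonization is the identity", {
  tab <- random_feature_table(n_scans = 1, n_rois = 10)
  model <- combat_fit(tab)
  out <- combat_apply(model, tab)
  f <- feature_catalog()$name
  expect_lt(max(abs(as.matrix(out[f]) - as.matrix(tab[f]))), 1e-10)
})

test_that("a degenerate all-zero covariate column changes nothing", {
  tab <- simulate_batch_table(gamma = 2, seed = 9)
  m0 <- combat_fit(tab)
  m1 <- combat_fit(tab, covariates = matrix(0, nrow(tab), 1))
  expect_equal(m1$gamma_star, m0$gamma_star)
  expect_equal(m1$delta_star, m0$delta_star)
})

test_that("harmonization leaves each feature's grand structure in place", {
  # the weighted grand mean moves only by the EB shrinkage residue, a
  # small fraction of the feature's spread (exact preservation would
  # require unshrunk batch means)
  tab <- simulate_batch_table(n_per_batch = 12, gamma = 3, delta = 1.5,
                              seed = 7)
  harm <- combat_apply(combat_fit(tab), tab)
  for (f in feature_catalog()$name[c(1, 20, 50, 91)]) {
    drift <- abs(mean(harm[[f]]) - mean(tab[[f]])) / stats::sd(tab[[f]])
    expect_lt(drift, 0.02, label = f)
  }
})

test_that("unseen batch labels and missing features are rejected", {
  tab <- simulate_batch_table()
  model <- combat_fit(tab)
  bad <- tab; bad$batch[1] <- "S99"
  expect_error(combat_apply(model, bad), "unseen batch")
  expect_error(combat_fit(tab[c(1, 11), ]), "at least 2 rows")
})

test_that("refitting on harmonized data finds no residual batch effect", {
  tab <- simulate_batch_table(n_per_batch = 100, gamma = 5, delta = 2,
                              seed = 13)
  harm <- combat_apply(combat_fit(tab), tab)
  refit <- combat_fit(harm)
  expect_lt(max(abs(refit$gamma_star)), 0.05)
  expect_lt(max(abs(refit$delta_star - 1)), 0.05)
})

test_that("the EB fit matches the published ComBat implementation", {
  skip_if_not_installed("sva")
  tab <- simulate_batch_table(n_per_batch = 15, gamma = 4, delta = 1.8,
                              seed = 5)
  harm <- combat_apply(combat_fit(tab), tab)
  f <- feature_catalog()$name
  dat <- t(as.matrix(tab[f]))             # features x samples
  ref <- suppressMessages(
    sva::ComBat(dat = dat, batch = tab$batch, mod = NULL,
                par.prior = TRUE, prior.plots = FALSE))
  expect_lt(max(abs(t(ref) - as.matrix(harm[f]))), 1e-4)
})
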