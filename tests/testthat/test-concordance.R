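test_that("the CCC hits its anchor values", {
  expect_equal(lins_ccc(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(lins_ccc(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(lins_ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  expect_equal(lins_ccc(rep(2, 5), rep(2, 5)), 1)   # 0/0 convention
  expect_error(lins_ccc(1:3, 1:4), "paired")
  expect_error(lins_ccc(1, 1), "at least 2")
})

test_that("the CCC obeys Lin's inequality, symmetry and affine invariance", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(3:20, 1)
    x <- rnorm(n); y <- rnorm(n)
    ccc <- lins_ccc(x, y)
    expect_lte(abs(ccc), abs(cor(x, y)) + 1e-12)
    expect_equal(ccc, lins_ccc(y, x))
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(lins_ccc(a * x + b, a * y + b), ccc, tolerance = 1e-10)
    expect_equal(ccc, oracle_ccc(x, y), tolerance = 1e-12)
  }
})

test_that("pairwise concordance counts features above a strict cutoff", {
  tab <- random_feature_table(n_scans = 2, n_rois = 10, seed = 3)
  # duplicate scan: every feature perfectly concordant
  f <- feature_catalog()$name
  for (nm in f) tab[[nm]][tab$scan_id == "S02"] <-
    tab[[nm]][tab$scan_id == "S01"]
  res <- pairwise_concordance(tab, c("S01", "S02"))
  expect_equal(res$count, 91)
  expect_equal(res$percentage, 100)

  # strictness at the boundary: a cutoff equal to the achieved CCC excludes
  tab2 <- random_feature_table(n_scans = 2, n_rois = 10, seed = 4)
  ccc1 <- pairwise_concordance(tab2, c("S01", "S02"))$ccc[[f[1]]]
  res2 <- pairwise_concordance(tab2, c("S01", "S02"), cutoff = ccc1)
  expect_false(f[1] %in% res2$concordant)
  expect_error(pairwise_concordance(tab2, c("S01", "S09")), "missing")
})

test_that("ROI mismatch between the scans of a pair is an error", {
  tab <- random_feature_table(n_scans = 2, n_rois = 10)
  tab <- tab[!(tab$scan_id == "S02" & tab$roi_label == 4), ]
  expect_error(pairwise_concordance(tab, c("S01", "S02")), "ROI labels")
})

test_that("all-pairs intersection is the plain set intersection", {
  mk <- function(set) list(concordant = set)
  expect_setequal(all_pairs_intersection(list(mk(c("A", "B")),
                                              mk(c("B", "C")))), "B")
  expect_length(all_pairs_intersection(list(mk(c("A")), mk(character(0)))), 0)
  same <- list(mk(c("A", "B")), mk(c("A", "B")), mk(c("A", "B")))
  expect_setequal(all_pairs_intersection(same), c("A", "B"))
})

test_that("greedy Spearman de-duplication keeps the first of each clique", {
  f <- feature_catalog()$name
  A <- f[1]; B <- f[2]; C <- f[3]
  tab <- random_feature_table(n_scans = 2, n_rois = 10, seed = 8)
  set.seed(8)
  # B is monotone in A (rho = 1); C correlates with B but not with A
  base <- rnorm(20)
  other <- rnorm(20)
  tab[[A]] <- base
  tab[[B]] <- exp(base)
  tab[[C]] <- other
  res <- spearman_dedup(tab, c(A, B, C))
  expect_setequal(res$kept, c(A, C))
  expect_setequal(res$dropped, B)

  # chain A~B, B~C, A!~C keeps {A, C} under greedy catalog order
  mix <- rank(base) + rank(other)        # correlated with both
  tab[[B]] <- mix + rnorm(20, 0, 1e-6)
  rho_ab <- abs(cor(tab[[A]], tab[[B]], method = "spearman"))
  rho_bc <- abs(cor(tab[[B]], tab[[C]], method = "spearman"))
  rho_ac <- abs(cor(tab[[A]], tab[[C]], method = "spearman"))
  thr <- min(rho_ab, rho_bc) - 0.01
  skip_if(thr <= rho_ac, "random draw did not produce a chain")
  res2 <- spearman_dedup(tab, c(A, B, C), threshold = thr)
  expect_setequal(res2$kept, c(A, C))

  # independent features all survive; constants are kept
  tab2 <- random_feature_table(n_scans = 2, n_rois = 25, seed = 9)
  cand <- f[10:14]
  tab2[[cand[1]]] <- 7                    # constant, undefined rho
  res3 <- spearman_dedup(tab2, cand)
  expect_setequal(res3$kept, cand)
})
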