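test_that("top_k_overlap matches a brute-force sorted-top-k check", {
  v <- c(5, 1, 4, 2, 3)
  expect_true(top_k_overlap(v, mask = 1L, k = 1))
  expect_false(top_k_overlap(v, mask = 2L, k = 1))
  expect_true(top_k_overlap(v, mask = seq_along(v), k = 3))  # full mask
  expect_error(top_k_overlap(v, mask = 1L, k = 6), "k must be")

  set.seed(11)
  for (rep in 1:20) {
    vals <- sample(1:8, 10, replace = TRUE)   # many ties
    mask <- sample(10, 3)
    # oracle: resolve ties by lower index, then check the top-5 set
    ord <- order(-vals, seq_along(vals))
    expect_equal(top_k_overlap(vals, mask, 5),
                 any(ord[1:5] %in% mask))
  }
})

test_that("chance_probability: closed form, boundaries, enumeration oracle", {
  expect_equal(chance_probability(90, 7, 1), 7 / 90)
  expect_equal(chance_probability(90, 0, 5), 0)
  expect_equal(round(chance_probability(90, 7, 5), 4), 0.3394)
  expect_equal(chance_probability(90, 7, 5),
               1 - choose(83, 5) / choose(90, 5), tolerance = 1e-12)

  set.seed(12)
  for (rep in 1:8) {
    N <- sample(5:12, 1); m <- sample(0:N, 1); n <- sample(1:min(N, 5), 1)
    expect_equal(chance_probability(N, m, n), chance_brute(N, m, n),
                 tolerance = 1e-12)
  }
})

test_that("chance_probability is monotone in m and n, and saturates", {
  N <- 20
  for (n in 1:4) {
    p <- vapply(0:N, function(m) chance_probability(N, m, n), numeric(1))
    expect_true(all(diff(p) >= -1e-12))
  }
  for (m in 1:5) {
    p <- vapply(1:N, function(n) chance_probability(N, m, n), numeric(1))
    expect_true(all(diff(p) >= -1e-12))
    expect_equal(p[(N - m + 1):N], rep(1, m))   # n > N - m forces a hit
  }
})

test_that("binomial overlap test: extreme tails and the printed-table case", {
  p0 <- chance_probability(90, 7, 5)
  expect_lt(binomial_overlap_test(94, 94, p0), 1e-30)
  expect_equal(binomial_overlap_test(0, 94, p0, alternative = "greater"), 1)
  # 46 of 94 patients with top-5 overlap at chance 0.3394 prints as 0.003
  # under the two-sided exact convention (the package default)
  expect_equal(round(binomial_overlap_test(46, 94, p0), 3), 0.003)
})

test_that("chi-square of independence reproduces published group contrasts", {
  # PLI top-1 overlap: 33% of 64 seizure-free vs 13% of 30 not seizure-free
  res <- chi2_independence(rbind(c(21, 43), c(4, 26)))
  expect_equal(res$statistic, 3.97, tolerance = 0.005)
  expect_equal(res$df, 1)
  expect_equal(res$p, 0.046, tolerance = 0.01)

  # perfect independence
  expect_equal(chi2_independence(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(chi2_independence(rbind(c(10, 10), c(10, 10)))$p, 1)

  # delta-power top-1 contrast (39% of 64 vs 23% of 30)
  res2 <- chi2_independence(rbind(c(25, 39), c(7, 23)))
  expect_equal(round(res2$p, 2), 0.13)

  # brute force sum((O - E)^2 / E) over the four cells
  tab <- rbind(c(21, 43), c(4, 26))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-12)

  expect_error(chi2_independence(rbind(c(0, 0), c(4, 26))), "margin")
})

test_that("pooled t-test from summaries and from raw samples agree", {
  res <- pooled_t_test(0.0844, 0.0184, 64, 0.0748, 0.0171, 30)
  expect_equal(round(res$statistic, 2), 2.41)
  expect_equal(res$df, 92)
  expect_equal(round(res$p, 4), 0.0179)

  res2 <- pooled_t_test(3.7159, 1.3100, 64, 3.3713, 1.3468, 30)
  expect_equal(round(res2$p, 3), 0.242)   # summaries are rounded inputs

  expect_equal(pooled_t_test(1, 0.5, 10, 1, 0.5, 10)$statistic, 0)
  expect_equal(pooled_t_test(1, 0.5, 10, 1, 0.5, 10)$p, 1)
  expect_equal(pooled_t_test(1, 0, 5, 1, 0, 5)$p, 1)
  expect_error(pooled_t_test(1, 0, 5, 2, 0, 5), "infinite")

  set.seed(13)
  x <- rnorm(20); y <- rnorm(15, 0.5)
  mine <- pooled_t_test(x = x, y = y)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
})

test_that("BH adjustment: step-up minima, caps, monotonicity", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_bh(0.2), 0.2)
  set.seed(14)
  p <- runif(30)
  adj <- fdr_bh(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(order(adj[order(p)]), seq_along(p))  # order respected
  # partial family: m_tests larger than the vector
  expect_equal(fdr_bh(0.01, m_tests = 10), 0.1)
  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("averaged measures follow their definitions", {
  atlas <- aal90_atlas()
  n <- nrow(atlas)
  mask <- c(1L, 3L, 5L)          # left-hemisphere ROIs

  am_const <- averaged_measures(rep(2.5, n), mask, atlas)
  expect_equal(unname(am_const),
               c(2.5, 2.5, 2.5, 2.5, 0, 0))

  ind <- numeric(n); ind[mask] <- 1
  am_ind <- averaged_measures(ind, mask, atlas)
  expect_equal(unname(am_ind["resection"]), 1)
  expect_equal(unname(am_ind["non_resection"]), 0)
  expect_equal(unname(am_ind["diff_non_resection"]), 1)
  expect_equal(unname(am_ind["contralateral"]), 0)  # homologs are unmarked

  set.seed(15)
  v <- rnorm(n)
  am <- averaged_measures(v, mask, atlas)
  expect_equal(unname(am["diff_contralateral"]),
               unname(am["resection"] - am["contralateral"]))
  expect_equal(unname(am["resection"]), mean(v[mask]))
  expect_equal(unname(am["contralateral"]), mean(v[atlas$homolog[mask]]))
  lobes <- unique(atlas$lobe[mask])
  expect_equal(unname(am["resection_lobe"]),
               mean(v[atlas$lobe %in% lobes]))
})

test_that("the shipped atlas is a valid 90-ROI involution table", {
  atlas <- aal90_atlas()
  expect_equal(nrow(atlas), 90)
  expect_equal(atlas$homolog[atlas$homolog], atlas$index)
  expect_true(all(atlas$hemisphere[atlas$homolog] != atlas$hemisphere))
  expect_equal(sum(atlas$lobe == "insula_subcortical"), 14)
})

test_that("overlap_table and group tables have the expected shape and FDR", {
  set.seed(16)
  n_pat <- 12; n_rois <- 16
  vals <- array(rnorm(n_pat * n_rois * 4),
                dim = c(n_pat, n_rois, 4),
                dimnames = list(sprintf("P%02d", 1:n_pat), NULL,
                                c("delta_power", "low_high_ratio",
                                  "mean_pli", "betweenness")))
  masks <- lapply(1:n_pat, function(i) sample(n_rois, 3))
  outcomes <- rep(c("seizure_free", "not_seizure_free"), times = c(7, 5))
  mt <- make_metric_table(vals, masks, outcomes)

  ov <- overlap_table(mt, k_max = 5)
  expect_equal(nrow(ov), 20)                     # 4 metrics x 5 k
  expect_true(all(ov$fdr_p >= ov$binomial_p - 1e-12))
  expect_true(all(ov$chance_p0 > 0 & ov$chance_p0 < 1))
  expect_equal(ov$chance_p0[ov$k == 1][1], chance_probability(16, 3, 1))

  gov <- group_overlap_table(mt, k_max = 5)
  expect_equal(nrow(gov), 20)
  expect_true(all(is.na(gov$p) | (gov$p >= 0 & gov$p <= 1)))

  toy_atlas <- data.frame(
    index = 1:16,
    name = sprintf("ROI_%02d", 1:16),
    hemisphere = rep(c("L", "R"), 8),
    lobe = rep(c("frontal", "temporal"), each = 8),
    homolog = as.vector(rbind(seq(2, 16, 2), seq(1, 15, 2)))
  )
  am <- averaged_measures_table(mt, atlas = toy_atlas)
  expect_equal(nrow(am), 24)                     # 4 metrics x 6 measures
  expect_true(all(am$fdr_p >= am$p - 1e-12))
  expect_equal(am$df, rep(10, 24))
})
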