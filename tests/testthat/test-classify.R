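metric_names <- c("delta_power", "low_high_ratio", "mean_pli", "betweenness")

random_metric_table <- function(n_pat, n_rois, mask_sizes, outcomes = NULL,
                                seed = 1) {
  set.seed(seed)
  vals <- array(rnorm(n_pat * n_rois * 4), dim = c(n_pat, n_rois, 4),
                dimnames = list(sprintf("P%03d", 1:n_pat), NULL, metric_names))
  masks <- lapply(mask_sizes, function(m) sort(sample(n_rois, m)))
  make_metric_table(vals, masks, outcomes)
}

test_that("ROI feature assembly conserves labels and counts", {
  # 94 patients x 90 ROIs with 626 resection ROIs total
  sizes <- rep(c(6, 7), times = c(32, 62))       # 32*6 + 62*7 = 626
  mt <- random_metric_table(94, 90, sizes)
  fm <- build_roi_features(mt)
  expect_equal(nrow(fm$features), 94 * 90)
  expect_equal(ncol(fm$features), 4)
  expect_equal(sum(fm$labels == "resection"), 626)
  expect_equal(sum(fm$labels == "non_resection"), 7834)
  expect_equal(sum(fm$labels == "resection"), sum(lengths(attr(mt, "masks"))))

  # single patient with everything resected: no negatives
  mt1 <- random_metric_table(1, 90, 90)
  fm1 <- build_roi_features(mt1)
  expect_equal(sum(fm1$labels == "resection"), 90)
  expect_equal(sum(fm1$labels == "non_resection"), 0)
})

test_that("patient feature assembly yields 384 aligned columns", {
  outcomes <- rep(c("seizure_free", "not_seizure_free"), times = c(4, 2))
  mt <- random_metric_table(6, 90, rep(5, 6), outcomes)
  fm <- build_patient_features(mt)
  expect_equal(dim(fm$features), c(6, 4 * 90 + 24))
  expect_equal(as.character(fm$labels), outcomes)
  # metric-major, ROI-minor ordering of the ROI block
  expect_equal(unname(fm$features[2, "low_high_ratio_roi7"]),
               mt[2, 7, "low_high_ratio"])
  expect_equal(unname(fm$features[5, "delta_power_roi90"]),
               mt[5, 90, "delta_power"])
  # averaged-measure block matches a direct computation
  am <- averaged_measures(mt[3, , "mean_pli"], attr(mt, "masks")[[3]])
  expect_equal(unname(fm$features[3, "mean_pli_resection"]),
               unname(am["resection"]))
})

test_that("z-scoring centres and scales each column, dropping constants", {
  mt <- random_metric_table(10, 20, rep(3, 10))
  fm <- build_roi_features(mt)
  z <- zscore_features(fm)
  expect_true(all(abs(colMeans(z$features)) < 1e-12))
  expect_true(all(abs(apply(z$features, 2, sd) - 1) < 1e-12))

  fm$features[, 2] <- 5
  expect_warning(z2 <- zscore_features(fm), "zero-variance")
  expect_equal(ncol(z2$features), 3)

  # two-point column under both sd conventions
  fm2 <- fm
  fm2$features <- matrix(c(0, 2, 1, 3), 2, 2)
  colnames(fm2$features) <- c("a", "b")
  expect_equal(zscore_features(fm2)$features[, 1],
               c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(zscore_features(fm2, sd_type = "population")$features[, 1],
               c(-1, 1), tolerance = 1e-12)
})

test_that("balanced subsampling yields exactly equal classes, reproducibly", {
  sizes <- rep(c(6, 7), times = c(32, 62))
  mt <- random_metric_table(94, 90, sizes)
  fm <- build_roi_features(mt)
  rounds <- subsample_balanced(fm, n_rounds = 10, seed = 5)
  expect_length(rounds, 10)
  for (idx in rounds) {
    expect_equal(as.integer(table(fm$labels[idx])), c(626L, 626L))
  }
  expect_false(identical(rounds[[1]], rounds[[2]]))  # rounds differ
  rounds2 <- subsample_balanced(fm, n_rounds = 10, seed = 5)
  expect_identical(rounds, rounds2)                  # but are seeded

  # already balanced input: all rounds identical membership
  mt_b <- random_metric_table(2, 10, c(5, 5))
  fm_b <- build_roi_features(mt_b)
  r_b <- subsample_balanced(fm_b, n_rounds = 3, seed = 1)
  expect_true(all(vapply(r_b, function(i) identical(sort(i), 1:20), TRUE)))

  fm_one <- fm_b
  fm_one$labels <- factor(rep("resection", 20),
                          levels = c("non_resection", "resection"))
  expect_error(subsample_balanced(fm_one), "non-empty")
})

test_that("LOOCV separates well-separated clouds and not permuted labels", {
  set.seed(21)
  n <- 30
  X <- rbind(matrix(rnorm(n * 2, 0), n, 2), matrix(rnorm(n * 2, 4), n, 2))
  colnames(X) <- c("f1", "f2")
  labs <- factor(rep(c("non_resection", "resection"), each = n),
                 levels = c("non_resection", "resection"))
  fm <- structure(list(features = X, labels = labs, positive = "resection"),
                  class = "feature_matrix")
  rounds <- subsample_balanced(fm, n_rounds = 2, seed = 2)
  for (clf in c("svm", "forest")) {
    rep_ <- loocv_evaluate(fm, rounds, classifier = clf, n_trees = 100,
                           seed = 3)
    expect_gt(rep_$accuracy_mean, 95)
    expect_equal(rowSums(rep_$confusion), c(2 * n, 2 * n))  # conservation
    expect_true(rep_$accuracy_ci95[1] <= rep_$accuracy_mean)
    expect_true(rep_$accuracy_ci95[2] >= rep_$accuracy_mean)
  }

  fm_null <- fm
  set.seed(22)
  fm_null$labels <- sample(fm$labels)
  rep0 <- loocv_evaluate(fm_null, subsample_balanced(fm_null, 4, seed = 9),
                         classifier = "svm", seed = 4)
  expect_gte(rep0$accuracy_mean, 30)
  expect_lte(rep0$accuracy_mean, 70)
})

test_that("LOOCV is deterministic for a fixed seed, including the forest", {
  set.seed(23)
  X <- matrix(rnorm(40 * 3), 40, 3)
  colnames(X) <- paste0("f", 1:3)
  labs <- factor(rep(c("non_resection", "resection"), 20),
                 levels = c("non_resection", "resection"))
  fm <- structure(list(features = X, labels = labs, positive = "resection"),
                  class = "feature_matrix")
  rounds <- subsample_balanced(fm, 2, seed = 6)
  r1 <- loocv_evaluate(fm, rounds, classifier = "forest", n_trees = 50,
                       seed = 11)
  r2 <- loocv_evaluate(fm, rounds, classifier = "forest", n_trees = 50,
                       seed = 11)
  expect_identical(r1$confusion, r2$confusion)
})

test_that("single-hold-out mode predicts one instance per round", {
  set.seed(24)
  X <- matrix(rnorm(20 * 2), 20, 2)
  colnames(X) <- c("f1", "f2")
  labs <- factor(rep(c("non_resection", "resection"), 10),
                 levels = c("non_resection", "resection"))
  fm <- structure(list(features = X, labels = labs, positive = "resection"),
                  class = "feature_matrix")
  rounds <- subsample_balanced(fm, 8, seed = 7)
  rep_ <- loocv_evaluate(fm, rounds, classifier = "svm", mode = "single",
                         seed = 8)
  expect_equal(unname(rowSums(rep_$confusion)), rep(1, 8))
  expect_equal(rep_$n_rounds, 8)
})

test_that("within-patient correlation depresses null LOOCV accuracy below iid level", {
  # instances of one patient share the same connectivity matrix, so LOOCV
  # without patient stratification "anti-learns" patient identity; breaking
  # the correlation by permuting each feature column restores the iid level
  spec <- cohort_spec(n_patients = 12, n_seizure_free = 12, n_rois = 90,
                      n_epochs = 8, epoch_samples = 1024,
                      sampling_rate = 1250, focus_size = 7,
                      delta_gain = 1, coupling_strength = 0, seed = 808)
  mt <- simulate_metric_cohort(spec)
  fm <- zscore_features(build_roi_features(mt))
  rounds <- subsample_balanced(fm, 2, seed = 1)
  r_clustered <- loocv_evaluate(fm, rounds, classifier = "svm", seed = 2)

  set.seed(3)
  fm_perm <- fm
  for (j in seq_len(ncol(fm_perm$features))) {
    fm_perm$features[, j] <- sample(fm_perm$features[, j])
  }
  r_decorr <- loocv_evaluate(fm_perm, rounds, classifier = "svm", seed = 2)

  expect_lt(r_clustered$accuracy_mean, r_decorr$accuracy_mean)
  expect_gte(r_decorr$accuracy_mean, 40)
  expect_lte(r_decorr$accuracy_mean, 60)
})
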