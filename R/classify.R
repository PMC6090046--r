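#' Assemble the ROI-level feature matrix (resection vs non-resection)
#'
#' One instance per (patient, ROI) with the four metric values as features
#' and the in-resection indicator as label, pooling all patients. This is
#' the individual-level task of telling resected regions from spared ones
#' using only the interictal metrics.
#'
#' @param metric_table A `metric_table` from [compute_metric_table()].
#' @param masks List of resection masks per patient (defaults to those
#'   attached to the table).
#' @return A `feature_matrix`: list with `features`
#'   (instances x 4 matrix), `labels` (factor), `positive`
#'   (`"resection"`).
#' @export
build_roi_features <- function(metric_table, masks = NULL) {
  masks <- metric_table_masks(metric_table, masks)
  n_pat <- dim(metric_table)[1]
  n_rois <- dim(metric_table)[2]
  stopifnot(length(masks) == n_pat)
  for (i in seq_len(n_pat)) {
    if (length(masks[[i]]) > 0 &&
        any(masks[[i]] < 1L | masks[[i]] > n_rois)) {
      stop("mask indices out of range for patient ", i)
    }
  }
  feats <- do.call(rbind, lapply(seq_len(n_pat), function(i) {
    metric_table[i, , , drop = TRUE]
  }))
  colnames(feats) <- dimnames(metric_table)[[3]]
  in_mask <- unlist(lapply(seq_len(n_pat), function(i) {
    seq_len(n_rois) %in% masks[[i]]
  }))
  labels <- factor(ifelse(in_mask, "resection", "non_resection"),
                   levels = c("non_resection", "resection"))
  structure(list(features = feats, labels = labels, positive = "resection"),
            class = "feature_matrix")
}

#' Assemble the patient-level feature matrix (surgery outcome)
#'
#' One instance per patient: the four metrics for every ROI in fixed
#' metric-major, ROI-minor order (4 x n_rois columns) plus the six
#' resection-referenced averages for each metric (24 columns with the
#' standard 90-ROI atlas: 384 features in total), labeled by surgery
#' outcome.
#'
#' @inheritParams build_roi_features
#' @param outcomes Outcome labels per patient (defaults to attached).
#' @param atlas Atlas table for the averaged measures.
#' @return A `feature_matrix` with `positive = "seizure_free"`.
#' @export
build_patient_features <- function(metric_table, masks = NULL,
                                   outcomes = NULL, atlas = aal90_atlas()) {
  masks <- metric_table_masks(metric_table, masks)
  outcomes <- metric_table_outcomes(metric_table, outcomes)
  n_pat <- dim(metric_table)[1]
  n_rois <- dim(metric_table)[2]
  metrics <- dimnames(metric_table)[[3]]
  measure_names <- c("resection", "resection_lobe", "contralateral",
                     "non_resection", "diff_contralateral",
                     "diff_non_resection")
  feats <- matrix(NA_real_, n_pat,
                  length(metrics) * n_rois + length(metrics) * 6)
  cn <- c(
    unlist(lapply(metrics, function(m) paste0(m, "_roi", seq_len(n_rois)))),
    unlist(lapply(metrics, function(m) paste0(m, "_", measure_names)))
  )
  colnames(feats) <- cn
  for (i in seq_len(n_pat)) {
    roi_part <- as.vector(metric_table[i, , ])       # ROI-minor within metric
    avg_part <- unlist(lapply(metrics, function(m) {
      averaged_measures(metric_table[i, , m], masks[[i]], atlas)
    }))
    feats[i, ] <- c(roi_part, avg_part)
  }
  if (anyNA(feats)) stop("missing values in assembled patient features")
  labels <- factor(outcomes, levels = c("not_seizure_free", "seizure_free"))
  structure(list(features = feats, labels = labels,
                 positive = "seizure_free"),
            class = "feature_matrix")
}

#' Z-score every feature column
#'
#' Standardizes each column using mean and standard deviation computed over
#' all instances. Note that standardizing before cross-validation lets
#' test-set statistics leak into training; it is nevertheless the
#' conventional order in several published pipelines and is therefore the
#' default here, with the per-fold alternative available through
#' `loocv_evaluate(rescale_per_fold = TRUE)`.
#'
#' @param fm A `feature_matrix`.
#' @param sd_type `"sample"` (default, n-1 denominator) or `"population"`.
#' @return The `feature_matrix` with standardized columns; zero-variance
#'   columns are dropped with a warning.
#' @export
zscore_features <- function(fm, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  X <- fm$features
  mu <- colMeans(X)
  s <- apply(X, 2, stats::sd)
  if (sd_type == "population") {
    n <- nrow(X)
    s <- s * sqrt((n - 1) / n)
  }
  zero <- s == 0 | !is.finite(s)
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-variance feature(s): ",
            paste(utils::head(colnames(X)[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ..." else "")
    X <- X[, !zero, drop = FALSE]
    mu <- mu[!zero]; s <- s[!zero]
  }
  if (ncol(X) == 0L) stop("no features left after dropping constants")
  fm$features <- sweep(sweep(X, 2, mu), 2, s, "/")
  fm
}

#' Balanced subsampling rounds for a class-imbalanced feature matrix
#'
#' Each round keeps the minority class in full and draws, without
#' replacement, an equally sized subset of the majority class; rounds use
#' consecutive draws from one seeded RNG stream, so the full sequence is
#' reproducible from `seed`.
#'
#' @param fm A `feature_matrix`.
#' @param n_rounds Number of rounds (default 100).
#' @param seed Integer seed.
#' @return List of `n_rounds` integer row-index vectors, each with exactly
#'   equal class counts.
#' @export
subsample_balanced <- function(fm, n_rounds = 100, seed = 1L) {
  labels <- fm$labels
  counts <- table(labels)
  if (length(counts) < 2L || any(counts == 0L)) {
    stop("both classes must be non-empty")
  }
  if (length(counts) != 2L) stop("labels must have exactly two classes")
  minority <- names(counts)[which.min(counts)]
  majority <- setdiff(names(counts), minority)
  idx_min <- which(labels == minority)
  idx_maj <- which(labels == majority)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lapply(seq_len(n_rounds), function(r) {
    sort(c(idx_min, sample(idx_maj, length(idx_min))))
  })
}

fit_predict <- function(train_x, train_y, test_x, classifier, n_trees, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  train_y <- droplevels(train_y)
  if (classifier == "svm") {
    fit <- e1071::svm(train_x, train_y, kernel = "linear", cost = 1,
                      scale = FALSE)
  } else {
    fit <- randomForest::randomForest(
      train_x, train_y, ntree = n_trees,
      mtry = max(1L, floor(sqrt(ncol(train_x))))
    )
  }
  as.character(stats::predict(fit, test_x))
}

#' Leave-one-out evaluation over balanced subsampling rounds
#'
#' Within each balanced round every instance is held out once and predicted
#' by a classifier trained on the remainder (`mode = "full"`); confusion
#' counts are aggregated within the round and accuracy, sensitivity and
#' specificity are averaged across rounds, with the 95% CI for accuracy
#' taken as mean +/- 1.96 x SD/sqrt(n_rounds). `mode = "single"` instead
#' holds out a single randomly chosen instance per round and aggregates the
#' one-per-round predictions, the literal reading of a
#' one-test-instance-per-round protocol.
#'
#' @param fm A `feature_matrix` (typically already through
#'   [zscore_features()]).
#' @param rounds List of row-index vectors from [subsample_balanced()].
#' @param classifier `"svm"` (linear kernel, cost 1, no further tuning) or
#'   `"forest"` (`n_trees` trees, sqrt(p) candidate features per split, no
#'   depth limit).
#' @param n_trees Trees for the forest (default 500).
#' @param mode `"full"` LOOCV over every instance per round (default) or
#'   `"single"` hold-out.
#' @param rescale_per_fold Re-standardize features inside every training
#'   fold (leakage-free variant; default `FALSE`, matching the
#'   standardize-then-split convention of [zscore_features()]).
#' @param seed Integer seed controlling classifier randomness and
#'   single-mode hold-out choice.
#' @return A `classifier_report`: `accuracy_mean`, `accuracy_ci95`,
#'   `sensitivity`, `specificity` (all percent), `n_rounds`, `classifier`,
#'   `mode`.
#' @export
loocv_evaluate <- function(fm, rounds, classifier = c("svm", "forest"),
                           n_trees = 500, mode = c("full", "single"),
                           rescale_per_fold = FALSE, seed = 1L) {
  classifier <- match.arg(classifier)
  mode <- match.arg(mode)
  labels <- as.character(fm$labels)
  pos <- fm$positive
  X <- fm$features

  hold_outs <- NULL
  if (mode == "single") {
    old <- .Random.seed_save()
    set.seed(patient_seed(seed, 999983L))
    hold_outs <- vapply(rounds, function(idx) sample(seq_along(idx), 1L),
                        integer(1))
    .Random.seed_restore(old)
  }

  conf <- matrix(0, length(rounds), 4,
                 dimnames = list(NULL, c("tp", "fp", "fn", "tn")))
  for (r in seq_along(rounds)) {
    idx <- rounds[[r]]
    if (length(idx) < 4L) stop("round ", r, " has fewer than 4 instances")
    test_pos <- if (mode == "full") seq_along(idx) else hold_outs[r]
    for (j in test_pos) {
      tr <- idx[-j]; te <- idx[j]
      train_x <- X[tr, , drop = FALSE]
      test_x <- X[te, , drop = FALSE]
      if (rescale_per_fold) {
        mu <- colMeans(train_x)
        s <- apply(train_x, 2, stats::sd)
        s[s == 0] <- 1
        train_x <- sweep(sweep(train_x, 2, mu), 2, s, "/")
        test_x <- sweep(sweep(test_x, 2, mu), 2, s, "/")
      }
      pred <- fit_predict(train_x, factor(labels[tr]), test_x,
                          classifier, n_trees,
                          seed = patient_seed(seed, r * 100000L + j))
      truth <- labels[te]
      cell <- if (truth == pos && pred == pos) "tp"
      else if (truth != pos && pred == pos) "fp"
      else if (truth == pos && pred != pos) "fn"
      else "tn"
      conf[r, cell] <- conf[r, cell] + 1
    }
  }

  if (mode == "full") {
    acc <- (conf[, "tp"] + conf[, "tn"]) / rowSums(conf)
    sens <- conf[, "tp"] / (conf[, "tp"] + conf[, "fn"])
    spec <- conf[, "tn"] / (conf[, "tn"] + conf[, "fp"])
    acc_mean <- mean(acc)
    ci <- acc_mean + c(-1, 1) * 1.96 * stats::sd(acc) / sqrt(length(rounds))
    sens_mean <- mean(sens, na.rm = TRUE)
    spec_mean <- mean(spec, na.rm = TRUE)
  } else {
    correct <- (conf[, "tp"] + conf[, "tn"]) > 0
    acc_mean <- mean(correct)
    ci <- acc_mean + c(-1, 1) * 1.96 * stats::sd(correct) / sqrt(length(rounds))
    tot <- colSums(conf)
    sens_mean <- tot["tp"] / (tot["tp"] + tot["fn"])
    spec_mean <- tot["tn"] / (tot["tn"] + tot["fp"])
  }
  structure(list(accuracy_mean = 100 * acc_mean,
                 accuracy_ci95 = 100 * pmin(pmax(ci, 0), 1),
                 sensitivity = 100 * sens_mean,
                 specificity = 100 * spec_mean,
                 n_rounds = length(rounds),
                 classifier = classifier,
                 mode = mode,
                 confusion = conf),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("%s (%s LOOCV, %d rounds): accuracy %.2f%% (95%% CI %.2f-%.2f%%), sensitivity %.2f%%, specificity %.2f%%\n",
              x$classifier, x$mode, x$n_rounds, x$accuracy_mean,
              x$accuracy_ci95[1], x$accuracy_ci95[2],
              x$sensitivity, x$specificity))
  invisible(x)
}
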