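#' Does any of the k highest-valued ROIs fall inside the resection?
#'
#' Values are ranked in decreasing order, ties broken by lower ROI index so
#' the result is deterministic; the overlap indicator is true when at least
#' one of the top `k` ROIs belongs to the resection mask.
#'
#' @param values Numeric vector, one metric value per ROI.
#' @param mask Integer vector of resected ROI indices (1-based).
#' @param k Number of top-ranked ROIs to consider.
#' @return Logical scalar.
#' @export
top_k_overlap <- function(values, mask, k) {
  n <- length(values)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  if (length(mask) == 0L) stop("resection mask is empty")
  if (any(mask < 1L | mask > n)) stop("mask indices outside 1..", n)
  top <- order(-values, seq_len(n))[seq_len(k)]
  any(top %in% mask)
}

#' Hypergeometric chance probability of hitting the resection
#'
#' Probability of drawing at least one of the `m` resection ROIs when `n`
#' of the `N` atlas ROIs are selected uniformly without replacement:
#' `1 - C(N-m, n) / C(N, n)`. This is the chance level against which the
#' observed number of patients with top-k overlap is tested.
#'
#' @param N Total number of ROIs (atlas size).
#' @param m Number of resection ROIs, `0 <= m <= N`.
#' @param n Number of draws (the `k` of the top-k rule), `1 <= n <= N`.
#' @return Probability in `[0, 1]`.
#' @examples
#' chance_probability(90, 7, 1)  # 7/90
#' chance_probability(90, 7, 5)  # ~0.3394
#' @export
chance_probability <- function(N, m, n) {
  if (N < 1 || m < 0 || m > N || n < 1 || n > N) {
    stop("need 0 <= m <= N and 1 <= n <= N")
  }
  # P(X >= 1), X ~ Hypergeometric(m successes, N - m failures, n draws)
  1 - stats::phyper(0, m, N - m, n)
}

#' Exact binomial test for the number of patients with overlap
#'
#' Tests whether `n_overlap` successes out of `n_patients` is compatible
#' with the per-patient chance probability `p0`. The default is the exact
#' two-sided test; `alternative = "greater"` gives the one-sided upper
#' tail `P(X >= n_overlap)`.
#'
#' @param n_overlap Number of patients whose top-k ROIs hit the resection.
#' @param n_patients Cohort size.
#' @param p0 Chance probability from [chance_probability()].
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return p-value.
#' @export
binomial_overlap_test <- function(n_overlap, n_patients, p0,
                                  alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (n_overlap < 0 || n_overlap > n_patients) {
    stop("need 0 <= n_overlap <= n_patients")
  }
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  stats::binom.test(n_overlap, n_patients, p = p0,
                    alternative = alternative)$p.value
}

#' Pearson chi-square test of independence for a 2x2 table
#'
#' Without continuity correction, df = 1, two-sided p-value; equivalent to
#' the brute-force sum of (observed - expected)^2 / expected over the four
#' cells.
#'
#' @param table 2x2 matrix of nonnegative counts with positive margins.
#' @return A `group_test` list: `statistic`, `df`, `p`.
#' @export
chi2_independence <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(table < 0)) stop("counts must be nonnegative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: zero margin")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(list(statistic = unname(res$statistic),
                 df = unname(res$parameter),
                 p = res$p.value),
            class = "group_test")
}

#' Unpaired two-sample t-test with pooled variance
#'
#' Student's t with pooled variance and `n1 + n2 - 2` degrees of freedom,
#' two-sided. Accepts either group summaries (mean, sd, n) -- so that tests
#' can be recomputed directly from published summary tables -- or raw
#' samples via `x` and `y`.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @param x,y Optional raw samples; when given, summaries are computed from
#'   them and the summary arguments are ignored.
#' @return A `group_test` list: `statistic`, `df`, `p`.
#' @examples
#' pooled_t_test(0.0844, 0.0184, 64, 0.0748, 0.0171, 30)  # t = 2.41
#' @export
pooled_t_test <- function(mean1, sd1, n1, mean2, sd2, n2, x = NULL, y = NULL) {
  if (!is.null(x) || !is.null(y)) {
    if (is.null(x) || is.null(y)) stop("supply both x and y, or neither")
    mean1 <- mean(x); sd1 <- stats::sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- stats::sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    if (mean1 == mean2) {
      return(structure(list(statistic = 0, df = df, p = 1),
                       class = "group_test"))
    }
    stop("zero pooled variance with unequal means: t statistic is infinite")
  }
  t_stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  structure(list(statistic = t_stat, df = df,
                 p = 2 * stats::pt(-abs(t_stat), df)),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat("statistic =", signif(x$statistic, 4), " df =", x$df,
      " p =", signif(x$p, 4), "\n")
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values for a family of `m_tests` tests:
#' `adj_(i) = min over j >= i of (m_tests / j) * p_(j)`, capped at 1 and
#' mapped back to the input order. `m_tests` may exceed the number of
#' supplied p-values when only part of a family is being adjusted.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param m_tests Family size (default `length(p_values)`).
#' @return Adjusted p-values in input order.
#' @export
fdr_bh <- function(p_values, m_tests = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  if (m_tests < length(p_values)) stop("m_tests must be >= length(p_values)")
  stats::p.adjust(p_values, method = "BH", n = m_tests)
}

#' Six resection-referenced averages of a metric
#'
#' Summarizes one patient's per-ROI metric relative to the resection:
#' (1) mean over resection ROIs, (2) mean over all ROIs in the lobe(s)
#' touched by the resection, (3) mean over the contralateral homologs of
#' the resection ROIs, (4) mean over all non-resection ROIs,
#' (5) = (1) - (3), and (6) = (1) - (4). Resection ROIs without a homolog
#' in the atlas are excluded from (3) with a warning.
#'
#' @param values Numeric vector, one value per ROI.
#' @param mask Integer vector of resected ROI indices.
#' @param atlas Atlas table from [aal90_atlas()] (needs `lobe` and
#'   `homolog` columns covering every ROI).
#' @return Named numeric vector: `resection`, `resection_lobe`,
#'   `contralateral`, `non_resection`, `diff_contralateral`,
#'   `diff_non_resection`.
#' @export
averaged_measures <- function(values, mask, atlas = aal90_atlas()) {
  n <- length(values)
  if (nrow(atlas) != n) {
    stop("atlas covers ", nrow(atlas), " ROIs but metric vector has ", n)
  }
  if (length(mask) == 0L || any(mask < 1L | mask > n)) {
    stop("mask must be a non-empty set of indices in 1..", n)
  }
  mask <- unique(as.integer(mask))
  lobes <- unique(atlas$lobe[mask])
  in_lobe <- which(atlas$lobe %in% lobes)
  hom <- atlas$homolog[mask]
  bad <- is.na(hom) | hom < 1L | hom > n
  if (any(bad)) {
    warning("excluding ", sum(bad), " resection ROI(s) without homolog ",
            "from the contralateral average")
    hom <- hom[!bad]
  }
  outside <- setdiff(seq_len(n), mask)
  m1 <- mean(values[mask])
  m2 <- mean(values[in_lobe])
  m3 <- if (length(hom) > 0) mean(values[hom]) else NA_real_
  m4 <- if (length(outside) > 0) mean(values[outside]) else NA_real_
  c(resection = m1, resection_lobe = m2, contralateral = m3,
    non_resection = m4, diff_contralateral = m1 - m3,
    diff_non_resection = m1 - m4)
}

#' Group-level overlap table: observed vs chance
#'
#' For every metric and every `k` in `1..k_max`, counts the patients whose
#' `k` highest-valued ROIs hit their resection mask, computes the
#' hypergeometric chance level, tests the count with an exact binomial
#' test, and FDR-adjusts over the whole `metrics x k` family.
#'
#' @param metric_table A `metric_table` from [compute_metric_table()].
#' @param masks List of resection masks, one per patient (defaults to the
#'   masks attached to the table).
#' @param k_max Largest top-k rule (default 5).
#' @param chance `"median"` (default): one chance level per k from the
#'   cohort-median mask size; `"per_patient"`: average of the per-patient
#'   exact chance probabilities.
#' @param alternative Sidedness of the binomial test, see
#'   [binomial_overlap_test()].
#' @return data.frame: `metric`, `k`, `n_overlap`, `n_patients`,
#'   `chance_p0`, `binomial_p`, `fdr_p`.
#' @export
overlap_table <- function(metric_table, masks = NULL, k_max = 5,
                          chance = c("median", "per_patient"),
                          alternative = c("two.sided", "greater")) {
  chance <- match.arg(chance)
  alternative <- match.arg(alternative)
  masks <- metric_table_masks(metric_table, masks)
  n_pat <- dim(metric_table)[1]
  n_rois <- dim(metric_table)[2]
  stopifnot(length(masks) == n_pat)
  sizes <- lengths(masks)
  m_med <- stats::median(sizes)
  metrics <- dimnames(metric_table)[[3]]
  metrics <- metrics[!apply(metric_table, 3, anyNA)]

  rows <- list()
  for (met in metrics) {
    for (k in seq_len(k_max)) {
      hits <- vapply(seq_len(n_pat), function(i) {
        top_k_overlap(metric_table[i, , met], masks[[i]], k)
      }, logical(1))
      p0 <- if (chance == "median") {
        chance_probability(n_rois, m_med, k)
      } else {
        mean(vapply(sizes, function(m) chance_probability(n_rois, m, k),
                    numeric(1)))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        metric = met, k = k, n_overlap = sum(hits), n_patients = n_pat,
        chance_p0 = p0,
        binomial_p = binomial_overlap_test(sum(hits), n_pat, p0, alternative)
      )
    }
  }
  out <- do.call(rbind, rows)
  out$fdr_p <- fdr_bh(out$binomial_p)
  out
}

#' Overlap-by-outcome table: chi-square tests between surgery outcomes
#'
#' For every metric and `k`, cross-tabulates overlap (yes/no) against
#' surgery outcome and applies the uncorrected Pearson chi-square test of
#' independence, FDR-adjusted over the family. Tables with a zero margin
#' (e.g. every patient overlapping) yield `NA` p-values.
#'
#' @inheritParams overlap_table
#' @param outcomes Character vector of outcomes per patient
#'   (`"seizure_free"` / `"not_seizure_free"`); defaults to those attached
#'   to the table.
#' @return data.frame: `metric`, `k`, `sf_pct`, `nsf_pct`, `chi2`, `df`,
#'   `p`, `fdr_p`.
#' @export
group_overlap_table <- function(metric_table, masks = NULL, outcomes = NULL,
                                k_max = 5) {
  masks <- metric_table_masks(metric_table, masks)
  outcomes <- metric_table_outcomes(metric_table, outcomes)
  n_pat <- dim(metric_table)[1]
  stopifnot(length(masks) == n_pat, length(outcomes) == n_pat)
  sf <- outcomes == "seizure_free"
  metrics <- dimnames(metric_table)[[3]]
  metrics <- metrics[!apply(metric_table, 3, anyNA)]

  rows <- list()
  for (met in metrics) {
    for (k in seq_len(k_max)) {
      hits <- vapply(seq_len(n_pat), function(i) {
        top_k_overlap(metric_table[i, , met], masks[[i]], k)
      }, logical(1))
      tab <- rbind(c(sum(hits & sf), sum(!hits & sf)),
                   c(sum(hits & !sf), sum(!hits & !sf)))
      res <- tryCatch(chi2_independence(tab),
                      error = function(e) list(statistic = NA_real_,
                                               df = NA_real_, p = NA_real_))
      rows[[length(rows) + 1L]] <- data.frame(
        metric = met, k = k,
        sf_pct = 100 * mean(hits[sf]), nsf_pct = 100 * mean(hits[!sf]),
        chi2 = res$statistic, df = res$df, p = res$p
      )
    }
  }
  out <- do.call(rbind, rows)
  out$fdr_p <- fdr_bh(out$p)
  out
}

#' Averaged-measures table: outcome-group comparison of the six averages
#'
#' Computes the six resection-referenced averages per patient and metric,
#' then compares seizure-free and not-seizure-free groups with pooled
#' t-tests, FDR-adjusted over the `metrics x 6` family.
#'
#' @inheritParams group_overlap_table
#' @param atlas Atlas table from [aal90_atlas()].
#' @return data.frame: `metric`, `measure`, `mean_sf`, `sd_sf`, `mean_nsf`,
#'   `sd_nsf`, `t`, `df`, `p`, `fdr_p`.
#' @export
averaged_measures_table <- function(metric_table, masks = NULL,
                                    outcomes = NULL, atlas = aal90_atlas()) {
  masks <- metric_table_masks(metric_table, masks)
  outcomes <- metric_table_outcomes(metric_table, outcomes)
  n_pat <- dim(metric_table)[1]
  sf <- outcomes == "seizure_free"
  if (sum(sf) < 2 || sum(!sf) < 2) stop("each outcome group needs >= 2 patients")
  metrics <- dimnames(metric_table)[[3]]
  metrics <- metrics[!apply(metric_table, 3, anyNA)]
  measure_names <- c("resection", "resection_lobe", "contralateral",
                     "non_resection", "diff_contralateral",
                     "diff_non_resection")

  rows <- list()
  for (met in metrics) {
    am <- t(vapply(seq_len(n_pat), function(i) {
      averaged_measures(metric_table[i, , met], masks[[i]], atlas)
    }, numeric(6)))
    colnames(am) <- measure_names
    for (ms in measure_names) {
      x <- am[sf, ms]; y <- am[!sf, ms]
      res <- pooled_t_test(x = x, y = y)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = met, measure = ms,
        mean_sf = mean(x), sd_sf = stats::sd(x),
        mean_nsf = mean(y), sd_nsf = stats::sd(y),
        t = res$statistic, df = res$df, p = res$p
      )
    }
  }
  out <- do.call(rbind, rows)
  out$fdr_p <- fdr_bh(out$p)
  out
}
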