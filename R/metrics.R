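METRIC_NAMES <- c("delta_power", "low_high_ratio", "mean_pli", "betweenness")

#' Compute the four ROI metrics for one patient
#'
#' Segments the recording into epochs and derives, per ROI: relative delta
#' power, low-to-high frequency power ratio, mean broadband PLI to all
#' other ROIs, and betweenness centrality on the minimum spanning tree of
#' the PLI network.
#'
#' @param timeseries Numeric matrix, ROIs x samples.
#' @param sampling_rate Hz.
#' @param n_epochs,epoch_samples Epoch geometry passed to
#'   [segment_epochs()].
#' @param bands Band table, default [default_bands()]; the broadband PLI
#'   uses the union of the band range (first `f_low` to last `f_high`).
#' @param metrics Which metrics to compute (subset of
#'   `c("delta_power", "low_high_ratio", "mean_pli", "betweenness")`).
#'   Restricting to the spectral metrics skips the connectivity step, which
#'   dominates run time; omitted metrics are returned as `NA`.
#' @return Matrix ROIs x 4 with the metric columns in fixed order.
#' @export
compute_patient_metrics <- function(timeseries, sampling_rate,
                                    n_epochs, epoch_samples,
                                    bands = default_bands(),
                                    metrics = METRIC_NAMES) {
  metrics <- match.arg(metrics, METRIC_NAMES, several.ok = TRUE)
  epochs <- segment_epochs(timeseries, n_epochs, epoch_samples, sampling_rate)
  n_rois <- dim(epochs)[2]
  out <- matrix(NA_real_, n_rois, length(METRIC_NAMES),
                dimnames = list(NULL, METRIC_NAMES))

  if (any(c("delta_power", "low_high_ratio") %in% metrics)) {
    bp <- relative_band_power(epochs, bands)
    if ("delta_power" %in% metrics) out[, "delta_power"] <- bp[, "delta"]
    if ("low_high_ratio" %in% metrics) {
      out[, "low_high_ratio"] <- low_high_ratio(bp)
    }
  }
  if (any(c("mean_pli", "betweenness") %in% metrics)) {
    pm <- pli_matrix(epochs, f_low = min(bands$f_low),
                     f_high = max(bands$f_high))
    if ("mean_pli" %in% metrics) out[, "mean_pli"] <- roi_mean_pli(pm)
    if ("betweenness" %in% metrics) {
      out[, "betweenness"] <- tree_betweenness(mst_from_pli(pm))
    }
  }
  out
}

#' Metric table for a whole cohort
#'
#' Applies [compute_patient_metrics()] to every patient and stacks the
#' results into a `metric_table`: a 3-D array `[patient, roi, metric]`
#' carrying patient ids, resection masks and outcomes as attributes when a
#' `synthetic_cohort` (or manifest-loaded cohort) is supplied.
#'
#' @param cohort A `synthetic_cohort`, or a list of patient-like lists each
#'   with `timeseries`, `sampling_rate`, `patient_id` and optionally
#'   `resection_mask` / `outcome`.
#' @param n_epochs,epoch_samples Epoch geometry; defaults taken from the
#'   cohort spec when present.
#' @param bands Band table.
#' @param metrics Metrics to compute, see [compute_patient_metrics()].
#' @param verbose Print one progress line per patient.
#' @return A `metric_table` array with dimnames
#'   `(patient_id, roi, metric)` and attributes `masks` (list of integer
#'   vectors) and `outcomes` (character).
#' @export
compute_metric_table <- function(cohort, n_epochs = NULL, epoch_samples = NULL,
                                 bands = default_bands(),
                                 metrics = METRIC_NAMES,
                                 verbose = FALSE) {
  has_spec <- is.list(cohort) && !is.null(cohort$patients)
  patients <- if (has_spec) cohort$patients else cohort
  if (has_spec && !is.null(cohort$spec)) {
    if (is.null(n_epochs)) n_epochs <- cohort$spec$n_epochs
    if (is.null(epoch_samples)) epoch_samples <- cohort$spec$epoch_samples
  }
  if (is.null(n_epochs) || is.null(epoch_samples)) {
    stop("n_epochs and epoch_samples are required unless the cohort carries a spec")
  }
  n_pat <- length(patients)
  if (n_pat == 0L) stop("empty cohort")
  n_rois <- nrow(patients[[1]]$timeseries)
  ids <- vapply(patients, function(p) p$patient_id, character(1))
  arr <- array(NA_real_, dim = c(n_pat, n_rois, length(METRIC_NAMES)),
               dimnames = list(ids, NULL, METRIC_NAMES))
  for (i in seq_len(n_pat)) {
    p <- patients[[i]]
    if (nrow(p$timeseries) != n_rois) {
      stop("patient ", p$patient_id, " has ", nrow(p$timeseries),
           " ROIs; expected ", n_rois)
    }
    if (verbose) message("metrics: ", p$patient_id, " (", i, "/", n_pat, ")")
    arr[i, , ] <- compute_patient_metrics(
      p$timeseries, p$sampling_rate, n_epochs, epoch_samples,
      bands = bands, metrics = metrics
    )
  }
  structure(arr,
            masks = lapply(patients, function(p) p$resection_mask),
            outcomes = vapply(patients, function(p) {
              if (is.null(p$outcome)) NA_character_ else p$outcome
            }, character(1)),
            class = c("metric_table", "array"))
}

metric_table_masks <- function(metric_table, masks = NULL) {
  if (!is.null(masks)) return(masks)
  m <- attr(metric_table, "masks")
  if (is.null(m)) stop("no resection masks supplied or attached to the table")
  m
}

metric_table_outcomes <- function(metric_table, outcomes = NULL) {
  if (!is.null(outcomes)) return(outcomes)
  o <- attr(metric_table, "outcomes")
  if (is.null(o) || anyNA(o)) {
    stop("no outcomes supplied or attached to the table")
  }
  o
}

#' Simulate a cohort and compute its metric table, streaming patient-wise
#'
#' Equivalent to `compute_metric_table(generate_cohort(spec))` but each
#' patient's time series is generated, reduced to metrics and discarded
#' before the next one, so cohort size is not limited by memory. This is
#' the recommended entry point for simulation studies.
#'
#' @param spec A [cohort_spec()].
#' @param bands Band table.
#' @param metrics Metrics to compute, see [compute_patient_metrics()].
#' @param verbose Progress messages.
#' @return A `metric_table` with `masks` and `outcomes` attached; focus
#'   sets are attached as attribute `foci`.
#' @export
simulate_metric_cohort <- function(spec, bands = default_bands(),
                                   metrics = METRIC_NAMES, verbose = FALSE) {
  validate_cohort_spec(spec)
  n_pat <- spec$n_patients
  if (n_pat == 0L) stop("empty cohort")
  arr <- array(NA_real_, dim = c(n_pat, spec$n_rois, length(METRIC_NAMES)),
               dimnames = list(sprintf("P%03d", seq_len(n_pat)), NULL,
                               METRIC_NAMES))
  masks <- vector("list", n_pat)
  foci <- vector("list", n_pat)
  outcomes <- character(n_pat)
  for (i in seq_len(n_pat)) {
    outcome <- if (i <= spec$n_seizure_free) "seizure_free" else "not_seizure_free"
    p <- generate_patient(spec, outcome = outcome,
                          seed = patient_seed(spec$seed, i),
                          patient_id = sprintf("P%03d", i))
    if (verbose) message("simulate+metrics: ", p$patient_id, " (", i, "/",
                         n_pat, ")")
    arr[i, , ] <- compute_patient_metrics(
      p$timeseries, p$sampling_rate, spec$n_epochs, spec$epoch_samples,
      bands = bands, metrics = metrics
    )
    masks[[i]] <- p$resection_mask
    foci[[i]] <- p$focus
    outcomes[i] <- p$outcome
  }
  structure(arr, masks = masks, foci = foci, outcomes = outcomes,
            class = c("metric_table", "array"))
}
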