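#' Write / read a ROI time-series matrix as TSV
#'
#' Plain tab-separated numeric matrix, ROIs as rows, no header, '.' decimal
#' separator, full floating precision -- a bit-exact interchange format for
#' virtual-electrode time series.
#'
#' @param timeseries Numeric matrix, ROIs x samples.
#' @param path Output file.
#' @export
write_timeseries <- function(timeseries, path) {
  stopifnot(is.matrix(timeseries))
  # %.17g guarantees the decimal text parses back to the identical double
  chr <- matrix(sprintf("%.17g", timeseries), nrow = nrow(timeseries))
  data.table::fwrite(data.table::as.data.table(chr), path,
                     sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param n_rois Expected channel count; when an `atlas` is given it
#'   defaults to the atlas size and a mismatch error names the absent ROIs.
#' @param atlas Optional atlas table from [aal90_atlas()].
#' @return `read_timeseries` returns the ROIs x samples matrix.
#' @export
read_timeseries <- function(path, n_rois = NULL, atlas = NULL) {
  if (!file.exists(path)) stop("cannot read time series: ", path)
  m <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  if (!is.null(atlas) && is.null(n_rois)) n_rois <- nrow(atlas)
  if (!is.null(n_rois) && nrow(m) != n_rois) {
    msg <- paste0("channel/atlas mismatch: file has ", nrow(m),
                  " rows, expected ", n_rois)
    if (!is.null(atlas) && nrow(m) < nrow(atlas)) {
      absent <- atlas$name[(nrow(m) + 1L):nrow(atlas)]
      msg <- paste0(msg, "; absent ROI(s): ",
                    paste(utils::head(absent, 8), collapse = ", "),
                    if (length(absent) > 8) ", ..." else "")
    }
    stop(msg)
  }
  m
}

#' Write a cohort to disk (per-patient TSV + JSON manifest)
#'
#' @param cohort A cohort list with `patients` and `spec` (e.g. from
#'   [generate_cohort()]).
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(cohort$patients, function(p) {
    file <- paste0(p$patient_id, "_timeseries.tsv")
    write_timeseries(p$timeseries, file.path(dir, file))
    list(id = p$patient_id, file = file,
         resection_mask = as.integer(p$resection_mask),
         focus = if (is.null(p$focus)) NULL else as.integer(p$focus),
         outcome = p$outcome)
  })
  manifest <- list(
    atlas = "AAL90",
    sampling_rate = cohort$patients[[1]]$sampling_rate,
    n_rois = nrow(cohort$patients[[1]]$timeseries),
    n_epochs = cohort$spec$n_epochs,
    epoch_samples = cohort$spec$epoch_samples,
    patients = entries
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load a cohort from a manifest directory
#'
#' @param dir Directory containing `manifest.json` and the referenced
#'   time-series files.
#' @return A cohort list (`patients`, `spec`) usable by
#'   [compute_metric_table()].
#' @export
read_cohort <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir)
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- man$patients$id
  if (anyDuplicated(ids)) stop("duplicate patient ids in manifest")
  patients <- lapply(seq_along(ids), function(i) {
    f <- file.path(dir, man$patients$file[i])
    mask <- as.integer(unlist(man$patients$resection_mask[i]))
    if (any(mask < 1L | mask > man$n_rois)) {
      stop("manifest mask indices outside atlas for patient ", ids[i])
    }
    list(patient_id = ids[i],
         timeseries = read_timeseries(f, n_rois = man$n_rois),
         resection_mask = mask,
         outcome = man$patients$outcome[i],
         sampling_rate = man$sampling_rate)
  })
  list(patients = patients,
       spec = list(n_epochs = man$n_epochs,
                   epoch_samples = man$epoch_samples,
                   sampling_rate = man$sampling_rate))
}

# 31-bit multiplicative checksum of a deparsed object; provenance only
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  m <- 2147483647
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 48271 + b) %% m
  sprintf("%08x", h)
}

#' Run the full analysis pipeline and write results to disk
#'
#' Orchestrates cohort acquisition (simulation or manifest loading), metric
#' computation, the group-level overlap and averaged-measures tables, and
#' the individual-level classification tasks, writing CSV/JSON outputs plus
#' a provenance record (config, config hash, seed, package and R versions).
#' Re-running with the same config reproduces identical outputs.
#'
#' @param config A nested list (or path to a JSON file encoding it) with
#'   elements:
#'   \describe{
#'     \item{`cohort`}{either `simulate = <args for [cohort_spec()]>` or
#'       `manifest = <directory>`}
#'     \item{`analysis`}{optional: `k_max` (default 5), `chance`,
#'       `alternative`, `metrics`}
#'     \item{`classify`}{optional: `tasks` (subset of `"roi"`, `"outcome"`),
#'       `classifiers` (subset of `"svm"`, `"forest"`), `n_rounds`
#'       (default 100), `mode`, `n_trees`}
#'     \item{`seed`}{integer used for subsampling and classifiers}
#'   }
#' @param out_dir Output directory.
#' @param verbose Progress messages.
#' @return Invisibly, a list with the in-memory results
#'   (`metric_table`, `overlap`, `group_overlap`, `averaged`, `reports`).
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  # --- cohort -------------------------------------------------------------
  if (!is.null(config$cohort$simulate)) {
    spec <- do.call(cohort_spec, config$cohort$simulate)
    cohort <- generate_cohort(spec)
  } else if (!is.null(config$cohort$manifest)) {
    cohort <- read_cohort(config$cohort$manifest)
    missing_mask <- vapply(cohort$patients,
                           function(p) length(p$resection_mask) == 0L,
                           logical(1))
    missing_out <- vapply(cohort$patients,
                          function(p) is.null(p$outcome) || is.na(p$outcome),
                          logical(1))
    if (any(missing_mask | missing_out)) {
      bad <- vapply(cohort$patients[missing_mask | missing_out],
                    function(p) p$patient_id, character(1))
      stop("incomplete cohort; patients lacking mask or outcome: ",
           paste(bad, collapse = ", "))
    }
  } else {
    stop("config$cohort must contain `simulate` or `manifest`")
  }

  an <- config$analysis
  k_max <- if (is.null(an$k_max)) 5L else as.integer(an$k_max)
  chance <- if (is.null(an$chance)) "median" else an$chance
  alternative <- if (is.null(an$alternative)) "two.sided" else an$alternative
  metrics <- if (is.null(an$metrics)) METRIC_NAMES else an$metrics

  mt <- compute_metric_table(cohort, metrics = metrics, verbose = verbose)
  n_rois <- dim(mt)[2]
  atlas <- if (n_rois == 90L) aal90_atlas() else NULL

  # --- tables -------------------------------------------------------------
  long <- expand.grid(patient_id = dimnames(mt)[[1]], roi = seq_len(n_rois),
                      metric = dimnames(mt)[[3]], KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  long$value <- as.vector(mt)
  if (!is.null(atlas)) long$roi_name <- atlas$name[long$roi]
  write_table <- function(df, name) {
    data.table::fwrite(df, file.path(out_dir, name), sep = ",")
  }
  write_table(long, "metrics.csv")

  ov <- overlap_table(mt, k_max = k_max, chance = chance,
                      alternative = alternative)
  write_table(ov, "overlap.csv")

  outcomes <- attr(mt, "outcomes")
  two_groups <- !anyNA(outcomes) && length(unique(outcomes)) == 2L
  gov <- NULL; am <- NULL
  if (two_groups) {
    gov <- group_overlap_table(mt, k_max = k_max)
    write_table(gov, "group_overlap.csv")
    if (!is.null(atlas) && all(table(outcomes) >= 2)) {
      am <- averaged_measures_table(mt, atlas = atlas)
      write_table(am, "averaged_measures.csv")
    }
  }

  # --- classification -----------------------------------------------------
  cl <- config$classify
  tasks <- if (is.null(cl$tasks)) "roi" else cl$tasks
  classifiers <- if (is.null(cl$classifiers)) "svm" else cl$classifiers
  n_rounds <- if (is.null(cl$n_rounds)) 100L else as.integer(cl$n_rounds)
  mode <- if (is.null(cl$mode)) "full" else cl$mode
  n_trees <- if (is.null(cl$n_trees)) 500L else as.integer(cl$n_trees)

  reports <- list()
  for (task in tasks) {
    fm <- if (task == "roi") {
      build_roi_features(mt)
    } else {
      build_patient_features(mt, atlas = atlas)
    }
    fm <- zscore_features(fm)
    rounds <- subsample_balanced(fm, n_rounds = n_rounds, seed = seed)
    for (clf in classifiers) {
      if (verbose) message("classify: task=", task, " classifier=", clf)
      rep <- loocv_evaluate(fm, rounds, classifier = clf, n_trees = n_trees,
                            mode = mode, seed = seed)
      reports[[paste(task, clf, sep = "_")]] <-
        rep[c("accuracy_mean", "accuracy_ci95", "sensitivity",
              "specificity", "n_rounds", "classifier", "mode")]
    }
  }
  if (length(reports) > 0) {
    jsonlite::write_json(reports, file.path(out_dir, "classification.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  provenance <- list(config = config, config_hash = config_hash(config),
                     seed = seed,
                     package_version = as.character(utils::packageVersion("megfocus")),
                     r_version = R.version.string)
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(metric_table = mt, overlap = ov, group_overlap = gov,
                 averaged = am, reports = reports))
}
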