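#' Canonical six-band definition
#'
#' The six frequency bands used throughout the analysis: delta (0.5-4 Hz),
#' theta (4-8 Hz), lower alpha (8-10 Hz), upper alpha (10-13 Hz), beta
#' (13-30 Hz) and gamma (30-48 Hz). Band membership of a spectral bin is
#' decided by the half-open interval `[f_low, f_high)`, so the shared edges
#' at 4, 8, 10, 13 and 30 Hz are never double counted.
#'
#' @return A data.frame with columns `name`, `f_low`, `f_high` (Hz).
#' @export
default_bands <- function() {
  data.frame(
    name   = c("delta", "theta", "lower_alpha", "upper_alpha", "beta", "gamma"),
    f_low  = c(0.5, 4, 8, 10, 13, 30),
    f_high = c(4, 8, 10, 13, 30, 48),
    stringsAsFactors = FALSE
  )
}

validate_bands <- function(bands, sampling_rate = NULL) {
  stopifnot(is.data.frame(bands), all(c("name", "f_low", "f_high") %in% names(bands)))
  if (any(bands$f_low <= 0) || any(bands$f_high <= bands$f_low)) {
    stop("each band requires 0 < f_low < f_high")
  }
  if (!is.null(sampling_rate) && any(bands$f_high > sampling_rate / 2)) {
    bad <- bands$name[bands$f_high > sampling_rate / 2]
    stop("band(s) beyond the Nyquist frequency (", sampling_rate / 2, " Hz): ",
         paste(bad, collapse = ", "))
  }
  invisible(bands)
}

#' Cut a multichannel recording into contiguous epochs
#'
#' Takes the first `n_epochs` non-overlapping windows of `epoch_samples`
#' consecutive samples, in temporal order, with no filtering, detrending or
#' artifact rejection. This mirrors an analysis protocol in which a fixed
#' number of initial epochs is taken from each recording regardless of
#' content, so that epoch selection cannot bias the metrics.
#'
#' @param timeseries Numeric matrix, ROIs x samples.
#' @param n_epochs Number of epochs to extract.
#' @param epoch_samples Samples per epoch.
#' @param sampling_rate Sampling frequency in Hz.
#' @return An `epoch_array`: a 3-D array `[epoch, roi, sample]` with
#'   attributes `sampling_rate` and `epoch_seconds`.
#' @examples
#' x <- matrix(rnorm(2 * 8192), nrow = 2)
#' ep <- segment_epochs(x, n_epochs = 2, epoch_samples = 4096,
#'                      sampling_rate = 1250)
#' dim(ep)              # 2 x 2 x 4096
#' epoch_duration(ep)   # 3.2768 s
#' @export
segment_epochs <- function(timeseries, n_epochs, epoch_samples, sampling_rate) {
  stopifnot(is.matrix(timeseries), n_epochs >= 1, epoch_samples >= 2,
            sampling_rate > 0)
  needed <- n_epochs * epoch_samples
  avail <- ncol(timeseries)
  if (avail < needed) {
    stop("insufficient samples: need ", needed, " (", n_epochs, " epochs of ",
         epoch_samples, "), have ", avail)
  }
  n_rois <- nrow(timeseries)
  arr <- array(NA_real_, dim = c(n_epochs, n_rois, epoch_samples))
  for (e in seq_len(n_epochs)) {
    cols <- ((e - 1L) * epoch_samples + 1L):(e * epoch_samples)
    arr[e, , ] <- timeseries[, cols, drop = FALSE]
  }
  structure(arr,
            sampling_rate = sampling_rate,
            epoch_seconds = epoch_samples / sampling_rate,
            class = c("epoch_array", "array"))
}

#' Duration of one epoch in seconds
#'
#' @param epochs An `epoch_array` from [segment_epochs()].
#' @param digits Rounding applied to the returned value (default 2, the
#'   precision at which epoch lengths are conventionally reported; use
#'   `Inf` for the exact value).
#' @return Epoch length in seconds.
#' @export
epoch_duration <- function(epochs, digits = 2) {
  secs <- attr(epochs, "epoch_seconds")
  if (is.null(secs)) stop("not an epoch_array")
  if (is.finite(digits)) round(secs, digits) else secs
}

#' One-sided power spectrum of each column of a sample matrix
#'
#' Plain discrete Fourier transform periodogram, no taper, no detrending.
#' Scaled so that the sum of `power` over all returned bins (DC included)
#' equals the mean square of the signal, i.e. Parseval's identity holds
#' exactly up to floating point.
#'
#' @param x Numeric matrix, samples x channels (a single epoch), or a vector.
#' @param sampling_rate Sampling frequency in Hz.
#' @return List with `freq` (Hz, bins 0..floor(n/2)) and `power`
#'   (bins x channels).
#' @export
power_spectrum <- function(x, sampling_rate) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  X <- stats::mvfft(x)
  half <- floor(n / 2)
  keep <- 1L:(half + 1L)                    # DC .. Nyquist
  pw <- Mod(X[keep, , drop = FALSE])^2 / n^2
  # double the interior bins so the one-sided sum preserves total power
  interior <- keep > 1L & (n %% 2L == 1L | keep < half + 1L)
  pw[interior, ] <- 2 * pw[interior, ]
  list(freq = (keep - 1L) * sampling_rate / n, power = pw)
}

#' Relative band power per ROI
#'
#' For every epoch and ROI the discrete Fourier power spectrum is computed,
#' band power is summed over bins whose frequency lies in `[f_low, f_high)`,
#' and relative power is the band share of the total power over the union
#' of the analysis bands (0.5-48 Hz with the defaults). Per-epoch relative
#' powers are then averaged across epochs, keeping the epoch as the unit of
#' analysis. With this convention each ROI's six relative powers sum to 1.
#'
#' @param epochs An `epoch_array` from [segment_epochs()].
#' @param bands Band table as from [default_bands()].
#' @return Matrix ROIs x bands of relative power in `[0, 1]`, class
#'   `band_power_table`.
#' @export
relative_band_power <- function(epochs, bands = default_bands()) {
  stopifnot(inherits(epochs, "epoch_array"))
  fs <- attr(epochs, "sampling_rate")
  validate_bands(bands, sampling_rate = fs)
  n_epochs <- dim(epochs)[1]
  n_rois <- dim(epochs)[2]
  n <- dim(epochs)[3]
  if (fs / n >= min(bands$f_high - bands$f_low)) {
    warning("frequency resolution ", signif(fs / n, 3),
            " Hz is coarser than the narrowest band; band powers will be crude")
  }
  freq <- (0:floor(n / 2)) * fs / n
  membership <- lapply(seq_len(nrow(bands)), function(b) {
    which(freq >= bands$f_low[b] & freq < bands$f_high[b])
  })
  if (any(lengths(membership) == 0L)) {
    stop("band(s) contain no spectral bins at this epoch length / rate: ",
         paste(bands$name[lengths(membership) == 0L], collapse = ", "))
  }
  in_union <- sort(unique(unlist(membership)))

  acc <- matrix(0, n_rois, nrow(bands))
  for (e in seq_len(n_epochs)) {
    ep <- matrix(epochs[e, , , drop = FALSE], nrow = n_rois)  # rois x samples
    ps <- power_spectrum(t(ep), fs)$power
    total <- colSums(ps[in_union, , drop = FALSE])
    if (any(total <= 0)) {
      stop("zero in-band power for ROI(s) ",
           paste(which(total <= 0), collapse = ", "), " in epoch ", e)
    }
    for (b in seq_len(nrow(bands))) {
      acc[, b] <- acc[, b] +
        colSums(ps[membership[[b]], , drop = FALSE]) / total
    }
  }
  rel <- acc / n_epochs
  dimnames(rel) <- list(NULL, bands$name)
  structure(rel, class = c("band_power_table", "matrix"))
}

#' Low-to-high frequency power ratio
#'
#' The summed relative power of the slow bands (delta + theta) divided by
#' the relative power of the lower alpha band, per ROI. Large values mark
#' regions whose spectrum is shifted toward pathological slow activity.
#'
#' @param powers A `band_power_table` (ROIs x bands) containing columns
#'   `delta`, `theta` and `lower_alpha`.
#' @return Numeric vector, one ratio per ROI.
#' @examples
#' p <- matrix(c(0.2, 0.2, 0.2, 0.2, 0.1, 0.1), nrow = 1,
#'             dimnames = list(NULL, c("delta", "theta", "lower_alpha",
#'                                     "upper_alpha", "beta", "gamma")))
#' low_high_ratio(p)  # (0.2 + 0.2) / 0.2 = 2
#' @export
low_high_ratio <- function(powers) {
  need <- c("delta", "theta", "lower_alpha")
  if (!all(need %in% colnames(powers))) {
    stop("band power table must contain columns: ", paste(need, collapse = ", "))
  }
  la <- powers[, "lower_alpha"]
  if (any(la <= 0)) {
    stop("low/high ratio undefined: zero lower-alpha power in ROI(s) ",
         paste(which(la <= 0), collapse = ", "))
  }
  unname((powers[, "delta"] + powers[, "theta"]) / la)
}
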