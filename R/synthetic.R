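#' Specify a synthetic MEG cohort
#'
#' Bundles the parameters of the synthetic cohort generator. The defaults
#' mirror the structure of a presurgical MEG cohort analysed at source
#' level: 90 AAL regions sampled at 1250 Hz, 174 epochs of 4096 samples per
#' patient, resection masks of 1-12 regions with median 7, and a designated
#' epileptogenic focus whose regions carry elevated delta power and lagged
#' phase coupling. Whether the resection covers the focus depends on the
#' simulated surgery outcome: seizure-free patients have their focus
#' resected with probability `resection_focus_overlap_sf` per focus region,
#' not-seizure-free patients with the lower
#' `resection_focus_overlap_nsf`, encoding the premise that persistent
#' seizures indicate an unresected epileptogenic zone.
#'
#' @param n_patients Number of patients.
#' @param n_seizure_free Number with seizure-free outcome
#'   (`<= n_patients`).
#' @param n_rois Number of atlas regions (default 90).
#' @param n_epochs Epochs per patient (default 174).
#' @param epoch_samples Samples per epoch (default 4096).
#' @param sampling_rate Hz (default 1250).
#' @param resection_size_range Inclusive integer range of resection-mask
#'   sizes (default `c(1, 12)`). With the default range, sizes are drawn as
#'   `1 + Binomial(11, 0.55)`, which has support 1-12 and median 7; any
#'   other range is sampled uniformly.
#' @param focus_size Number of focus regions (default 7, matching the
#'   median resection extent).
#' @param delta_gain Multiplicative amplitude gain (>= 1) applied to the
#'   delta band (0.5-4 Hz) of focus regions; 1 disables the spectral
#'   effect. Default 2.
#' @param coupling_strength Fraction in `[0, 1]` of shared lagged signal
#'   mixed into focus regions; 0 disables the connectivity effect.
#'   Default 0.3.
#' @param resection_focus_overlap_sf,resection_focus_overlap_nsf Per-focus-
#'   region probability that the resection includes it, for seizure-free
#'   (default 0.9) and not-seizure-free (default 0.25) patients.
#' @param seed Integer cohort seed; per-patient streams are derived from it
#'   so each patient is reproducible independently of generation order.
#' @return A validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients,
                        n_seizure_free,
                        n_rois = 90,
                        n_epochs = 174,
                        epoch_samples = 4096,
                        sampling_rate = 1250,
                        resection_size_range = c(1L, 12L),
                        focus_size = 7,
                        delta_gain = 2,
                        coupling_strength = 0.3,
                        resection_focus_overlap_sf = 0.9,
                        resection_focus_overlap_nsf = 0.25,
                        seed = 1L) {
  spec <- list(
    n_patients = as.integer(n_patients),
    n_seizure_free = as.integer(n_seizure_free),
    n_rois = as.integer(n_rois),
    n_epochs = as.integer(n_epochs),
    epoch_samples = as.integer(epoch_samples),
    sampling_rate = sampling_rate,
    resection_size_range = as.integer(resection_size_range),
    focus_size = as.integer(focus_size),
    delta_gain = delta_gain,
    coupling_strength = coupling_strength,
    resection_focus_overlap_sf = resection_focus_overlap_sf,
    resection_focus_overlap_nsf = resection_focus_overlap_nsf,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_patients < 0L) stop("invalid spec: n_patients < 0")
    if (n_seizure_free < 0L || n_seizure_free > n_patients) {
      stop("invalid spec: need 0 <= n_seizure_free <= n_patients")
    }
    if (n_rois < 2L) stop("invalid spec: n_rois < 2")
    if (focus_size < 1L || focus_size > n_rois) {
      stop("invalid spec: focus_size must be in [1, n_rois]")
    }
    if (length(resection_size_range) != 2L ||
        resection_size_range[1] < 1L ||
        resection_size_range[2] > n_rois ||
        resection_size_range[1] > resection_size_range[2]) {
      stop("invalid spec: resection_size_range must lie within [1, n_rois]")
    }
    if (delta_gain < 1) stop("invalid spec: delta_gain must be >= 1")
    fr <- c(coupling_strength, resection_focus_overlap_sf,
            resection_focus_overlap_nsf)
    if (any(fr < 0 | fr > 1)) {
      stop("invalid spec: fractions must lie in [0, 1]")
    }
    if (n_epochs < 1L || epoch_samples < 8L || sampling_rate <= 0) {
      stop("invalid spec: epoch geometry")
    }
  })
  invisible(spec)
}

# Deterministic per-patient seed from (cohort seed, patient index) via a
# Lehmer-style mix; keeps all intermediates below 2^53 and results in
# [1, 2^31 - 2] so they are valid set.seed() inputs on any platform.
patient_seed <- function(cohort_seed, patient_index) {
  m <- 2147483647
  h <- (abs(as.numeric(cohort_seed)) %% m)
  h <- (h * 48271 + 11) %% m
  h <- (h + as.numeric(patient_index)) %% m
  h <- (h * 48271 + 11) %% m
  as.integer(h %% (m - 1) + 1)
}

# Amplitude profile of the background spectrum: 1/f-like decay (power ~ 1/f,
# flattened below 0.5 Hz) plus an alpha-band oscillatory bump near 10 Hz,
# which gives realistic nonzero power in all six analysis bands.
background_amplitude <- function(freq) {
  1 / sqrt(pmax(freq, 0.5)) + 0.6 * exp(-(freq - 10)^2 / (2 * 1.5^2))
}

# Real-valued shaped Gaussian noise, built in the frequency domain: complex
# Gaussian coefficients scaled by the amplitude profile, Hermitian-
# symmetrized, inverse transformed, standardized to unit sd.
shaped_noise <- function(n, fs) {
  half <- floor(n / 2)
  freq <- (1:half) * fs / n
  amp <- background_amplitude(freq)
  coef <- complex(real = rnorm(half), imaginary = rnorm(half)) * amp
  spec <- complex(real = numeric(n))
  spec[2:(half + 1)] <- coef
  if (n %% 2 == 0) {
    spec[half + 1] <- complex(real = rnorm(1) * amp[half])  # Nyquist bin real
    spec[n:(n - half + 2)] <- Conj(coef[1:(half - 1)])
  } else {
    spec[n:(n - half + 1)] <- Conj(coef[1:half])
  }
  x <- Re(stats::fft(spec, inverse = TRUE)) / sqrt(n)
  x / stats::sd(x)
}

# Broadband analytic (positive-frequency) signal with the same amplitude
# profile as the background; the common source shared by the focus regions.
# Each focus region receives Re(z * exp(i * phi_j)) -- a constant phase
# rotation at every frequency -- so pairwise phase lags are constant and
# strictly between 0 and pi, the regime the PLI detects. Because its
# spectrum matches the background, mixing it in does not distort the
# relative band-power profile of focus regions.
shared_analytic <- function(n, fs) {
  half <- floor(n / 2)
  freq <- (1:half) * fs / n
  amp <- background_amplitude(freq)
  coef <- complex(real = rnorm(half), imaginary = rnorm(half)) * amp
  spec <- complex(real = numeric(n))
  spec[2:(half + 1)] <- coef
  z <- stats::fft(spec, inverse = TRUE) / sqrt(n)
  z / stats::sd(Re(z))
}

# Multiply the amplitude of spectral bins with frequency in [band) by
# `gain`, preserving phases; used to inject the focal delta-power effect.
apply_band_gain <- function(x, fs, gain, band = c(0.5, 4)) {
  if (gain == 1) return(x)
  n <- length(x)
  freq <- (0:(n - 1)) * fs / n
  freq_mirror <- fs - freq
  sel <- (freq >= band[1] & freq < band[2]) |
    (freq_mirror >= band[1] & freq_mirror < band[2])
  X <- stats::fft(x)
  X[sel] <- X[sel] * gain
  Re(stats::fft(X, inverse = TRUE)) / n
}

draw_resection_size <- function(range) {
  if (identical(as.integer(range), c(1L, 12L))) {
    1L + rbinom(1L, 11L, 0.55)                # support 1..12, median 7
  } else {
    sample(range[1]:range[2], 1L)
  }
}

#' Generate one synthetic patient
#'
#' Background activity per ROI is Gaussian noise with a 1/f-like amplitude
#' decay plus an 8-13 Hz alpha oscillation, giving realistic nonzero power
#' in all six analysis bands. Focus regions additionally receive (a) a
#' delta-band amplitude gain of `delta_gain` and (b) a share
#' `coupling_strength` of a common broadband signal whose spectrum matches
#' the background, injected with a distinct constant phase rotation per
#' focus region (multiples of one ninth of a cycle) so every pairwise lag
#' is strictly between 0 and pi -- the regime the phase lag index is
#' sensitive to, while leaving relative band powers undistorted. The
#' delta gain is applied to the mixed signal, so both effects coexist.
#' The resection mask covers each
#' focus region with the outcome-dependent probability and is topped up
#' with non-focus regions to the drawn resection size, so not-seizure-free
#' patients tend to have resections displaced off the focus.
#'
#' @param spec A [cohort_spec()].
#' @param outcome `"seizure_free"` or `"not_seizure_free"`.
#' @param seed Integer seed for this patient's RNG stream (default derived
#'   from `spec$seed` and patient index 1).
#' @param patient_id Identifier string.
#' @return A `synthetic_patient` list: `patient_id`, `timeseries`
#'   (ROIs x samples), `resection_mask`, `focus`, `outcome`,
#'   `sampling_rate`.
#' @export
generate_patient <- function(spec,
                             outcome = c("seizure_free", "not_seizure_free"),
                             seed = patient_seed(spec$seed, 1L),
                             patient_id = "P001") {
  validate_cohort_spec(spec)
  outcome <- match.arg(outcome)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n_rois <- spec$n_rois
  n <- spec$n_epochs * spec$epoch_samples
  fs <- spec$sampling_rate
  focus <- sort(sample.int(n_rois, spec$focus_size))

  ts <- matrix(0, nrow = n_rois, ncol = n)
  for (r in seq_len(n_rois)) {
    ts[r, ] <- shaped_noise(n, fs)
  }
  c_str <- spec$coupling_strength
  z <- if (c_str > 0 && spec$focus_size >= 2L) shared_analytic(n, fs) else NULL
  for (j in seq_along(focus)) {
    x <- ts[focus[j], ]
    if (!is.null(z)) {
      rot <- Re(z * exp(1i * j * 2 * pi / 9))   # lags ~1/9 cycle apart
      x <- sqrt(1 - c_str^2) * x + c_str * rot  # power-preserving mix
    }
    ts[focus[j], ] <- apply_band_gain(x, fs, spec$delta_gain)
  }

  p_cover <- if (outcome == "seizure_free") {
    spec$resection_focus_overlap_sf
  } else {
    spec$resection_focus_overlap_nsf
  }
  size <- draw_resection_size(spec$resection_size_range)
  covered <- focus[runif(spec$focus_size) < p_cover]
  mask <- covered
  fill_needed <- size - length(covered)
  if (fill_needed > 0L) {
    pool <- setdiff(seq_len(n_rois), focus)
    mask <- c(mask, sample(pool, min(fill_needed, length(pool))))
  }
  if (length(mask) == 0L) {
    mask <- sample(setdiff(seq_len(n_rois), focus), 1L)
  }
  mask <- sort(mask)

  structure(list(patient_id = patient_id,
                 timeseries = ts,
                 resection_mask = mask,
                 focus = focus,
                 outcome = outcome,
                 sampling_rate = fs),
            class = "synthetic_patient")
}

#' Generate a synthetic cohort
#'
#' The first `n_seizure_free` patients are seizure-free, the remainder are
#' not. Each patient's RNG stream is derived by hashing the cohort seed
#' with the patient index, so individual patients can be regenerated
#' independently and the cohort is bit-reproducible for a given spec.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort`: list with elements `patients` (list of
#'   `synthetic_patient`) and `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  patients <- vector("list", spec$n_patients)
  for (i in seq_len(spec$n_patients)) {
    outcome <- if (i <= spec$n_seizure_free) "seizure_free" else "not_seizure_free"
    patients[[i]] <- generate_patient(
      spec, outcome = outcome,
      seed = patient_seed(spec$seed, i),
      patient_id = sprintf("P%03d", i)
    )
  }
  structure(list(patients = patients, spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  sf <- sum(vapply(x$patients, function(p) p$outcome == "seizure_free", TRUE))
  cat("synthetic_cohort:", length(x$patients), "patients (", sf,
      "seizure-free ),", x$spec$n_rois, "ROIs,",
      x$spec$n_epochs, "x", x$spec$epoch_samples, "samples @",
      x$spec$sampling_rate, "Hz\n")
  invisible(x)
}

# save/restore the global RNG state so generators do not perturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
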