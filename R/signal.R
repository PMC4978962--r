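#' Frequency band specification
#'
#' @param name band name, one of `delta`, `theta`, `alpha`, `beta`.
#' @param f_lo,f_hi band edges in Hz, `0 < f_lo < f_hi`.
#' @return a `band_spec` object.
#' @export
band_spec <- function(name, f_lo, f_hi) {
  name <- match.arg(name, c("delta", "theta", "alpha", "beta"))
  if (!(is.finite(f_lo) && is.finite(f_hi) && 0 < f_lo && f_lo < f_hi)) {
    .stopf("plvmotif_domain_error", "band edges must satisfy 0 < f_lo < f_hi")
  }
  structure(list(name = name, f_lo = f_lo, f_hi = f_hi), class = "band_spec")
}

#' Default analysis bands
#'
#' The four canonical bands: delta (2-3.9 Hz), theta (4.1-7.9 Hz),
#' alpha (8.1-11.9 Hz) and beta (12.1-29.9 Hz).
#'
#' @return named list of [band_spec()] objects.
#' @export
dmn_bands <- function() {
  list(delta = band_spec("delta", 2, 3.9),
       theta = band_spec("theta", 4.1, 7.9),
       alpha = band_spec("alpha", 8.1, 11.9),
       beta  = band_spec("beta", 12.1, 29.9))
}

#' Zero-phase FIR band-pass filter
#'
#' Windowed-sinc (Hamming) finite impulse response band-pass, applied forward
#' and backward (`two_pass = TRUE`) so the net response has zero phase: an
#' in-band tone is passed with its phase intact and its amplitude preserved,
#' while out-of-band components are strongly attenuated. The default order is
#' 1500 taps at 1000 Hz, scaled proportionally at other sampling rates to
#' preserve the transition width (and rounded to an even tap count).
#'
#' @param ts numeric matrix (nodes x samples) or vector of raw time series.
#' @param band a [band_spec()].
#' @param fs sampling rate in Hz; `band$f_hi` must be below `fs / 2`.
#' @param order filter order; default `round(1500 * fs / 1000)`.
#' @param two_pass apply forward-backward (zero-phase) filtering.
#' @return filtered series, same shape as `ts`.
#' @export
bandpass <- function(ts, band, fs, order = NULL, two_pass = TRUE) {
  vec <- is.null(dim(ts))
  x <- if (vec) matrix(ts, nrow = 1) else as.matrix(ts)
  if (band$f_hi >= fs / 2) {
    .stopf("plvmotif_domain_error", "band edge %.2f Hz is at or above Nyquist (%.2f Hz)",
           band$f_hi, fs / 2)
  }
  if (is.null(order)) order <- round(1500 * fs / 1000)
  order <- 2L * round(order / 2)
  if (ncol(x) <= 3 * order) {
    .stopf("plvmotif_length_error", "signal too short (%d samples) for filter order %d",
           ncol(x), order)
  }
  h <- signal::fir1(order, c(band$f_lo, band$f_hi) / (fs / 2), type = "pass")
  out <- t(apply(x, 1, function(row) {
    if (two_pass) signal::filtfilt(h, row)
    else as.numeric(signal::filter(h, row))
  }))
  if (vec) as.numeric(out) else out
}

#' Trial-set container
#'
#' Holds one subject/session's segmented data as a trials x nodes x samples
#' array, either as real band-limited signals (`kind = "signal"`) or as
#' instantaneous phases (`kind = "phase"`).
#'
#' @param data numeric array, trials x nodes x samples, all finite.
#' @param fs sampling rate in Hz.
#' @param subject_id,session,band metadata carried with the data.
#' @param kind `"signal"` or `"phase"`.
#' @param node_ids optional character node labels (length = node dimension).
#' @param min_trials minimum trial count to accept.
#' @return a `trial_set` object.
#' @export
trial_set <- function(data, fs, subject_id = NA_character_,
                      session = NA_character_, band = NULL,
                      kind = c("signal", "phase"), node_ids = NULL,
                      min_trials = 1) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3) {
    .stopf("plvmotif_data_error", "data must be a trials x nodes x samples array")
  }
  if (any(!is.finite(data))) {
    .stopf("plvmotif_data_error", "trial data contains non-finite samples")
  }
  if (dim(data)[1] < min_trials) {
    .stopf("plvmotif_insufficient_data", "only %d trials available; %d required",
           dim(data)[1], min_trials)
  }
  if (!is.null(node_ids) && length(node_ids) != dim(data)[2]) {
    .stopf("plvmotif_data_error", "node_ids length does not match node dimension")
  }
  structure(list(data = data, fs = fs, subject_id = subject_id,
                 session = session, band = band, kind = kind,
                 node_ids = node_ids),
            class = "trial_set")
}

#' Segment a continuous recording into fixed-length trials
#'
#' Cuts a nodes x samples recording into consecutive non-overlapping trials
#' of `trial_len` seconds, dropping the remainder. Fewer than `min_trials`
#' complete trials is an error: too little clean data for a stable PLV
#' estimate.
#'
#' @param ts numeric matrix, nodes x samples.
#' @param fs sampling rate in Hz; `fs * trial_len` must be an integer.
#' @param trial_len trial length in seconds (default 4).
#' @param min_trials minimum acceptable number of trials (default 15).
#' @inheritParams trial_set
#' @return a [trial_set()].
#' @export
segment_trials <- function(ts, fs, trial_len = 4, min_trials = 15,
                           subject_id = NA_character_, session = NA_character_,
                           band = NULL, kind = "signal") {
  ts <- if (is.null(dim(ts))) matrix(ts, nrow = 1) else as.matrix(ts)
  len <- fs * trial_len
  if (abs(len - round(len)) > 1e-9) {
    .stopf("plvmotif_domain_error", "fs * trial_len must be an integer sample count")
  }
  len <- as.integer(round(len))
  n_trials <- floor(ncol(ts) / len)
  if (n_trials < min_trials) {
    .stopf("plvmotif_insufficient_data",
           "%d complete trials of %g s available; at least %d required",
           n_trials, trial_len, min_trials)
  }
  data <- array(0, dim = c(n_trials, nrow(ts), len))
  for (k in seq_len(n_trials)) {
    data[k, , ] <- ts[, ((k - 1) * len + 1):(k * len), drop = FALSE]
  }
  trial_set(data, fs = fs, subject_id = subject_id, session = session,
            band = band, kind = kind, min_trials = min_trials)
}

# Analytic signal (FFT construction) of each row of x; returns complex matrix.
.analytic_signal <- function(x) {
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else x
  n <- ncol(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  t(apply(x, 1, function(row) stats::fft(stats::fft(row) * h, inverse = TRUE) / n))
}
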