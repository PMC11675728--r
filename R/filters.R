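#' FFT band-pass filter (spectral zeroing)
#'
#' Filters each node's signal by taking the FFT, zeroing every bin whose
#' (two-sided) frequency magnitude falls outside `[f_lo, f_hi]` — the DC bin
#' included — and inverting. This brick-wall spectral filter is applied to the
#' full record at once; the first and last ~100 ms are edge-affected.
#'
#' @param signals a `signal_set` from [simulate_network()], or an N x T
#'   numeric matrix (then `fs` is required).
#' @param f_lo,f_hi passband edges in Hz; `f_hi` must not exceed the Nyquist
#'   frequency.
#' @param fs sampling rate in Hz, only when `signals` is a bare matrix.
#' @return Same type as the input: a `signal_set` with filtered `values`, or
#'   a filtered matrix.
#' @export
bandpass_fft <- function(signals, f_lo, f_hi, fs = NULL) {
  x <- signal_values(signals)
  fs <- signal_fs(signals, fs)
  if (f_lo <= 0 || f_hi <= f_lo)
    stop("need 0 < f_lo < f_hi", call. = FALSE)
  if (f_hi > fs / 2)
    stop("`f_hi` (", f_hi, " Hz) exceeds the Nyquist frequency (", fs / 2,
         " Hz)", call. = FALSE)
  out <- fft_mask_filter(x, fs, function(f_abs) f_abs >= f_lo & f_abs <= f_hi)
  replace_values(signals, out)
}

#' FFT low-pass filter (spectral zeroing)
#'
#' Zeroes every FFT bin at or above `f_cut` (and the DC bin) and inverts;
#' used to isolate the sub-gamma collective oscillations before phase
#' extraction.
#'
#' @inheritParams bandpass_fft
#' @param f_cut cutoff in Hz, below Nyquist.
#' @return Same type as the input.
#' @export
lowpass_fft <- function(signals, f_cut, fs = NULL) {
  x <- signal_values(signals)
  fs <- signal_fs(signals, fs)
  if (f_cut <= 0 || f_cut > fs / 2)
    stop("`f_cut` must lie in (0, Nyquist]", call. = FALSE)
  out <- fft_mask_filter(x, fs, function(f_abs) f_abs > 0 & f_abs < f_cut)
  replace_values(signals, out)
}

# Apply a frequency-domain mask per node. x: N x T. keep(f_abs) -> logical.
fft_mask_filter <- function(x, fs, keep) {
  T_len <- ncol(x)
  f <- (seq_len(T_len) - 1) * fs / T_len
  f_abs <- pmin(f, fs - f)   # two-sided frequency magnitude
  mask <- keep(f_abs)
  X <- stats::mvfft(t(x))    # columns are nodes
  X[!mask, ] <- 0
  t(Re(stats::mvfft(X, inverse = TRUE))) / T_len
}

#' Amplitude envelope via the Hilbert transform
#'
#' Magnitude of the analytic signal of each node: the instantaneous amplitude
#' of band-limited activity.
#'
#' @inheritParams bandpass_fft
#' @return N x T non-negative matrix of envelopes.
#' @export
hilbert_envelope <- function(signals) {
  x <- signal_values(signals)
  if (!all(is.finite(x))) stop("non-finite values in input", call. = FALSE)
  Mod(analytic_signal(x))
}

#' Instantaneous phase of low-pass-filtered signals
#'
#' Low-pass filters below `f_cut` (spectral zeroing), then takes the angle of
#' the analytic signal per node; phases lie in (-pi, pi].
#'
#' @inheritParams bandpass_fft
#' @param f_cut low-pass cutoff in Hz (default 30, isolating sub-gamma
#'   activity); `NULL` skips filtering.
#' @return N x T matrix of phases in radians.
#' @export
instantaneous_phase <- function(signals, f_cut = 30, fs = NULL) {
  fs <- signal_fs(signals, fs)
  x <- signal_values(signals)
  if (!all(is.finite(x))) stop("non-finite values in input", call. = FALSE)
  if (!is.null(f_cut)) x <- signal_values(lowpass_fft(x, f_cut, fs = fs))
  Arg(analytic_signal(x))
}

# Analytic signal per row of an N x T real matrix (FFT method).
analytic_signal <- function(x) {
  one_row <- is.null(dim(x))
  if (one_row) x <- matrix(x, nrow = 1)
  T_len <- ncol(x)
  h <- numeric(T_len)
  if (T_len %% 2 == 0) {
    h[c(1, T_len / 2 + 1)] <- 1
    h[2:(T_len / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((T_len + 1) / 2)] <- 2
  }
  X <- stats::mvfft(t(x)) * h
  out <- t(stats::mvfft(X, inverse = TRUE)) / T_len
  if (one_row) out[1, ] else out
}

signal_fs <- function(signals, fs) {
  if (inherits(signals, "signal_set")) return(signals$sampling_rate)
  if (is.null(fs)) stop("`fs` is required for matrix input", call. = FALSE)
  fs
}

signal_values <- function(signals) {
  if (inherits(signals, "signal_set")) signals$values
  else if (is.matrix(signals)) signals
  else stop("expected a `signal_set` or a numeric matrix", call. = FALSE)
}

replace_values <- function(signals, values) {
  if (inherits(signals, "signal_set")) {
    signals$values <- values
    signals
  } else values
}

`%||%` <- function(a, b) if (is.null(a)) b else a
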