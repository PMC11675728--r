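#' Canonical sub-gamma frequency bands
#'
#' The four bands in which metastable oscillatory modes are sought: delta
#' (0.5-4 Hz), theta (4-8 Hz), alpha (8-13 Hz) and beta (13-30 Hz).
#'
#' @return A tibble with columns `band`, `f_lo`, `f_hi` (Hz).
#' @export
#' @examples
#' band_specs()
band_specs <- function() {
  tibble::tibble(
    band = factor(c("delta", "theta", "alpha", "beta"),
                  levels = c("delta", "theta", "alpha", "beta")),
    f_lo = c(0.5, 4, 8, 13),
    f_hi = c(4, 8, 13, 30)
  )
}

validate_bands <- function(bands, fs) {
  stopifnot(is.data.frame(bands),
            all(c("band", "f_lo", "f_hi") %in% names(bands)))
  if (any(bands$f_lo <= 0) || any(bands$f_hi <= bands$f_lo))
    stop("each band needs 0 < f_lo < f_hi", call. = FALSE)
  if (any(bands$f_hi > fs / 2))
    stop("band edge above the Nyquist frequency (", fs / 2, " Hz)",
         call. = FALSE)
  bands
}

#' Band-limited amplitude envelopes
#'
#' Band-pass filters the signals into each requested band ([bandpass_fft()])
#' and extracts the per-node Hilbert amplitude envelope.
#'
#' @param signals a `signal_set`.
#' @param bands a band table as returned by [band_specs()].
#' @return Named list (one element per band) of N x T envelope matrices.
#' @export
band_envelopes <- function(signals, bands = band_specs()) {
  validate_bands(bands, signals$sampling_rate)
  envs <- lapply(seq_len(nrow(bands)), function(i)
    hilbert_envelope(bandpass_fft(signals, bands$f_lo[i], bands$f_hi[i])))
  names(envs) <- as.character(bands$band)
  envs
}

#' Baseline amplitude statistics from a no-delay twin run
#'
#' The detection threshold for each node and band is calibrated on a twin
#' simulation with the mean delay forced to zero and every other parameter
#' (including the seed, by default) unchanged: without delays the network
#' produces no sub-gamma collective oscillations, so the band-limited
#' envelopes measure the noise floor. The threshold is
#' `mean + n_std * sd` of that baseline envelope (`threshold_formula =
#' "mean_plus_sd"`), or `n_std * sd` alone (`"sd_only"`).
#'
#' @param params an [sl_params] object (the main run's parameters).
#' @param conn a [connectome] object.
#' @param bands band table, see [band_specs()].
#' @param n_std number of baseline standard deviations defining the
#'   threshold (default 5).
#' @param threshold_formula `"mean_plus_sd"` (default) or `"sd_only"`.
#' @param baseline_seed seed for the no-delay run; defaults to the main
#'   run's seed (paired noise).
#' @param normalize passed to [simulate_network()].
#'
#' @return A tibble of class `baseline_stats` with columns `node`, `band`,
#'   `mean_amp`, `sd_amp`, `threshold`.
#' @export
compute_baseline <- function(params, conn, bands = band_specs(), n_std = 5,
                             threshold_formula = c("mean_plus_sd", "sd_only"),
                             baseline_seed = NULL,
                             normalize = c("mean_all", "mean_nonzero", "none")) {
  stopifnot(inherits(params, "sl_params"))
  threshold_formula <- match.arg(threshold_formula)
  if (n_std <= 0) stop("`n_std` must be positive", call. = FALSE)
  p0 <- params
  p0$mean_delay <- 0
  if (!is.null(baseline_seed)) p0$seed <- as.integer(baseline_seed)
  sig0 <- simulate_network(p0, conn, normalize = normalize)
  envs <- band_envelopes(sig0, bands)

  out <- purrr::map_dfr(names(envs), function(b) {
    e <- envs[[b]]
    m <- rowMeans(e)
    s <- apply(e, 1, sd)
    if (any(s <= 0)) {
      bad <- which(s <= 0)[1]
      stop("degenerate (zero-variance) baseline envelope for node ", bad,
           ", band ", b, call. = FALSE)
    }
    tibble::tibble(node = seq_len(nrow(e)), band = b, mean_amp = m, sd_amp = s)
  })
  out$band <- factor(out$band, levels = as.character(bands$band))
  out$threshold <- switch(threshold_formula,
                          mean_plus_sd = out$mean_amp + n_std * out$sd_amp,
                          sd_only = n_std * out$sd_amp)
  structure(out,
            class = c("baseline_stats", class(tibble::tibble()))) |>
    set_attrs(n_std = n_std, threshold_formula = threshold_formula,
              baseline_seed = p0$seed)
}

set_attrs <- function(x, ...) {
  dots <- list(...)
  for (nm in names(dots)) attr(x, nm) <- dots[[nm]]
  x
}

#' Per-band coalition size series
#'
#' A node belongs to a coalition at a sample if its band-limited envelope
#' exceeds its baseline threshold for that band. The coalition size is the
#' raw count of such nodes; the total series sums counts across bands. No
#' minimum-size masking is applied here — the minimum coalition size only
#' classifies discrete MOM events in [detect_mom_events()].
#'
#' @param envelopes named list of per-band N x T envelope matrices, as from
#'   [band_envelopes()].
#' @param baseline a `baseline_stats` tibble from [compute_baseline()].
#' @param fs sampling rate in Hz (for the time axis); default 500.
#' @param t0 time of the first sample in seconds.
#'
#' @return A tibble of class `coalition_series` with columns `sample`,
#'   `time`, one integer column per band, and `total`. The per-band
#'   supra-threshold logical matrices are kept in the `"above"` attribute.
#' @export
coalition_counts <- function(envelopes, baseline, fs = 500, t0 = 0) {
  stopifnot(inherits(baseline, "baseline_stats"))
  bands <- levels(baseline$band)
  if (!setequal(names(envelopes), bands))
    stop("envelope bands (", paste(names(envelopes), collapse = ", "),
         ") do not match baseline bands (", paste(bands, collapse = ", "), ")",
         call. = FALSE)
  N <- nrow(envelopes[[1]])
  T_len <- ncol(envelopes[[1]])

  above <- lapply(bands, function(b) {
    e <- envelopes[[b]]
    if (nrow(e) != N || ncol(e) != T_len)
      stop("envelope shape mismatch in band ", b, call. = FALSE)
    thr <- baseline$threshold[baseline$band == b]
    if (length(thr) != N)
      stop("baseline has ", length(thr), " nodes for band ", b,
           " but envelopes have ", N, call. = FALSE)
    e > thr   # thr recycles down columns: one threshold per node
  })
  names(above) <- bands

  counts <- lapply(above, function(a) as.integer(colSums(a)))
  out <- tibble::tibble(sample = seq_len(T_len),
                        time = t0 + (seq_len(T_len) - 1) / fs)
  for (b in bands) out[[b]] <- counts[[b]]
  out$total <- as.integer(Reduce(`+`, counts))
  structure(out, class = c("coalition_series", class(tibble::tibble()))) |>
    set_attrs(above = above, fs = fs, n_nodes = N, bands = bands)
}

#' Classify metastable oscillatory mode (MOM) events
#'
#' Scans each band's coalition-size series for maximal contiguous runs in
#' which at least `min_coalition` nodes simultaneously exceed their amplitude
#' threshold; each run becomes one MOM event with its start, duration, peak
#' coalition size and the node set at the peak (earliest peak sample on
#' ties).
#'
#' @param series a `coalition_series` from [coalition_counts()].
#' @param min_coalition minimum simultaneous coalition size (default 5).
#' @return A tibble with columns `band`, `start`, `duration` (seconds),
#'   `peak_size`, `peak_time`, and `nodes` (list-column of node indices at
#'   the peak).
#' @export
detect_mom_events <- function(series, min_coalition = 5) {
  stopifnot(inherits(series, "coalition_series"))
  if (min_coalition < 1) stop("`min_coalition` must be >= 1", call. = FALSE)
  fs <- attr(series, "fs")
  above <- attr(series, "above")
  bands <- attr(series, "bands")

  purrr::map_dfr(bands, function(b) {
    counts <- series[[b]]
    in_event <- counts >= min_coalition
    if (!any(in_event)) return(NULL)
    r <- rle(in_event)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    purrr::map_dfr(keep, function(k) {
      i0 <- starts[k]; i1 <- ends[k]
      seg <- counts[i0:i1]
      peak_i <- i0 + which.max(seg) - 1   # which.max: earliest on ties
      tibble::tibble(
        band = b,
        start = series$time[i0],
        duration = (i1 - i0 + 1) / fs,
        peak_size = counts[peak_i],
        peak_time = series$time[peak_i],
        nodes = list(which(above[[b]][, peak_i]))
      )
    })
  })
}

#' @describeIn coalition_counts Stacked per-band coalition-size traces.
#' @param object a `coalition_series`.
#' @param ... unused.
#' @export
autoplot.coalition_series <- function(object, ...) {
  long <- tidyr::pivot_longer(as_plain_tibble(object),
                              cols = -c("sample", "time"),
                              names_to = "band", values_to = "size")
  long$band <- factor(long$band, levels = c(attr(object, "bands"), "total"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$size)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$band)) +
    ggplot2::labs(x = "time (s)", y = "coalition size (nodes)")
}

as_plain_tibble <- function(x) {
  out <- tibble::as_tibble(unclass(x)[seq_along(x)])
  names(out) <- names(x)
  out
}
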