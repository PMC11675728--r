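#' Average a sample-rate series over entropy windows
#'
#' Averages a per-sample series (e.g. the total coalition size) over exactly
#' the sliding windows used for the entropy computation, so the two series
#' live on a common time grid.
#'
#' @param series numeric vector on the signal sampling grid.
#' @param windows window metadata: the `"windows"` attribute of an
#'   [entropy_timeseries()] result, or an `entropy_series` itself.
#' @return Numeric vector with one mean per window.
#' @export
window_average <- function(series, windows) {
  if (inherits(windows, "entropy_series")) windows <- attr(windows, "windows")
  stopifnot(is.list(windows), !is.null(windows$start_index))
  need <- max(windows$start_index) + windows$n_samples - 1L
  if (length(series) < need)
    stop("series has ", length(series), " samples but the windows need ",
         need, " (grid mismatch)", call. = FALSE)
  vapply(windows$start_index,
         function(i0) mean(series[i0:(i0 + windows$n_samples - 1L)]),
         numeric(1))
}

#' Pearson correlation with t-distribution p-value
#'
#' Product-moment correlation between two equal-length series and the
#' two-sided p-value from the t distribution with `length(x) - 2` degrees of
#' freedom. Zero-variance input yields an `NA` correlation with a reason code rather
#' than a spurious 0. Note the p-value treats windows as independent; with
#' 50% window overlap it is anti-conservative (see
#' [permutation_pvalue()] for an overlap-robust alternative).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return A tibble with columns `r`, `p_value`, `n`, `reason` (`NA` unless
#'   the correlation is undefined).
#' @export
#' @examples
#' pearson_correlation(1:3, c(2, 4, 6))
pearson_correlation <- function(x, y) {
  if (length(x) != length(y))
    stop("series lengths differ: ", length(x), " vs ", length(y),
         call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("non-finite values in input", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = length(x),
                          reason = "zero_variance"))
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
                 reason = NA_character_)
}

#' Circular-shift permutation p-value for correlated windows
#'
#' Null distribution of |r| obtained by circularly shifting one series by a
#' random offset (preserving its autocorrelation) `n_perm` times; the
#' p-value is the fraction of permuted |r| at least as large as observed
#' (add-one correction).
#'
#' @param x,y numeric vectors of equal length.
#' @param n_perm number of circular shifts (default 1000).
#' @param seed integer seed.
#' @return A one-row tibble with `r`, `p_value`, `n`, `method`.
#' @export
permutation_pvalue <- function(x, y, n_perm = 1000, seed = 1) {
  obs <- pearson_correlation(x, y)
  if (is.na(obs$r)) return(obs)
  set.seed(as.integer(seed))
  W <- length(x)
  shifts <- sample.int(W - 1, n_perm, replace = TRUE)
  null_r <- vapply(shifts, function(s) {
    ys <- c(y[(s + 1):W], y[1:s])
    suppressWarnings(stats::cor(x, ys))
  }, numeric(1))
  p <- (1 + sum(abs(null_r) >= abs(obs$r), na.rm = TRUE)) / (1 + n_perm)
  tibble::tibble(r = obs$r, p_value = p, n = W, method = "circular_shift")
}

#' Bonferroni adjustment with an explicit family size
#'
#' Multiplies each p-value by the family size `m` and caps at 1. Unlike
#' [stats::p.adjust()], the family may be larger than the vector supplied
#' (e.g. one cell of a 9-cell grid); for `m == length(p)` the two agree.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param m family size, at least `length(p)`.
#' @return Adjusted p-values, same length as `p`.
#' @export
#' @examples
#' bonferroni_adjust(0.004, m = 9)
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < length(p)) stop("`m` must be >= length(p)", call. = FALSE)
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) stop("p-values outside [0, 1]", call. = FALSE)
  pmin(1, m * p)
}

#' Run the full coalition-entropy pipeline for one parameter setting
#'
#' Orchestrates one complete analysis: simulate the delay-coupled network,
#' calibrate the no-delay baseline, extract band-limited coalition-size
#' series and MOM events, compute the windowed eigenvalue-spectrum entropy,
#' average the total coalition size over the same windows, and correlate the
#' two series (Pearson).
#'
#' @param params an [sl_params] object.
#' @param conn a [connectome] object.
#' @param bands band table, see [band_specs()].
#' @param n_std baseline threshold multiplier (default 5).
#' @param min_coalition minimum coalition size for MOM events (default 5).
#' @param threshold_formula,baseline_seed passed to [compute_baseline()].
#' @param window_length,overlap,phase_method,lowpass_hz entropy settings,
#'   see [entropy_timeseries()].
#' @param normalize weight normalization, see [scaled_coupling()].
#' @param keep_signals retain the simulated `signal_set` in the result
#'   (memory-heavy for long runs).
#'
#' @return An object of class `mom_entropy_fit`: list with `windows` (tibble:
#'   `window`, `window_start`, `coalition`, `entropy`), `coalition`
#'   (`coalition_series`), `entropy` (`entropy_series`), `events` (tibble),
#'   `correlation` (tibble from [pearson_correlation()]), `params`, and the
#'   baseline.
#' @export
run_pipeline <- function(params, conn, bands = band_specs(), n_std = 5,
                         min_coalition = 5,
                         threshold_formula = c("mean_plus_sd", "sd_only"),
                         baseline_seed = NULL, window_length = 0.2,
                         overlap = 0.5,
                         phase_method = c("complex_phase", "cosine_phase"),
                         lowpass_hz = 30,
                         normalize = c("mean_all", "mean_nonzero", "none"),
                         keep_signals = FALSE) {
  stopifnot(inherits(params, "sl_params"), inherits(conn, "connectome"))
  threshold_formula <- match.arg(threshold_formula)
  phase_method <- match.arg(phase_method)
  normalize <- match.arg(normalize)

  stage <- "simulate"
  res <- tryCatch({
    sig <- simulate_network(params, conn, normalize = normalize)
    stage <- "baseline"
    baseline <- compute_baseline(params, conn, bands, n_std,
                                 threshold_formula, baseline_seed, normalize)
    stage <- "mom_detection"
    envs <- band_envelopes(sig, bands)
    coal <- coalition_counts(envs, baseline, fs = sig$sampling_rate,
                             t0 = sig$t0)
    events <- detect_mom_events(coal, min_coalition)
    stage <- "entropy"
    ent <- entropy_timeseries(sig, window_length, overlap, phase_method,
                              f_cut = lowpass_hz)
    stage <- "correlation"
    coal_avg <- window_average(coal$total, ent)
    corr <- pearson_correlation(coal_avg, ent$entropy)
    windows <- tibble::tibble(window = ent$window,
                              window_start = ent$window_start,
                              coalition = coal_avg, entropy = ent$entropy)
    list(sig = sig, baseline = baseline, coal = coal, events = events,
         ent = ent, corr = corr, windows = windows)
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })

  structure(
    list(windows = res$windows, coalition = res$coal, entropy = res$ent,
         events = res$events, correlation = res$corr, baseline = res$baseline,
         params = params, min_coalition = min_coalition,
         signals = if (keep_signals) res$sig else NULL),
    class = "mom_entropy_fit"
  )
}

#' @export
print.mom_entropy_fit <- function(x, ...) {
  cat("<mom_entropy_fit> K=", x$params$K, ", <tau>=",
      x$params$mean_delay * 1000, " ms, ", nrow(x$windows), " windows\n",
      "  Pearson r = ", signif(x$correlation$r, 4), " (p = ",
      signif(x$correlation$p_value, 3), "), ", nrow(x$events),
      " MOM events\n", sep = "")
  invisible(x)
}

#' @describeIn run_pipeline One row per analysis window: window-averaged
#'   total coalition size and entropy.
#' @param x a `mom_entropy_fit`.
#' @param ... unused.
#' @export
tidy.mom_entropy_fit <- function(x, ...) x$windows

#' @describeIn run_pipeline One-row summary: `r`, `p_value`, `n_windows`,
#'   `mean_coalition`, `mean_entropy`, `n_events`.
#' @export
glance.mom_entropy_fit <- function(x, ...) {
  tibble::tibble(
    r = x$correlation$r, p_value = x$correlation$p_value,
    n_windows = nrow(x$windows),
    mean_coalition = mean(x$windows$coalition),
    mean_entropy = mean(x$windows$entropy),
    n_events = nrow(x$events)
  )
}

#' @describeIn run_pipeline Standardized coalition and entropy traces on one
#'   axis, with the correlation in the title.
#' @param object a `mom_entropy_fit`.
#' @export
autoplot.mom_entropy_fit <- function(object, ...) {
  w <- object$windows
  df <- tibble::tibble(
    time = rep(w$window_start, 2),
    series = rep(c("coalition size", "entropy"), each = nrow(w)),
    z = c(scale(w$coalition)[, 1], scale(w$entropy)[, 1])
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$z,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c("steelblue", "darkorange")) +
    ggplot2::labs(x = "time (s)", y = "z-score",
                  title = sprintf("r = %.3f (p = %.2g)",
                                  object$correlation$r,
                                  object$correlation$p_value))
}

#' Sweep the coupling-delay parameter grid
#'
#' Runs [run_pipeline()] for every combination of global coupling strength
#' and mean delay (default 3 x 3 grid: K in {0.1, 10, 50}, mean delay in
#' {0, 3, 10} ms), with per-cell seeds derived deterministically from a
#' master seed, and Bonferroni-corrects the per-cell p-values over the grid.
#' Cell failures are recorded (`error` column) without aborting the sweep.
#'
#' @param conn a [connectome] object.
#' @param K_values numeric vector of coupling strengths.
#' @param delay_values numeric vector of mean delays (seconds).
#' @param base_params an [sl_params] giving everything except `K`,
#'   `mean_delay` and `seed`.
#' @param master_seed integer master seed; cell seeds are derived from it by
#'   cell index.
#' @param ... further arguments passed to [run_pipeline()].
#'
#' @return A tibble of class `sweep_result` with one row per grid cell:
#'   `K`, `tau_ms`, `r`, `p_raw`, `p_adj`, `mean_coalition`, `mean_entropy`,
#'   `n_events`, `seed`, `reason`, `error`. Fitted objects are kept in the
#'   `"fits"` attribute.
#' @export
run_parameter_sweep <- function(conn, K_values = c(0.1, 10, 50),
                                delay_values = c(0, 0.003, 0.010),
                                base_params = sl_params(),
                                master_seed = 1, ...) {
  if (!length(K_values) || !length(delay_values))
    stop("empty parameter grid", call. = FALSE)
  grid <- tidyr::expand_grid(K = K_values, mean_delay = delay_values)
  m <- nrow(grid)
  seeds <- derive_seeds(master_seed, m)

  fits <- vector("list", m)
  rows <- purrr::map_dfr(seq_len(m), function(i) {
    p <- base_params
    p$K <- grid$K[i]
    p$mean_delay <- grid$mean_delay[i]
    p$seed <- seeds[i]
    fit <- tryCatch(run_pipeline(p, conn, ...), error = identity)
    if (inherits(fit, "error"))
      return(tibble::tibble(K = p$K, tau_ms = p$mean_delay * 1000,
                            r = NA_real_, p_raw = NA_real_,
                            mean_coalition = NA_real_, mean_entropy = NA_real_,
                            n_events = NA_integer_, seed = seeds[i],
                            reason = NA_character_,
                            error = conditionMessage(fit)))
    fits[[i]] <<- fit
    g <- glance(fit)
    tibble::tibble(K = p$K, tau_ms = p$mean_delay * 1000, r = g$r,
                   p_raw = g$p_value, mean_coalition = g$mean_coalition,
                   mean_entropy = g$mean_entropy, n_events = g$n_events,
                   seed = seeds[i], reason = fit$correlation$reason,
                   error = NA_character_)
  })
  rows$p_adj <- bonferroni_adjust(rows$p_raw, m = m)
  rows <- rows[c("K", "tau_ms", "r", "p_raw", "p_adj", "mean_coalition",
                 "mean_entropy", "n_events", "seed", "reason", "error")]
  structure(rows, class = c("sweep_result", class(tibble::tibble()))) |>
    set_attrs(fits = fits, m = m, master_seed = master_seed)
}

# Deterministic per-cell seeds below 2^31, spread by a large prime.
derive_seeds <- function(master_seed, n) {
  as.integer((as.numeric(master_seed) + 7919 * seq_len(n)) %% 2147483647L)
}

#' @describeIn run_parameter_sweep Tile plot of the grid with r in each cell;
#'   significant (Bonferroni) cells starred.
#' @param object a `sweep_result`.
#' @param ... unused.
#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- as_plain_tibble(object)
  df$label <- ifelse(is.na(df$r), "NA",
                     sprintf("%.2f%s", df$r,
                             ifelse(!is.na(df$p_adj) & df$p_adj < 0.05,
                                    "*", "")))
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$tau_ms), factor(.data$K),
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label)) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), na.value = "grey85") +
    ggplot2::labs(x = "mean delay (ms)", y = "coupling strength K",
                  fill = "r",
                  title = "Coalition-entropy correlation across regimes")
}
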