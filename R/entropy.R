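#' Sliding-window phase covariance matrices
#'
#' Slices the phase record into windows of `window_length` seconds with the
#' given overlap (windows start at multiples of the step and must lie wholly
#' inside the record; a partial trailing window is dropped) and computes one
#' N x N covariance matrix per window.
#'
#' Phase angles are circular, so the default method forms the Hermitian
#' covariance of the unit-modulus phase factors \eqn{e^{i\theta_n(t)}}
#' (within-window means subtracted). This is positive semi-definite with real
#' eigenvalues, insensitive to phase wrapping, and rotation-invariant. The
#' `cosine_phase` alternative takes the real covariance of
#' \eqn{\cos\theta_n(t)}.
#'
#' @param phases N x T matrix of phases in radians, from
#'   [instantaneous_phase()].
#' @param fs sampling rate of the phase record, Hz.
#' @param window_length window length in seconds (default 0.2).
#' @param overlap fraction of overlap between consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @param method `"complex_phase"` (default) or `"cosine_phase"`.
#' @return A list with `cov` (list of W covariance matrices), `window_starts`
#'   (seconds, relative to the first sample), `start_index`, `n_samples`,
#'   `step_samples`, `fs`.
#' @export
windowed_phase_covariance <- function(phases, fs, window_length = 0.2,
                                      overlap = 0.5,
                                      method = c("complex_phase",
                                                 "cosine_phase")) {
  method <- match.arg(method)
  stopifnot(is.matrix(phases))
  if (overlap < 0 || overlap >= 1)
    stop("`overlap` must lie in [0, 1)", call. = FALSE)
  T_len <- ncol(phases)
  w_s <- as.integer(round(window_length * fs))
  if (w_s < 2) stop("window shorter than 2 samples", call. = FALSE)
  if (w_s > T_len)
    stop("window (", w_s, " samples) longer than the record (", T_len, ")",
         call. = FALSE)
  step <- max(1L, as.integer(round(w_s * (1 - overlap))))
  starts <- seq.int(1L, T_len - w_s + 1L, by = step)

  covs <- lapply(starts, function(i0) {
    idx <- i0:(i0 + w_s - 1L)
    if (method == "complex_phase") {
      X <- exp(1i * phases[, idx, drop = FALSE])
      Xc <- X - rowMeans(X)
      (Xc %*% Conj(t(Xc))) / (w_s - 1)
    } else {
      X <- cos(phases[, idx, drop = FALSE])
      Xc <- X - rowMeans(X)
      (Xc %*% t(Xc)) / (w_s - 1)
    }
  })
  list(cov = covs, window_starts = (starts - 1) / fs, start_index = starts,
       n_samples = w_s, step_samples = step, fs = fs)
}

#' Normalized eigenvalue distribution of a covariance matrix
#'
#' Eigendecomposes a Hermitian (or real symmetric) positive semi-definite
#' matrix, clips numerically negative eigenvalues to zero, sorts them in
#' descending order and normalizes by their sum, yielding a probability
#' distribution over covariance eigenmodes — the fraction of the system's
#' "energy" captured by each mode.
#'
#' @param cov N x N Hermitian PSD matrix.
#' @return Numeric vector of length N, non-negative, summing to 1, sorted
#'   descending.
#' @export
#' @examples
#' eigenvalue_distribution(diag(c(3, 1)))
eigenvalue_distribution <- function(cov) {
  stopifnot(is.matrix(cov), nrow(cov) == ncol(cov))
  herm_err <- max(Mod(cov - Conj(t(cov))))
  if (herm_err > 1e-8 * max(1, max(Mod(cov))))
    stop("matrix is not Hermitian within tolerance", call. = FALSE)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(Re(ev), 0)
  s <- sum(ev)
  if (s <= 0) stop("zero-trace covariance matrix: no variance to distribute",
                   call. = FALSE)
  sort(ev / s, decreasing = TRUE)
}

#' Shannon entropy of a probability vector (nats)
#'
#' \eqn{H = -\sum_n p_n \ln p_n} with the convention \eqn{0 \ln 0 = 0}.
#' Applied to a normalized eigenvalue spectrum it ranges from 0 (all variance
#' in one eigenmode: full order) to \eqn{\ln N} (flat spectrum: full
#' disorder).
#'
#' @param p non-negative numeric vector summing to 1 (tolerance 1e-6).
#' @return Entropy in nats, in `[0, log(length(p))]`.
#' @export
#' @examples
#' shannon_entropy(rep(1 / 90, 90))  # log(90)
shannon_entropy <- function(p) {
  if (any(p < 0)) stop("negative probabilities", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-6)
    stop("probabilities sum to ", format(sum(p)), ", not 1", call. = FALSE)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Time-resolved eigenvalue-spectrum entropy
#'
#' The system-level order parameter: instantaneous phases of the
#' low-pass-filtered signals, sliding-window phase covariance, normalized
#' eigenvalue distribution per window, Shannon entropy per window. Low H
#' means the dynamics are dominated by few collective modes (high order);
#' H near log(N) means the nodes evolve independently.
#'
#' @param signals a `signal_set` or an N x T matrix (then `fs` required).
#' @inheritParams windowed_phase_covariance
#' @param f_cut low-pass cutoff in Hz before phase extraction (default 30);
#'   `NULL` to skip filtering.
#' @param fs sampling rate, only for matrix input.
#' @return A tibble of class `entropy_series` with columns `window`,
#'   `window_start` (seconds, absolute), `entropy` (nats). The W x N matrix
#'   of eigenvalue distributions is in attribute `"eigen_dist"` and the
#'   window metadata in `"windows"`.
#' @export
entropy_timeseries <- function(signals, window_length = 0.2, overlap = 0.5,
                               method = c("complex_phase", "cosine_phase"),
                               f_cut = 30, fs = NULL) {
  method <- match.arg(method)
  fs <- signal_fs(signals, fs)
  t0 <- if (inherits(signals, "signal_set")) signals$t0 else 0
  phases <- instantaneous_phase(signals, f_cut = f_cut, fs = fs)
  wc <- windowed_phase_covariance(phases, fs, window_length, overlap, method)
  eig <- t(vapply(wc$cov, eigenvalue_distribution,
                  numeric(nrow(phases))))
  H <- apply(eig, 1, shannon_entropy)
  windows <- wc[c("window_starts", "start_index", "n_samples",
                  "step_samples", "fs")]
  out <- tibble::tibble(window = seq_along(H),
                        window_start = t0 + wc$window_starts,
                        entropy = H)
  structure(out, class = c("entropy_series", class(tibble::tibble()))) |>
    set_attrs(eigen_dist = eig, windows = windows, method = method,
              f_cut = f_cut)
}

#' @describeIn entropy_timeseries Entropy trace over time.
#' @param object an `entropy_series`.
#' @param ... unused.
#' @export
autoplot.entropy_series <- function(object, ...) {
  n_modes <- ncol(attr(object, "eigen_dist"))
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$window_start, .data$entropy)) +
    ggplot2::geom_line(colour = "darkorange") +
    ggplot2::geom_hline(yintercept = log(n_modes), linetype = "dashed") +
    ggplot2::labs(x = "time (s)", y = "Shannon entropy H(t) (nats)",
                  title = "Eigenvalue-spectrum entropy",
                  subtitle = paste0("dashed: log(N) = ",
                                    round(log(n_modes), 3)))
}
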