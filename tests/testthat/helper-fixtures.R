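# Small deterministic fixtures shared across test files.

# fully connected toy connectome with constant distances
toy_connectome <- function(n = 3, dist = 50) {
  w <- matrix(1, n, n)
  diag(w) <- 0
  d <- matrix(dist, n, n)
  diag(d) <- 0
  connectome(w, d)
}

# baseline_stats with hand-set thresholds: thr_by_band is a named list of
# per-node threshold vectors
fake_baseline <- function(thr_by_band) {
  bands <- names(thr_by_band)
  out <- purrr::map_dfr(bands, function(b)
    tibble::tibble(node = seq_along(thr_by_band[[b]]), band = b,
                   mean_amp = 0, sd_amp = 1, threshold = thr_by_band[[b]]))
  out$band <- factor(out$band, levels = bands)
  structure(out, class = c("baseline_stats", class(tibble::tibble())),
            n_std = 5, threshold_formula = "mean_plus_sd")
}

# envelope matrix realizing a prescribed per-sample count against threshold 1
count_envelope <- function(counts, n_nodes) {
  env <- matrix(0, n_nodes, length(counts))
  for (t in seq_along(counts))
    if (counts[t] > 0) env[seq_len(counts[t]), t] <- 2
  env
}

# window metadata in the shape entropy_timeseries attaches
fake_windows <- function(start_index, n_samples, step_samples = n_samples,
                         fs = 500) {
  list(window_starts = (start_index - 1) / fs, start_index = start_index,
       n_samples = n_samples, step_samples = step_samples, fs = fs)
}

# characteristic-polynomial eigenvalues via principal minors (brute force,
# independent of eigen()) for small symmetric matrices
charpoly_eigenvalues <- function(A) {
  N <- nrow(A)
  ek <- vapply(seq_len(N), function(k)
    sum(utils::combn(N, k, function(idx) det(A[idx, idx, drop = FALSE]))),
    numeric(1))
  # det(xI - A) = x^N - e1 x^(N-1) + e2 x^(N-2) - ...; polyroot wants
  # coefficients in increasing order of power
  coefs <- c(rev((-1)^seq_len(N) * ek), 1)
  sort(Re(polyroot(coefs)), decreasing = TRUE)
}
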