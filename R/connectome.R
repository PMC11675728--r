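#' Connectome objects
#'
#' A connectome couples the oscillator network: `weights` holds non-negative
#' connection strengths (symmetric, zero diagonal, arbitrary units) and
#' `distances` the fiber lengths between connected region pairs, from which
#' conduction delays are derived. Constructed by [read_connectome()] or
#' [synthetic_connectome()].
#'
#' @param weights N x N non-negative symmetric numeric matrix, zero diagonal.
#' @param distances N x N non-negative symmetric numeric matrix; every pair
#'   with a positive weight must have a positive distance.
#' @param labels character vector of N region identifiers; defaults to
#'   `"R001"`, `"R002"`, ...
#' @param provenance optional list recording how the matrices were obtained
#'   (file paths or generator parameters and seed).
#'
#' @return An object of class `connectome`: a list with elements `n_nodes`,
#'   `weights`, `distances`, `labels`, `provenance`.
#' @export
#' @examples
#' w <- matrix(c(0, 1, 1, 0), 2, 2)
#' d <- matrix(c(0, 40, 40, 0), 2, 2)
#' connectome(w, d)
connectome <- function(weights, distances, labels = NULL, provenance = list()) {
  if (!is.matrix(weights) || !is.numeric(weights))
    stop("`weights` must be a numeric matrix", call. = FALSE)
  if (nrow(weights) != ncol(weights))
    stop("`weights` must be square, got ", nrow(weights), " x ", ncol(weights),
         call. = FALSE)
  if (!is.matrix(distances) || !all(dim(distances) == dim(weights)))
    stop("`distances` must be a matrix with the same dimensions as `weights` (",
         nrow(weights), " x ", ncol(weights), ")", call. = FALSE)
  n <- nrow(weights)
  if (any(weights < 0)) stop("`weights` contains negative entries", call. = FALSE)
  if (any(distances < 0)) stop("`distances` contains negative entries", call. = FALSE)
  if (!isTRUE(all.equal(weights, t(weights), tolerance = 1e-8)))
    stop("`weights` is not symmetric; pass symmetrize = TRUE to read_connectome() ",
         "to average with the transpose", call. = FALSE)
  if (!isTRUE(all.equal(distances, t(distances), tolerance = 1e-8)))
    stop("`distances` is not symmetric", call. = FALSE)
  if (any(diag(weights) != 0))
    stop("`weights` diagonal must be zero (no self-coupling)", call. = FALSE)
  bad <- weights > 0 & distances <= 0
  diag(bad) <- FALSE
  if (any(bad))
    stop("connected pairs with zero distance found (e.g. [",
         paste(which(bad, arr.ind = TRUE)[1, ], collapse = ","),
         "]); every positive weight needs a positive distance", call. = FALSE)
  if (is.null(labels)) labels <- sprintf("R%03d", seq_len(n))
  if (length(labels) != n)
    stop("`labels` must have length ", n, call. = FALSE)
  diag(distances) <- 0
  structure(
    list(n_nodes = n, weights = unname(weights), distances = unname(distances),
         labels = as.character(labels), provenance = provenance),
    class = "connectome"
  )
}

#' @export
print.connectome <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] > 0)
  tot <- x$n_nodes * (x$n_nodes - 1) / 2
  cat("<connectome> ", x$n_nodes, " nodes, ", nz, "/", tot,
      " connected pairs (density ", round(nz / tot, 3), ")\n", sep = "")
  invisible(x)
}

#' Read a connectome from delimited matrix files
#'
#' Reads square weight and distance matrices stored as delimited text
#' (comma-separated by default, no header, one row per node) and validates
#' the connectome invariants.
#'
#' @param weights_path,distances_path paths to the two matrix files.
#' @param format currently only `"delimited"` is supported.
#' @param sep field separator, `","` by default.
#' @param symmetrize if `TRUE`, an asymmetric weight or distance matrix is
#'   replaced by the average with its transpose; if `FALSE` (default)
#'   asymmetric input is an error.
#' @param labels optional region labels.
#'
#' @return A [connectome] object.
#' @export
read_connectome <- function(weights_path, distances_path,
                            format = c("delimited", "mat", "hdf5"),
                            sep = ",", symmetrize = FALSE, labels = NULL) {
  format <- match.arg(format)
  if (format != "delimited")
    stop("unsupported format \"", format,
         "\": only delimited text matrices are supported", call. = FALSE)
  for (p in c(weights_path, distances_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  w <- as.matrix(read.table(weights_path, sep = sep, header = FALSE))
  d <- as.matrix(read.table(distances_path, sep = sep, header = FALSE))
  dimnames(w) <- dimnames(d) <- NULL
  if (nrow(w) != ncol(w))
    stop("weight matrix is not square: ", nrow(w), " x ", ncol(w), call. = FALSE)
  if (!all(dim(d) == dim(w)))
    stop("dimension mismatch: weights are ", nrow(w), " x ", ncol(w),
         ", distances are ", nrow(d), " x ", ncol(d), call. = FALSE)
  if (symmetrize) {
    w <- (w + t(w)) / 2
    d <- (d + t(d)) / 2
  }
  connectome(w, d, labels = labels,
             provenance = list(source = "delimited",
                               weights_path = weights_path,
                               distances_path = distances_path,
                               symmetrized = symmetrize))
}

#' Write a connectome to a directory
#'
#' Writes `weights.csv`, `distances.csv` (no headers, comma-separated) and a
#' `connectome.json` sidecar with labels and provenance, so that
#' [read_connectome()] round-trips the matrices exactly.
#'
#' @param conn a [connectome] object.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_connectome <- function(conn, dir) {
  stopifnot(inherits(conn, "connectome"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  # 17 significant digits so doubles survive the text round-trip bit-exactly
  wt <- function(m, f) write.table(formatC(m, digits = 17, format = "g"),
                                   file.path(dir, f), sep = ",",
                                   quote = FALSE, row.names = FALSE,
                                   col.names = FALSE)
  wt(conn$weights, "weights.csv")
  wt(conn$distances, "distances.csv")
  jsonlite::write_json(
    list(n_nodes = conn$n_nodes, labels = conn$labels,
         provenance = conn$provenance),
    file.path(dir, "connectome.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Generate a synthetic connectome
#'
#' Emulates the statistical structure of a diffusion-MRI structural
#' connectome: symmetric sparse non-negative weights with a heavy-tailed
#' (log-normal) strength distribution, zero diagonal, and distances given by
#' Euclidean separation of random 3-D node positions, so the distribution of
#' conduction delays over connected pairs is right-skewed and unimodal.
#' Connection probability decays with distance (short-range connections more
#' likely), as in real cortical networks.
#'
#' @param n_nodes number of regions (>= 2); the reference parcellation has 90.
#' @param density fraction of off-diagonal pairs connected, in (0, 1].
#' @param weight_scale multiplicative scale of the log-normal weights
#'   (arbitrary units; removed again by [scaled_coupling()] normalization).
#' @param seed integer seed; identical seeds give bit-identical connectomes.
#' @param box_mm edge lengths (mm) of the box the 3-D node positions are drawn
#'   from; the default approximates brain dimensions.
#' @param sdlog log-scale standard deviation of the weight distribution
#'   (1 gives the heavy right tail typical of streamline counts).
#'
#' @return A [connectome] object with generator parameters in `$provenance`.
#' @export
#' @examples
#' conn <- synthetic_connectome(30, density = 0.3, seed = 1)
#' mean(conn$weights[upper.tri(conn$weights)] > 0)
synthetic_connectome <- function(n_nodes = 90, density = 0.35,
                                 weight_scale = 1, seed = 1,
                                 box_mm = c(140, 170, 120), sdlog = 1) {
  if (n_nodes < 2) stop("`n_nodes` must be at least 2", call. = FALSE)
  if (density <= 0 || density > 1)
    stop("`density` must lie in (0, 1]", call. = FALSE)
  if (weight_scale <= 0) stop("`weight_scale` must be positive", call. = FALSE)
  set.seed(as.integer(seed))

  pos <- cbind(runif(n_nodes, 0, box_mm[1]),
               runif(n_nodes, 0, box_mm[2]),
               runif(n_nodes, 0, box_mm[3]))
  d <- as.matrix(stats::dist(pos))
  dimnames(d) <- NULL

  ut <- which(upper.tri(d))
  n_pairs <- length(ut)
  m <- max(1L, round(density * n_pairs))
  # distance-dependent wiring: nearer pairs connect preferentially
  p_conn <- exp(-d[ut] / (mean(d[ut]) / 2))
  chosen <- if (m >= n_pairs) ut else sample(ut, m, prob = p_conn)

  w <- matrix(0, n_nodes, n_nodes)
  w[chosen] <- weight_scale * rlnorm(length(chosen), meanlog = 0, sdlog = sdlog)
  w <- w + t(w)

  connectome(w, d,
             provenance = list(source = "synthetic", n_nodes = n_nodes,
                               density = density, weight_scale = weight_scale,
                               seed = seed, box_mm = box_mm, sdlog = sdlog))
}

#' Scale the coupling matrix by the global coupling strength
#'
#' Normalizes the weights, then multiplies by the global coupling strength K.
#' The default `"mean_all"` divides by the mean over all off-diagonal entries
#' (zeros included), so the summed input weight per node averages N
#' regardless of connection density and the effective coupling mass is K*N.
#' Under this convention K = 10 with a 3 ms mean delay places the slowest
#' collective mode of the delay-coupled network in the alpha band, the regime
#' in which metastable oscillatory modes are observed. Zero entries stay zero
#' under every normalization.
#'
#' @param conn a [connectome] object.
#' @param K global coupling strength (>= 0).
#' @param normalize `"mean_all"` (default) divides by the mean off-diagonal
#'   weight; `"mean_nonzero"` divides by the mean of the nonzero weights;
#'   `"none"` multiplies the raw weights by K.
#' @return An N x N numeric matrix.
#' @export
scaled_coupling <- function(conn, K,
                            normalize = c("mean_all", "mean_nonzero",
                                          "none")) {
  stopifnot(inherits(conn, "connectome"))
  normalize <- match.arg(normalize)
  if (K < 0) stop("`K` must be non-negative", call. = FALSE)
  w <- conn$weights
  nz <- w > 0
  if (!any(nz)) stop("weight matrix is all zero; cannot scale", call. = FALSE)
  offd <- row(w) != col(w)
  w <- switch(normalize,
              mean_all = w / mean(w[offd]),
              mean_nonzero = w / mean(w[nz]),
              none = w)
  K * w
}

#' Conduction-delay matrix for a target mean delay
#'
#' Rescales the distance matrix so that the mean delay over *connected* pairs
#' (weight > 0) equals `mean_delay`, assuming homogeneous conduction speed.
#' Pairs with zero weight are excluded from the mean and get delay 0, as does
#' the diagonal.
#'
#' @param conn a [connectome] object.
#' @param mean_delay target mean conduction delay in seconds (>= 0); 0 gives
#'   an all-zero delay matrix (the no-delay condition).
#' @return An N x N matrix of delays in seconds.
#' @export
delay_matrix <- function(conn, mean_delay) {
  stopifnot(inherits(conn, "connectome"))
  if (mean_delay < 0) stop("`mean_delay` must be non-negative", call. = FALSE)
  conn_mask <- conn$weights > 0
  diag(conn_mask) <- FALSE
  if (!any(conn_mask)) stop("connectome has no connected pairs", call. = FALSE)
  tau <- matrix(0, conn$n_nodes, conn$n_nodes)
  if (mean_delay == 0) return(tau)
  dbar <- mean(conn$distances[conn_mask])
  tau[conn_mask] <- conn$distances[conn_mask] * (mean_delay / dbar)
  tau
}

#' @describeIn connectome Tidy a connectome into one row per connected pair
#'   (upper triangle): columns `from`, `to`, `weight`, `distance`.
#' @param x a `connectome` object.
#' @param ... unused.
#' @export
tidy.connectome <- function(x, ...) {
  idx <- which(upper.tri(x$weights) & x$weights > 0, arr.ind = TRUE)
  tibble::tibble(
    from = x$labels[idx[, 1]],
    to = x$labels[idx[, 2]],
    weight = x$weights[idx],
    distance = x$distances[idx]
  )
}

#' @describeIn connectome Heatmap of connection weights.
#' @param object a `connectome` object.
#' @export
autoplot.connectome <- function(object, ...) {
  df <- tidyr::expand_grid(row = seq_len(object$n_nodes),
                           col = seq_len(object$n_nodes))
  df$weight <- object$weights[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "region", y = "region", fill = "weight",
                  title = "Structural connectivity") +
    ggplot2::coord_fixed()
}
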