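#' Functional connectivity matrices
#'
#' Builds a symmetric channel x channel weight matrix from narrowband
#' (default 4-12 Hz) epochs, by Pearson correlation of amplitudes
#' (`pcc_matrix()`) or by the phase-locking value (`plv_matrix()`), and
#' derives sparse k-nearest-neighbour adjacency graphs from it
#' ([knn_graph()], [connectivity_graph()]).
#'
#' Signals are z-scored per trial and channel (population normalization),
#' so the average cross-moment `(1/N_s) sum_k r_i(k) r_j(k)` equals the
#' Pearson correlation; per-trial matrices are averaged across trials.
#' Zero-variance channels get zeroed rows/columns with a warning.
#'
#' @param epochs An `eeg_epochs` object (already narrowband-filtered), or a
#'   channels x samples matrix treated as one trial.
#' @return A symmetric channels x channels matrix; PCC entries in
#'   `[-1, 1]` with unit diagonal.
#' @export
pcc_matrix <- function(epochs) {
  avg_trial_matrix(epochs, pcc_trial)
}

pcc_trial <- function(x) {
  xc <- x - rowMeans(x)
  s <- sqrt(rowMeans(xc^2))                  # population z-score
  ok <- s > 0
  z <- xc / ifelse(ok, s, 1)
  z[!ok, ] <- 0
  w <- tcrossprod(z) / ncol(x)
  zero_bad_channels(w, ok)
}

#' @rdname pcc_matrix
#' @details For `plv_matrix()` the instantaneous phase comes from the
#'   analytic signal (Hilbert transform); the PLV between two channels is
#'   the modulus of the time-averaged unit phasor of their phase
#'   difference, in `[0, 1]` with unit diagonal. Constant channels have no
#'   defined phase and are zeroed with a warning.
#' @export
plv_matrix <- function(epochs) {
  avg_trial_matrix(epochs, plv_trial)
}

plv_trial <- function(x) {
  if (ncol(x) < 8L) stop_invalid("PLV needs at least 8 samples")
  ok <- apply(x, 1, sd) > 0
  ph <- matrix(0, nrow(x), ncol(x))
  ph[ok, ] <- t(Arg(analytic_signal(t(x[ok, , drop = FALSE]))))
  e <- exp(1i * ph)
  w <- Mod(tcrossprod(e, Conj(e))) / ncol(x)
  zero_bad_channels(w, ok)
}

# Per-trial connectivity matrices (trials x channels x channels array);
# their mean equals pcc_matrix()/plv_matrix() of the same epochs.
connectivity_trials <- function(epochs, method = c("pcc", "plv")) {
  method <- match.arg(method)
  fn <- if (method == "pcc") pcc_trial else plv_trial
  nc <- n_channels_of(epochs)
  out <- array(0, dim = c(n_trials(epochs), nc, nc))
  for (tr in seq_len(n_trials(epochs))) {
    out[tr, , ] <- fn(epochs$data[tr, , ])
  }
  out
}

avg_trial_matrix <- function(epochs, fn) {
  if (is.matrix(epochs)) return(name_w(fn(epochs), rownames(epochs)))
  stopifnot(inherits(epochs, "eeg_epochs"))
  if (n_samples(epochs) < 2L) stop_invalid("need at least 2 samples")
  acc <- 0
  for (tr in seq_len(n_trials(epochs))) {
    acc <- acc + fn(epochs$data[tr, , ])
  }
  name_w(acc / n_trials(epochs), epochs$channels)
}

name_w <- function(w, labels) {
  if (!is.null(labels)) dimnames(w) <- list(labels, labels)
  w
}

zero_bad_channels <- function(w, ok) {
  if (!all(ok)) {
    warn(sprintf("%d zero-variance channel(s); rows/columns set to 0",
                 sum(!ok)))
    w[!ok, ] <- 0
    w[, !ok] <- 0
  }
  diag(w)[ok] <- 1
  w
}

#' k-nearest-neighbour graph from a weight matrix
#'
#' For each node the k off-diagonal entries largest in absolute value are
#' kept (ties broken deterministically toward the lower channel index) and
#' the result is symmetrized by union: an edge survives if either endpoint
#' selected it, carrying the original weight. Diagonal is zero.
#'
#' @param W Symmetric weight matrix.
#' @param k Neighbours per node, `1 <= k < nrow(W)`.
#' @return Adjacency matrix of the same dimension.
#' @export
knn_graph <- function(W, k) {
  n <- nrow(W)
  check_scalar_num(k, "k", lower = 1, upper = n - 1)
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    w <- abs(W[i, ])
    w[i] <- -Inf
    ord <- order(w, seq_len(n), decreasing = c(TRUE, FALSE),
                 method = "radix")
    keep[i, ord[seq_len(k)]] <- TRUE
  }
  keep <- keep | t(keep)
  A <- ifelse(keep, W, 0)
  diag(A) <- 0
  A
}

degree_matrix <- function(A) diag(rowSums(A), nrow(A))

#' Assemble a connectivity graph
#'
#' Bundles the full weight matrix with its single-hop (`k1 = 1`) and
#' multi-hop (`k2 = 8`) k-NN adjacencies and their degree matrices, the
#' containers consumed by the graph-signal-processing stage.
#'
#' @param epochs Narrowband `eeg_epochs`, or a precomputed weight matrix.
#' @param method `"pcc"` or `"plv"` (ignored for matrix input).
#' @param band Frequency band recorded as metadata.
#' @param k1,k2 Neighbour counts of the two graphs (defaults 1 and 8).
#' @return A `conn_graph` list with `W`, `A1`, `A2`, `D1`, `D2`, `method`,
#'   `band`, and the subject metadata when available.
#' @export
connectivity_graph <- function(epochs, method = c("pcc", "plv"),
                               band = c(4, 12), k1 = 1, k2 = 8) {
  method <- match.arg(method)
  W <- if (is.matrix(epochs)) epochs else {
    if (method == "pcc") pcc_matrix(epochs) else plv_matrix(epochs)
  }
  A1 <- knn_graph(W, k1)
  A2 <- knn_graph(W, k2)
  structure(list(
    W = W, A1 = A1, A2 = A2,
    D1 = degree_matrix(abs(A1)), D2 = degree_matrix(abs(A2)),
    method = method, band = band,
    subject_id = if (inherits(epochs, "eeg_epochs")) epochs$subject_id else NA,
    group = if (inherits(epochs, "eeg_epochs")) epochs$group else NA
  ), class = "conn_graph")
}

#' @export
print.conn_graph <- function(x, ...) {
  cat(sprintf("<conn_graph> %s, %d nodes, band %g-%g Hz; |E(A1)| = %d, |E(A2)| = %d\n",
              x$method, nrow(x$W), x$band[1], x$band[2],
              sum(x$A1 != 0) / 2, sum(x$A2 != 0) / 2))
  invisible(x)
}
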