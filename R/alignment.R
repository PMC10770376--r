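#' Graph-matching objective
#'
#' Frobenius topology-consistency objective
#' \eqn{\|A_2 - S^T A_1 S\|_F^2}: zero iff `S` maps the single-hop graph
#' exactly onto the multi-hop graph.
#'
#' @param S Similarity/permutation matrix (n x n).
#' @param A1,A2 Adjacency matrices of the two graphs (n x n).
#' @return Scalar objective value.
#' @export
matching_objective <- function(S, A1, A2) {
  if (!all(dim(S) == dim(A1), dim(A1) == dim(A2))) {
    stop_invalid("S, A1, A2 must be conformable square matrices")
  }
  r <- A2 - t(S) %*% A1 %*% S
  sum(r^2)
}

#' Prior similarity from group-mean adjacencies
#'
#' Encodes how similar node i's connection profile in the group-0 mean
#' network is to node j's profile in the group-1 mean network:
#' `H_ij = sin(pi/2 * c+)` with `c+` the cosine similarity of the two rows
#' clipped to `[0, 1]`. `H` is normalized to sum 1 and vectorized
#' column-major into `h`, the restart distribution of the random walk.
#'
#' @param meanA_group0,meanA_group1 Group-mean adjacency matrices.
#' @return A list with matrix `H` and vector `h = vec(H)`.
#' @export
build_prior <- function(meanA_group0, meanA_group1) {
  if (!all(dim(meanA_group0) == dim(meanA_group1))) {
    stop_invalid("group-mean adjacencies must have the same shape")
  }
  n <- nrow(meanA_group0)
  n0 <- sqrt(rowSums(meanA_group0^2))
  n1 <- sqrt(rowSums(meanA_group1^2))
  if (all(n0 == 0) || all(n1 == 0)) {
    warn("all-zero mean adjacency; using a uniform prior")
    H <- matrix(1 / n^2, n, n)
    return(list(H = H, h = as.vector(H)))
  }
  cs <- (meanA_group0 %*% t(meanA_group1)) /
    (pmax(n0, .Machine$double.eps) %o% pmax(n1, .Machine$double.eps))
  H <- sin((pi / 2) * pmin(pmax(cs, 0), 1))
  H <- H / sum(H)
  list(H = H, h = as.vector(H))
}

row_normalize <- function(A) {
  d <- rowSums(abs(A))
  A / ifelse(d > 0, d, 1)
}

#' Kronecker random-walk similarity fixed point
#'
#' Solves `s = alpha (A1 (x) A2) s + (1 - alpha) h` by fixed-point
#' iteration after row-normalizing both adjacencies (random-walk form, so
#' the Kronecker operator has spectral radius at most 1 and the iteration
#' contracts for `alpha < 1`). The n^2 x n^2 Kronecker product is never
#' materialized: the matrix-vector product uses the identity
#' `(A1 (x) A2) vec(X) = vec(A2 X A1^T)`.
#'
#' @param A1,A2 Adjacency matrices (n x n, nonnegative weights expected).
#' @param h Restart vector of length n^2 (e.g. from [build_prior()]).
#' @param alpha Mixing weight in `[0, 1)` (default 0.5).
#' @param tol Sup-norm residual tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 10000).
#' @return A list with `s` (length n^2), `S` (n x n), `iterations`, and
#'   `residual`.
#' @export
kronecker_fixed_point <- function(A1, A2, h, alpha = 0.5, tol = 1e-8,
                                  max_iter = 10000L) {
  check_scalar_num(alpha, "alpha", lower = 0, upper = 1,
                   closed_upper = FALSE)
  n1 <- nrow(A1)
  n2 <- nrow(A2)
  stopifnot(length(h) == n1 * n2)
  P1 <- row_normalize(A1)
  P2 <- row_normalize(A2)
  X <- matrix(h, n2, n1)
  Hm <- (1 - alpha) * X
  res <- Inf
  for (it in seq_len(max_iter)) {
    Xn <- alpha * (P2 %*% X %*% t(P1)) + Hm
    res <- max(abs(Xn - X))
    X <- Xn
    if (res <= tol) {
      return(list(s = as.vector(X), S = X, iterations = it, residual = res))
    }
  }
  stop_state("Kronecker fixed point did not converge in %d iterations (residual %g)",
             max_iter, res)
}

#' Combined alignment objective
#'
#' Evaluates
#' \eqn{\alpha s^T (D - A_1 \otimes A_2) s + (1-\alpha) \|D^{1/2}(s-h)\|^2}
#' with `D = D1 (x) D2` the Kronecker degree matrix, using implicit
#' Kronecker identities throughout.
#'
#' @inheritParams kronecker_fixed_point
#' @param s Similarity vector of length n^2.
#' @param D1,D2 Degree matrices; default `diag(rowSums(abs(A)))`.
#' @return Scalar objective value.
#' @export
ineat_objective <- function(s, A1, A2, h, alpha = 0.5,
                            D1 = degree_matrix(abs(A1)),
                            D2 = degree_matrix(abs(A2))) {
  n1 <- nrow(A1)
  n2 <- nrow(A2)
  if (length(s) != n1 * n2 || length(h) != n1 * n2) {
    stop_invalid("s and h must have length nrow(A1) * nrow(A2)")
  }
  X <- matrix(s, n2, n1)
  d <- as.vector(diag(D2) %o% diag(D1))       # diag of D1 (x) D2, vec order
  quad <- sum(s * (d * s)) - sum(s * as.vector(A2 %*% X %*% t(A1)))
  fit <- sum(d * (s - h)^2)
  alpha * quad + (1 - alpha) * fit
}

#' Extract a permutation from a similarity matrix
#'
#' Maximum-weight linear assignment over `S`: returns the permutation
#' matrix `P` maximizing `sum_ij S_ij P_ij` (ties broken deterministically
#' in row-major order by the solver's scan order).
#'
#' @param S Square nonnegative similarity matrix.
#' @return Permutation matrix `P` with `P[i, j] = 1` when row-node i is
#'   assigned column-node j.
#' @export
extract_permutation <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  a <- solve_assignment(max(S) - S)
  P <- matrix(0, nrow(S), ncol(S))
  P[cbind(seq_len(nrow(S)), a)] <- 1
  P
}

permutation_vector <- function(P) apply(P > 0, 1, which)

#' Reorganize channels by a permutation
#'
#' Applies a channel permutation to an `eeg_epochs` object (rows of every
#' trial), an ERP, or a square channel x channel matrix (rows and
#' columns). Applying `P` then `t(P)` is the identity, and permuting
#' epochs commutes with computing connectivity.
#'
#' @param x `eeg_epochs`, `eeg_erp`, or square matrix.
#' @param P Permutation matrix from [extract_permutation()].
#' @return Same type as `x`, channels reordered.
#' @export
reorganize_channels <- function(x, P) {
  perm <- permutation_vector(P)
  if (inherits(x, "eeg_epochs")) {
    if (length(perm) != n_channels_of(x)) {
      stop_invalid("permutation size %d does not match %d channels",
                   length(perm), n_channels_of(x))
    }
    x$data <- x$data[, perm, , drop = FALSE]
    x$channels <- x$channels[perm]
    x
  } else if (inherits(x, "eeg_erp")) {
    x$data <- x$data[perm, , drop = FALSE]
    x$channels <- x$channels[perm]
    x
  } else if (is.matrix(x)) {
    if (length(perm) != nrow(x)) {
      stop_invalid("permutation size %d does not match matrix dimension %d",
                   length(perm), nrow(x))
    }
    x[perm, perm, drop = FALSE]
  } else {
    stop_invalid("cannot reorganize an object of class %s", class(x)[1])
  }
}

#' Align one subject's single- and multi-hop graphs
#'
#' The full incomplete-network-alignment step for one subject: random-walk
#' similarity between the nodes of the subject's single-hop graph `A1` and
#' multi-hop graph `A2` under a group-informed prior, hard permutation
#' extraction, and evaluation of both objectives.
#'
#' @param graph A `conn_graph` for the subject.
#' @param prior A [build_prior()] result (group templates from the
#'   training split); defaults to the uniform prior.
#' @param alpha,tol,max_iter Passed to [kronecker_fixed_point()].
#' @return An `alignment_result` with `S`, `s`, `P`, `alpha`,
#'   `objective_values` (matching and combined), `iterations`, `residual`.
#' @export
align_subject <- function(graph, prior = NULL, alpha = 0.5, tol = 1e-8,
                          max_iter = 10000L) {
  A1 <- abs(graph$A1)
  A2 <- abs(graph$A2)
  n <- nrow(A1)
  h <- if (is.null(prior)) rep(1 / n^2, n^2) else prior$h
  fp <- kronecker_fixed_point(A1, A2, h, alpha, tol, max_iter)
  S <- matrix(fp$s, n, n)
  P <- extract_permutation(S)
  structure(list(
    s = fp$s, S = S, P = P, alpha = alpha,
    objective_values = c(
      matching = matching_objective(P, A1, A2),
      combined = ineat_objective(fp$s, A1, A2, h, alpha)
    ),
    iterations = fp$iterations, residual = fp$residual
  ), class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %d nodes, alpha = %g, %d iterations (residual %.2e)\n",
              nrow(x$S), x$alpha, x$iterations, x$residual))
  cat(sprintf("  objectives: matching %.4g, combined %.4g\n",
              x$objective_values["matching"], x$objective_values["combined"]))
  invisible(x)
}
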