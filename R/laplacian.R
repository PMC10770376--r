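#' Graph Laplacians
#'
#' Combinatorial (`L = D - A`) or symmetric normalized
#' (`L = I - D^{-1/2} A D^{-1/2}`) Laplacian of a symmetric, nonnegative,
#' zero-diagonal adjacency. Zero-degree nodes get `D^{-1/2} = 0`, leaving
#' isolated rows equal to the identity row in the normalized form.
#'
#' @param A Adjacency matrix.
#' @param normalized Use the normalized form (default `TRUE`).
#' @return Laplacian matrix.
#' @export
graph_laplacian <- function(A, normalized = TRUE) {
  if (!isSymmetric(unname(A), tol = 1e-10)) {
    stop_invalid("adjacency must be symmetric")
  }
  d <- rowSums(A)
  if (normalized) {
    dis <- ifelse(d > 0, 1 / sqrt(d), 0)
    diag(nrow(A)) - A * (dis %o% dis)
  } else {
    diag(d, nrow(A)) - A
  }
}

#' Graph spectrum
#'
#' Eigendecomposition of a Laplacian: orthonormal Fourier basis `U`,
#' eigenvalues, and the scaled Laplacian `2 L / lambda_max - I` whose
#' spectrum lies in `[-1, 1]` for Chebyshev filtering.
#'
#' @param A Adjacency matrix.
#' @param normalized Normalized Laplacian (default `TRUE`).
#' @return A list with `L`, `U`, `lambda`, `L_tilde`.
#' @export
graph_spectrum <- function(A, normalized = TRUE) {
  L <- graph_laplacian(A, normalized)
  eg <- eigen(L, symmetric = TRUE)
  ord <- order(eg$values)
  list(L = L, U = eg$vectors[, ord, drop = FALSE],
       lambda = eg$values[ord],
       L_tilde = scale_laplacian(L, max(eg$values)))
}

#' Graph Fourier transform
#'
#' `chi = U^T x` and its inverse `x = U chi` with `U` the Laplacian
#' eigenvector basis; exact round trip, Parseval holds.
#'
#' @param x Graph signal (vector or node x feature matrix).
#' @param U Eigenvector matrix.
#' @return Transformed signal of the same shape.
#' @export
graph_fourier <- function(x, U) {
  if (NROW(x) != nrow(U)) stop_invalid("signal and basis dimensions differ")
  crossprod(U, x)
}

#' @rdname graph_fourier
#' @param chi Spectral coefficients.
#' @export
inverse_graph_fourier <- function(chi, U) {
  if (NROW(chi) != nrow(U)) stop_invalid("signal and basis dimensions differ")
  U %*% chi
}

# Largest Laplacian eigenvalue by power iteration (L is PSD so plain
# power iteration converges to lambda_max); deterministic start vector.
lambda_max_power <- function(L, tol = 1e-6, max_iter = 1000L) {
  n <- nrow(L)
  v <- rep(1, n) + seq_len(n) / n        # breaks symmetry deterministically
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (i in seq_len(max_iter)) {
    w <- L %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v_new <- as.vector(w / nw)
    lam_new <- sum(v_new * (L %*% v_new))
    if (abs(lam_new - lam) <= tol * max(1, abs(lam_new))) return(lam_new)
    v <- v_new
    lam <- lam_new
  }
  lam
}

#' Scale a Laplacian for Chebyshev filtering
#'
#' `L_tilde = 2 L / lambda_max - I`. When `lambda_max` is not supplied it
#' is computed by power iteration (tolerance 1e-6).
#'
#' @param L Laplacian.
#' @param lambda_max Optional precomputed largest eigenvalue.
#' @return Scaled Laplacian.
#' @export
scale_laplacian <- function(L, lambda_max = NULL) {
  lambda_max <- lambda_max %||% lambda_max_power(L)
  if (lambda_max <= 0) stop_invalid("Laplacian has no positive eigenvalue")
  2 * L / lambda_max - diag(nrow(L))
}

#' Chebyshev graph filtering
#'
#' Evaluates `y = sum_k theta_k T_k(L_tilde) x` through the three-term
#' recursion `T_k = 2 L_tilde T_{k-1} - T_{k-2}` (no eigendecomposition).
#'
#' @param x Graph signal (vector or node x feature matrix).
#' @param L_tilde Scaled Laplacian from [scale_laplacian()].
#' @param theta Coefficient vector, length `K >= 1`.
#' @return Filtered signal, same shape as `x`.
#' @export
cheb_filter <- function(x, L_tilde, theta) {
  K <- length(theta)
  if (K < 1L) stop_invalid("need at least one Chebyshev coefficient")
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  Tkm2 <- x
  y <- theta[1] * x
  if (K >= 2L) {
    Tkm1 <- L_tilde %*% x
    y <- y + theta[2] * Tkm1
    if (K >= 3L) {
      for (k in 3:K) {
        Tk <- 2 * (L_tilde %*% Tkm1) - Tkm2
        y <- y + theta[k] * Tk
        Tkm2 <- Tkm1
        Tkm1 <- Tk
      }
    }
  }
  if (vec) drop(y) else y
}

# Greedy weighted-edge pairing for graph coarsening: heaviest edges pair
# first (ties by node index); leftover nodes are paired by index so the
# node count exactly halves. Returns the cluster index per node.
coarsen_pairing <- function(A) {
  n <- nrow(A)
  stopifnot(n %% 2 == 0)
  w <- abs(A)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    ord <- order(-w[idx], idx[, 1], idx[, 2])
    idx <- idx[ord, , drop = FALSE]
  }
  matched <- rep(FALSE, n)
  partner <- integer(n)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (!matched[i] && !matched[j]) {
      matched[c(i, j)] <- TRUE
      partner[i] <- j
      partner[j] <- i
    }
  }
  left <- which(!matched)
  if (length(left) > 0) {
    for (k in seq(1, length(left), by = 2)) {
      i <- left[k]; j <- left[k + 1]
      partner[i] <- j
      partner[j] <- i
    }
  }
  cl <- integer(n)
  next_id <- 0L
  for (i in seq_len(n)) {
    if (cl[i] == 0L) {
      next_id <- next_id + 1L
      cl[i] <- next_id
      cl[partner[i]] <- next_id
    }
  }
  cl
}

# Mean-pooling matrix (n/2 x n) for a cluster assignment.
pool_matrix <- function(cl) {
  n <- length(cl)
  m <- max(cl)
  Matrix::sparseMatrix(i = cl, j = seq_len(n), x = 1 / 2, dims = c(m, n))
}

# Coarse adjacency: sum of inter-cluster weights, zero diagonal.
coarsen_adjacency <- function(A, cl) {
  M <- Matrix::sparseMatrix(i = seq_along(cl), j = cl, x = 1,
                            dims = c(length(cl), max(cl)))
  Ac <- as.matrix(Matrix::t(M) %*% A %*% M)
  diag(Ac) <- 0
  Ac
}
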