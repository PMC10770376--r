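#' Self-expressive dictionary for one electrode
#'
#' For electrode `e`, each subject's trial-averaged signal at `e` is the
#' target `x_i` (length d) and the signals of the remaining electrodes
#' form the dictionary `X_i` (d x (E-1)): the sparse-graph stage asks how
#' well every electrode is reconstructed from the others.
#'
#' @param erps List of per-subject ERPs ([eeg_erp()] objects or
#'   channels x samples matrices, identical channel order).
#' @param e Electrode index (1-based).
#' @return A list with `x` (list of vectors), `X` (list of d x (E-1)
#'   matrices), `electrode`, `dict_index` (the electrode index of each
#'   dictionary column), and `channels`.
#' @export
build_dictionary <- function(erps, e) {
  mats <- lapply(erps, function(s) if (inherits(s, "eeg_erp")) s$data else s)
  E <- nrow(mats[[1]])
  if (E < 2L) stop_invalid("need at least 2 electrodes")
  check_scalar_num(e, "e", lower = 1, upper = E)
  channels <- if (inherits(erps[[1]], "eeg_erp")) erps[[1]]$channels
              else rownames(mats[[1]]) %||% paste0("ch", seq_len(E))
  list(
    x = lapply(mats, function(m) m[e, ]),
    X = lapply(mats, function(m) t(m[-e, , drop = FALSE])),
    electrode = as.integer(e),
    dict_index = setdiff(seq_len(E), e),
    channels = channels
  )
}

#' Pairwise subject similarities for the smoothness penalties
#'
#' Pearson correlation between the subjects' electrode signals, clipped to
#' `[0, 1]`, with unit diagonal. In `"group"` mode pairs from different
#' groups are masked to zero, so the quadratic smoothness penalty pulls
#' together reconstruction weights only within a group; in `"trial"` mode
#' the columns are replicates and pairs from different subjects are
#' masked.
#'
#' @param signals d x n matrix, one column per subject (or replicate).
#' @param mode `"group"` or `"trial"`.
#' @param block Group label (mode `"group"`) or subject id (mode
#'   `"trial"`) per column; `NULL` leaves all pairs active.
#' @return Symmetric n x n similarity matrix in `[0, 1]`.
#' @export
pairwise_similarities <- function(signals, mode = c("group", "trial"),
                                  block = NULL) {
  mode <- match.arg(mode)
  if (ncol(signals) < 2L) stop_invalid("need at least 2 subjects")
  S <- suppressWarnings(cor(signals))
  S[!is.finite(S)] <- 0
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  if (!is.null(block)) {
    same <- outer(block, block, "==")
    S[!same] <- 0
  }
  S
}

l21_row_weights <- function(B, lambda, nr) {
  if (lambda == 0) return(numeric(nr))
  if (is.null(B)) return(rep(lambda, nr))
  spread <- apply(B, 1, function(r) diff(range(r)))
  if (any(spread > 1e-12)) {
    stop_invalid("the proximal step requires weighting matrices constant within each row")
  }
  lambda * B[, 1]
}

smooth_laplacian <- function(S) {
  if (is.null(S)) return(NULL)
  diag(rowSums(S)) - S
}

#' Sparse-graph objective
#'
#' Full objective of the per-electrode sparse reconstruction:
#' reconstruction error plus row-wise l2,1 sparsity (group- and
#' trial-weighted) plus the two quadratic smoothness penalties.
#'
#' @param W (E-1) x n weight matrix, one column per subject.
#' @param dict A [build_dictionary()] result.
#' @param lambdas Nonnegative `c(lambda1, lambda2, lambda3, lambda4)`.
#' @param Bg,Bt Optional weighting matrices (defaults: all ones).
#' @param Sg,St Optional similarity matrices from
#'   [pairwise_similarities()] (defaults: no smoothness).
#' @return Scalar objective value.
#' @export
sparse_objective <- function(W, dict, lambdas, Bg = NULL, Bt = NULL,
                             Sg = NULL, St = NULL) {
  if (any(lambdas < 0)) stop_invalid("lambdas must be nonnegative")
  recon <- 0
  for (i in seq_along(dict$x)) {
    r <- dict$x[[i]] - dict$X[[i]] %*% W[, i]
    recon <- recon + 0.5 * sum(r^2)
  }
  rn <- sqrt(rowSums(W^2))
  pen <- sum(l21_row_weights(Bg, lambdas[1], nrow(W)) * rn) +
    sum(l21_row_weights(Bt, lambdas[3], nrow(W)) * rn)
  sm <- 0
  if (lambdas[2] > 0 && !is.null(Sg)) {
    sm <- sm + lambdas[2] * 2 * sum((W %*% smooth_laplacian(Sg)) * W)
  }
  if (lambdas[4] > 0 && !is.null(St)) {
    sm <- sm + lambdas[4] * 2 * sum((W %*% smooth_laplacian(St)) * W)
  }
  recon + pen + sm
}

#' Fit the sparse self-expressive graph for one electrode
#'
#' Proximal-gradient (ISTA-style) minimization: the reconstruction and
#' smoothness terms are handled by gradient steps with backtracking line
#' search, the l2,1 terms by a row-wise group soft-threshold. The
#' objective is non-increasing by construction; the solver stops when the
#' relative decrease falls below `tol`.
#'
#' @inheritParams sparse_objective
#' @param lambdas Defaults `c(0.1, 0.01, 0.1, 0.01)`.
#' @param tol Relative-decrease stopping tolerance (default 1e-9).
#' @param max_iter Iteration cap (default 2000).
#' @return A `sparse_graph_fit` with `W`, `objective_trace`, `lambdas`,
#'   `electrode`, `dict_index`, `iterations`.
#' @export
fit_sparse_graph <- function(dict, lambdas = c(0.1, 0.01, 0.1, 0.01),
                             Bg = NULL, Bt = NULL, Sg = NULL, St = NULL,
                             tol = 1e-9, max_iter = 2000L) {
  if (any(lambdas < 0)) stop_invalid("lambdas must be nonnegative")
  n <- length(dict$x)
  p <- ncol(dict$X[[1]])
  G <- lapply(dict$X, crossprod)                       # X^T X
  cvec <- mapply(function(X, x) crossprod(X, x), dict$X, dict$x,
                 SIMPLIFY = FALSE)
  x2 <- vapply(dict$x, function(x) 0.5 * sum(x^2), 0)
  Lg <- if (lambdas[2] > 0 && !is.null(Sg)) smooth_laplacian(Sg)
  Lt <- if (lambdas[4] > 0 && !is.null(St)) smooth_laplacian(St)
  cr <- l21_row_weights(Bg, lambdas[1], p) + l21_row_weights(Bt, lambdas[3], p)

  smooth_val <- function(W) {
    v <- 0
    for (i in seq_len(n)) {
      v <- v + 0.5 * sum(W[, i] * (G[[i]] %*% W[, i])) -
        sum(cvec[[i]] * W[, i]) + x2[i]
    }
    if (!is.null(Lg)) v <- v + lambdas[2] * 2 * sum((W %*% Lg) * W)
    if (!is.null(Lt)) v <- v + lambdas[4] * 2 * sum((W %*% Lt) * W)
    v
  }
  smooth_grad <- function(W) {
    Gr <- matrix(0, p, n)
    for (i in seq_len(n)) Gr[, i] <- G[[i]] %*% W[, i] - cvec[[i]]
    if (!is.null(Lg)) Gr <- Gr + 4 * lambdas[2] * (W %*% Lg)
    if (!is.null(Lt)) Gr <- Gr + 4 * lambdas[4] * (W %*% Lt)
    Gr
  }
  prox <- function(W, step) {
    if (all(cr == 0)) return(W)
    rn <- sqrt(rowSums(W^2))
    shrink <- pmax(0, 1 - step * cr / pmax(rn, .Machine$double.eps))
    W * shrink
  }
  objective <- function(W) {
    smooth_val(W) + sum(cr * sqrt(rowSums(W^2)))
  }

  W <- matrix(0, p, n)
  obj <- objective(W)
  trace <- obj
  # gradient Lipschitz bound: block Hessian is blkdiag(G_i) plus the
  # smoothness couplings 4*lambda*(L (x) I)
  spec_norm <- function(M) max(eigen(M, symmetric = TRUE,
                                     only.values = TRUE)$values)
  L_lip <- max(vapply(G, spec_norm, 0))
  if (!is.null(Lg)) L_lip <- L_lip + 4 * lambdas[2] * spec_norm(Lg)
  if (!is.null(Lt)) L_lip <- L_lip + 4 * lambdas[4] * spec_norm(Lt)
  step0 <- 1 / max(L_lip, 1e-12)
  step <- step0
  bad <- 0L
  for (it in seq_len(max_iter)) {
    Gr <- smooth_grad(W)
    repeat {
      Wn <- prox(W - step * Gr, step)
      objn <- objective(Wn)
      if (objn <= obj + 1e-12 || step < 1e-14) break
      step <- step / 2
    }
    if (objn > obj + 1e-10) {
      bad <- bad + 1L
      if (bad >= 3L) stop_state("sparse-graph objective diverged")
    } else bad <- 0L
    rel <- (obj - objn) / max(abs(trace[1]), 1e-12)
    W <- Wn
    obj <- objn
    trace <- c(trace, obj)
    if (rel >= 0 && rel < tol) break
    step <- min(step * 1.5, 1.9 * step0)   # cautious step re-growth
  }
  structure(list(W = W, objective_trace = trace, lambdas = lambdas,
                 electrode = dict$electrode, dict_index = dict$dict_index,
                 channels = dict$channels, iterations = length(trace) - 1L),
            class = "sparse_graph_fit")
}

#' Reweight a connectivity graph from sparse-graph fits
#'
#' Replaces the weight of edge (e, e') by the symmetrized reconstruction
#' mass `0.5 * (|W^e[e']| + |W^e'[e]|)`, with `|W^e[e']|` the absolute
#' weight of electrode e' in the reconstruction of electrode e, averaged
#' over the subjects of the fit (or a single subject if `subject` is
#' given). Rows the solver zeroed prune their edges.
#'
#' @param models List of `sparse_graph_fit`, one per electrode, in
#'   electrode order.
#' @param W_conn Connectivity weight matrix the mass reweights (used for
#'   dimension/labels only).
#' @param subject Optional subject column index.
#' @return Symmetric reweighted adjacency matrix, zero diagonal.
#' @export
apply_sparse_graph <- function(models, W_conn, subject = NULL) {
  E <- nrow(W_conn)
  if (length(models) != E || any(!vapply(models, inherits, TRUE,
                                         "sparse_graph_fit"))) {
    stop_invalid("need one fitted model per electrode")
  }
  M <- matrix(0, E, E, dimnames = dimnames(W_conn))
  for (e in seq_len(E)) {
    w <- if (is.null(subject)) rowMeans(abs(models[[e]]$W))
         else abs(models[[e]]$W[, subject])
    M[e, models[[e]]$dict_index] <- w
  }
  A <- (M + t(M)) / 2
  diag(A) <- 0
  A
}

#' Fit the sparse-graph stage across all electrodes
#'
#' Convenience wrapper: builds every electrode's dictionary from the
#' subjects' ERPs, computes group-masked similarities, fits each
#' electrode, and returns the fits plus the pooled reweighted adjacency.
#'
#' @param erps List of per-subject ERPs (matrices or [eeg_erp()]).
#' @param groups Group label per subject.
#' @param lambdas,tol,max_iter Passed to [fit_sparse_graph()].
#' @return A list with `models` (per electrode) and `A` (reweighted
#'   adjacency from [apply_sparse_graph()]).
#' @export
sparse_graph_stage <- function(erps, groups,
                               lambdas = c(0.1, 0.01, 0.1, 0.01),
                               tol = 1e-5, max_iter = 150L) {
  mats <- lapply(erps, function(s) if (inherits(s, "eeg_erp")) s$data else s)
  E <- nrow(mats[[1]])
  models <- vector("list", E)
  for (e in seq_len(E)) {
    dict <- build_dictionary(mats, e)
    Sg <- if (lambdas[2] > 0) {
      pairwise_similarities(sapply(mats, function(m) m[e, ]),
                            mode = "group", block = groups)
    }
    models[[e]] <- fit_sparse_graph(dict, lambdas, Sg = Sg,
                                    tol = tol, max_iter = max_iter)
  }
  W0 <- matrix(0, E, E,
               dimnames = list(rownames(mats[[1]]), rownames(mats[[1]])))
  list(models = models, A = apply_sparse_graph(models, W0))
}
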