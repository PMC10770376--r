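#' Chebyshev spectral GCN classifier
#'
#' `build_model()` describes the architecture: two Chebyshev graph
#' convolutions with interleaved node-coarsening pools, global mean
#' pooling, a fully connected layer and a softmax output.
#' With the default widths (64-feature input, 64 then 32 convolution
#' features, 32-unit fully connected layer) the trainable parameter
#' counts are `4096 K1 + 64` (conv1), `2048 K2 + 32` (conv2) and `1056`
#' (fully connected); the output head adds `32 M + M`.
#'
#' Each subject is one sample: node features are the rows of the
#' subject's (reorganized) connectivity matrix, and the convolution
#' Laplacian comes from the subject's graph (or a shared
#' graph-signal-processing graph). Pooling halves the node set twice by
#' greedy heaviest-edge pairing; pools carry no trainable parameters.
#'
#' @param K1,K2 Chebyshev orders of the two convolution layers.
#' @param M Number of classes (>= 2).
#' @param n_nodes Nodes of the input graph (divisible by 4).
#' @param n_features Input features per node (defaults to `n_nodes`).
#' @param f1,f2,fc Layer widths (defaults 64, 32, 32).
#' @param dropout Dropout rate on the fully connected activations
#'   (default 0.35).
#' @param lr Reference learning rate stored with the architecture
#'   (default 1e-5); [gcn_fit()] exposes its own optimization schedule.
#' @return A `gcn_model` architecture description.
#' @export
build_model <- function(K1 = 3, K2 = 3, M = 2, n_nodes = 64,
                        n_features = n_nodes, f1 = 64, f2 = 32, fc = 32,
                        dropout = 0.35, lr = 1e-5) {
  check_scalar_num(K1, "K1", lower = 1)
  check_scalar_num(K2, "K2", lower = 1)
  check_scalar_num(M, "M", lower = 2)
  check_scalar_num(dropout, "dropout", lower = 0, upper = 1,
                   closed_upper = FALSE)
  if (n_nodes %% 4 != 0) {
    stop_invalid("n_nodes must be divisible by 4 (two halving pools)")
  }
  structure(list(K1 = as.integer(K1), K2 = as.integer(K2),
                 M = as.integer(M), n_nodes = as.integer(n_nodes),
                 n_features = as.integer(n_features),
                 f1 = as.integer(f1), f2 = as.integer(f2),
                 fc = as.integer(fc), dropout = dropout, lr = lr),
            class = "gcn_model")
}

#' Trainable parameter counts per layer
#'
#' @param model A `gcn_model`.
#' @return Named vector: `conv1`, `conv2`, `fc`, `out`.
#' @export
model_param_counts <- function(model) {
  c(conv1 = model$K1 * model$n_features * model$f1 + model$f1,
    conv2 = model$K2 * model$f1 * model$f2 + model$f2,
    fc = model$f2 * model$fc + model$fc,
    out = model$fc * model$M + model$M)
}

#' @export
print.gcn_model <- function(x, ...) {
  pc <- model_param_counts(x)
  cat(sprintf("<gcn_model> ChebConv(K=%d, %d->%d) | pool/2 | ChebConv(K=%d, %d->%d) | pool/2 | mean | fc(%d->%d) | out(%d->%d)\n",
              x$K1, x$n_features, x$f1, x$K2, x$f1, x$f2,
              x$f2, x$fc, x$fc, x$M))
  cat(sprintf("  parameters: conv1 %d, conv2 %d, fc %d, out %d (dropout %g)\n",
              pc[1], pc[2], pc[3], pc[4], x$dropout))
  invisible(x)
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

gcn_init_params <- function(model) {
  list(
    W1 = glorot(model$K1 * model$n_features, model$f1),
    b1 = numeric(model$f1),
    W2 = glorot(model$K2 * model$f1, model$f2),
    b2 = numeric(model$f2),
    Wf = glorot(model$f2, model$fc),
    bf = numeric(model$fc),
    Wo = glorot(model$fc, model$M),
    bo = numeric(model$M)
  )
}

# [T_0 X | T_1 X | ... | T_{K-1} X] via the Chebyshev recursion;
# L may be a dense matrix or a sparse block-diagonal Matrix.
cheb_stack <- function(L, X, K) {
  out <- vector("list", K)
  out[[1]] <- X
  if (K >= 2) {
    out[[2]] <- as.matrix(L %*% X)
    if (K >= 3) {
      for (k in 3:K) {
        out[[k]] <- as.matrix(2 * (L %*% out[[k - 1]]) - out[[k - 2]])
      }
    }
  }
  do.call(cbind, out)
}

# Clenshaw evaluation of sum_k T_k(L) d_k for a list of matrices d_k
# (adjoint of cheb_stack contractions; L symmetric).
clenshaw_adjoint <- function(L, dlist) {
  K <- length(dlist)
  if (K == 1) return(dlist[[1]])
  b1 <- matrix(0, nrow(dlist[[1]]), ncol(dlist[[1]]))
  b2 <- b1
  for (k in K:2) {
    b0 <- dlist[[k]] + as.matrix(2 * (L %*% b1)) - b2
    b2 <- b1
    b1 <- b0
  }
  dlist[[1]] + as.matrix(L %*% b1) - b2
}

split_blocks <- function(M, width) {
  K <- ncol(M) / width
  lapply(seq_len(K), function(k) {
    M[, ((k - 1) * width + 1):(k * width), drop = FALSE]
  })
}

# Graph-dependent precomputation (independent of the node features).
prep_graph_part <- function(A) {
  lt1 <- scale_laplacian(graph_laplacian(A))
  cl1 <- coarsen_pairing(A)
  A2c <- coarsen_adjacency(A, cl1)
  lt2 <- scale_laplacian(graph_laplacian(A2c))
  cl2 <- coarsen_pairing(A2c)
  list(lt1 = lt1, lt2 = lt2,
       P1 = pool_matrix(cl1), P2 = pool_matrix(cl2))
}

# Per-subject precomputation: conv1 basis plus the graph part.
gcn_prep_subject <- function(X, A, model, gp = NULL) {
  stopifnot(nrow(X) == model$n_nodes, ncol(X) == model$n_features)
  gp <- gp %||% prep_graph_part(A)
  c(list(TX = cheb_stack(gp$lt1, X, model$K1)), gp)
}

# Prep a list of inputs, computing the graph part once per distinct
# adjacency (trial-level prediction reuses one subject graph many times).
gcn_prep_inputs <- function(inputs, model) {
  keys <- vapply(inputs, function(s) hash_object(s$A), "")
  cache <- new.env(parent = emptyenv())
  lapply(seq_along(inputs), function(i) {
    k <- keys[i]
    gp <- if (!is.null(cache[[k]])) cache[[k]] else {
      cache[[k]] <- prep_graph_part(inputs[[i]]$A)
      cache[[k]]
    }
    gcn_prep_subject(inputs[[i]]$X, inputs[[i]]$A, model, gp)
  })
}

gcn_make_batch <- function(preps, model) {
  S <- length(preps)
  n3 <- model$n_nodes / 4
  list(
    S = S,
    TX = do.call(rbind, lapply(preps, `[[`, "TX")),
    L1 = Matrix::bdiag(lapply(preps, `[[`, "lt1")),
    L2 = Matrix::bdiag(lapply(preps, `[[`, "lt2")),
    P1 = Matrix::bdiag(lapply(preps, `[[`, "P1")),
    P2 = Matrix::bdiag(lapply(preps, `[[`, "P2")),
    Gm = Matrix::sparseMatrix(i = rep(seq_len(S), each = n3),
                              j = seq_len(S * n3), x = 1 / n3,
                              dims = c(S, S * n3))
  )
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

gcn_forward <- function(params, batch, model, dropmask = NULL) {
  Z1 <- add_bias(batch$TX %*% params$W1, params$b1)
  H1 <- pmax(Z1, 0)
  Hp1 <- as.matrix(batch$P1 %*% H1)
  C2 <- cheb_stack(batch$L2, Hp1, model$K2)
  Z2 <- add_bias(C2 %*% params$W2, params$b2)
  H2 <- pmax(Z2, 0)
  Hp2 <- as.matrix(batch$P2 %*% H2)
  g <- as.matrix(batch$Gm %*% Hp2)
  Zf <- add_bias(g %*% params$Wf, params$bf)
  Hf <- pmax(Zf, 0)
  Hd <- if (is.null(dropmask)) Hf else Hf * dropmask
  Zo <- add_bias(Hd %*% params$Wo, params$bo)
  list(Z1 = Z1, H1 = H1, Hp1 = Hp1, C2 = C2, Z2 = Z2, H2 = H2,
       Hp2 = Hp2, g = g, Zf = Zf, Hf = Hf, Hd = Hd, Zo = Zo,
       probs = softmax_rows(Zo))
}

# Backward pass. `seed_grad`: gradient at the logits (defaults to the
# cross-entropy gradient wrt Y). `guided` applies the
# guided-backpropagation overwrite at every ReLU: the gradient is kept
# only where both the forward activation and the upstream gradient are
# positive. `input_grad` additionally chains down to the node features.
gcn_backward <- function(params, cache, batch, model, Y = NULL,
                         seed_grad = NULL, dropmask = NULL,
                         guided = FALSE, input_grad = FALSE) {
  relu_back <- function(up, Z) {
    g <- up * (Z > 0)
    if (guided) g <- g * (up > 0)
    g
  }
  dZo <- seed_grad %||% ((cache$probs - Y) / nrow(Y))
  dWo <- crossprod(cache$Hd, dZo)
  dbo <- colSums(dZo)
  dHd <- dZo %*% t(params$Wo)
  dHf <- if (is.null(dropmask)) dHd else dHd * dropmask
  dZf <- relu_back(dHf, cache$Zf)
  dWf <- crossprod(cache$g, dZf)
  dbf <- colSums(dZf)
  dg <- dZf %*% t(params$Wf)
  dHp2 <- as.matrix(Matrix::t(batch$Gm) %*% dg)
  dH2 <- as.matrix(Matrix::t(batch$P2) %*% dHp2)
  dZ2 <- relu_back(dH2, cache$Z2)
  dW2 <- crossprod(cache$C2, dZ2)
  db2 <- colSums(dZ2)
  dC2 <- dZ2 %*% t(params$W2)
  dHp1 <- clenshaw_adjoint(batch$L2, split_blocks(dC2, model$f1))
  dH1 <- as.matrix(Matrix::t(batch$P1) %*% dHp1)
  dZ1 <- relu_back(dH1, cache$Z1)
  dW1 <- crossprod(batch$TX, dZ1)
  db1 <- colSums(dZ1)
  grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                Wf = dWf, bf = dbf, Wo = dWo, bo = dbo)
  if (input_grad) {
    W1k <- lapply(seq_len(model$K1), function(k) {
      params$W1[((k - 1) * model$n_features + 1):(k * model$n_features), ,
                drop = FALSE]
    })
    grads$X <- clenshaw_adjoint(batch$L1, lapply(W1k, function(Wk) {
      dZ1 %*% t(Wk)
    }))
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

#' Multi-class cross-entropy loss
#'
#' `-(1/N) sum_i sum_c y_ic log(p_ic)` with the log clamped at 1e-12.
#' Rows of the prediction matrix must sum to 1.
#'
#' @param y_true Label vector or one-hot matrix.
#' @param y_pred_probs N x M probability matrix.
#' @return Scalar loss.
#' @export
cross_entropy <- function(y_true, y_pred_probs) {
  y_pred_probs <- as.matrix(y_pred_probs)
  if (any(abs(rowSums(y_pred_probs) - 1) > 1e-6) || any(y_pred_probs < 0)) {
    stop_invalid("prediction rows must be probability vectors")
  }
  if (is.null(dim(y_true))) y_true <- onehot(y_true, ncol(y_pred_probs))
  # rows of y_true are one-hot, so the inner sum picks the true class
  -mean(rowSums(y_true * log(pmax(y_pred_probs, 1e-12))))
}

onehot <- function(labels, M = NULL, classes = NULL) {
  classes <- classes %||% sort(unique(labels))
  if (!is.null(M) && length(classes) < M) classes <- seq_len(M) - 1
  Y <- matrix(0, length(labels), length(classes),
              dimnames = list(NULL, as.character(classes)))
  Y[cbind(seq_along(labels), match(labels, classes))] <- 1
  Y
}

#' Fit the GCN on a set of subjects
#'
#' Full-batch Adam training of [build_model()] on per-subject graph
#' inputs. Training is deterministic given `seed` (parameter
#' initialization and dropout masks); it stops early when the training
#' loss has not improved for `patience` epochs, returning the best-loss
#' parameters.
#'
#' @param inputs List, one element per subject: `list(X = node-feature
#'   matrix, A = adjacency matrix)`.
#' @param labels Group label per subject (0 = PD, 1 = HC).
#' @param model A `gcn_model` (default matches the subjects' dimensions).
#' @param seed Integer seed.
#' @param epochs Maximum epochs (default 200).
#' @param lr Adam learning rate for this schedule (default 1e-3; the
#'   full-batch subject-level setting takes few, large steps).
#' @param patience Early-stopping patience in epochs (default 20).
#' @return A `gcn_fit` with `params`, `model`, `loss_trace`, `classes`.
#' @export
gcn_fit <- function(inputs, labels, model = NULL, seed = 1, epochs = 200,
                    lr = 1e-3, patience = 20) {
  n <- nrow(inputs[[1]]$X)
  model <- model %||% build_model(n_nodes = n, n_features = ncol(inputs[[1]]$X),
                                  f1 = ncol(inputs[[1]]$X))
  classes <- sort(unique(labels))
  Y <- onehot(labels, classes = classes)
  preps <- gcn_prep_inputs(inputs, model)
  batch <- gcn_make_batch(preps, model)
  trace <- numeric(0)
  with_seed(seed, {
    params <- gcn_init_params(model)
    state <- adam_init(params)
    best <- list(loss = Inf, params = params)
    wait <- 0L
    for (ep in seq_len(epochs)) {
      dropmask <- NULL
      if (model$dropout > 0) {
        keep <- 1 - model$dropout
        dropmask <- matrix(rbinom(batch$S * model$fc, 1, keep) / keep,
                           batch$S, model$fc)
      }
      cache <- gcn_forward(params, batch, model, dropmask)
      loss <- cross_entropy(Y, cache$probs)
      trace <- c(trace, loss)
      if (loss < best$loss - 1e-6) {
        best <- list(loss = loss, params = params)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
      grads <- gcn_backward(params, cache, batch, model, Y,
                            dropmask = dropmask)
      upd <- adam_step(params, grads, state, lr)
      params <- upd$params
      state <- upd$state
    }
    # final-state evaluation so the best tracker sees the last update
    cache <- gcn_forward(params, batch, model)
    loss <- cross_entropy(Y, cache$probs)
    if (loss < best$loss) best <- list(loss = loss, params = params)
  })
  structure(list(model = model, params = best$params, loss = best$loss,
                 loss_trace = trace, classes = classes),
            class = "gcn_fit")
}

#' @export
print.gcn_fit <- function(x, ...) {
  cat(sprintf("<gcn_fit> %d epochs run, best training loss %.4f\n",
              length(x$loss_trace), x$loss))
  invisible(x)
}

#' Predict class probabilities for subjects
#'
#' @param object A `gcn_fit`.
#' @param inputs Subject inputs as in [gcn_fit()].
#' @param ... Unused.
#' @return N x M matrix of class probabilities (columns named by class).
#' @export
predict.gcn_fit <- function(object, inputs, ...) {
  preps <- gcn_prep_inputs(inputs, object$model)
  batch <- gcn_make_batch(preps, object$model)
  probs <- gcn_forward(object$params, batch, object$model)$probs
  colnames(probs) <- as.character(object$classes)
  probs
}

make_folds <- function(labels, folds, seed) {
  idx <- seq_along(labels)
  fold_of <- integer(length(labels))
  with_seed(seed, {
    for (cl in unique(labels)) {
      members <- sample(idx[labels == cl])
      fold_of[members] <- rep_len(seq_len(folds), length(members))
    }
  })
  for (f in seq_len(folds)) {
    if (length(unique(labels[fold_of != f])) < 2) {
      stop_state("fold %d leaves a training split without both classes", f)
    }
  }
  fold_of
}

#' Subject-level cross-validated training
#'
#' Splits subjects (never trials) into stratified folds, fits the model
#' on each training split and evaluates on the held-out subjects. Same
#' seed, same metrics.
#'
#' @inheritParams gcn_fit
#' @param folds Number of folds (default 5).
#' @return A `gcn_cv` object: `metrics` (per-fold tibble with ACC, AUC,
#'   sensitivity, specificity), `fold_of`, `fits`, `probs` (per-subject
#'   held-out probability of class 0), `labels`, `roc` (per-fold ROC
#'   points).
#' @export
gcn_train <- function(inputs, labels, model = NULL, folds = 5, seed = 1,
                      epochs = 200, lr = 1e-3, patience = 20) {
  if (length(labels) < 10) stop_invalid("need at least 10 subjects")
  fold_of <- make_folds(labels, folds, seed)
  metrics <- vector("list", folds)
  fits <- vector("list", folds)
  rocs <- vector("list", folds)
  score0 <- rep(NA_real_, length(labels))
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    fit <- gcn_fit(inputs[tr], labels[tr], model,
                   seed = derive_seed(seed, paste0("fold", f)),
                   epochs = epochs, lr = lr, patience = patience)
    probs <- predict.gcn_fit(fit, inputs[te])
    ev <- evaluate_metrics(labels[te], probs[, "0"])
    metrics[[f]] <- tibble::tibble(fold = f, acc = ev$acc, auc = ev$auc,
                                   sensitivity = ev$sensitivity,
                                   specificity = ev$specificity)
    rocs[[f]] <- dplyr::mutate(ev$roc, fold = f)
    fits[[f]] <- fit
    score0[te] <- probs[, "0"]
  }
  structure(list(metrics = dplyr::bind_rows(metrics), fold_of = fold_of,
                 fits = fits, probs = score0, labels = labels,
                 roc = dplyr::bind_rows(rocs)),
            class = "gcn_cv")
}

#' @export
print.gcn_cv <- function(x, ...) {
  m <- colMeans(x$metrics[, c("acc", "auc", "sensitivity", "specificity")])
  cat(sprintf("<gcn_cv> %d folds: ACC %.3f, AUC %.3f, sens %.3f, spec %.3f (means)\n",
              max(x$metrics$fold), m[1], m[2], m[3], m[4]))
  invisible(x)
}

#' Classification metrics from held-out scores
#'
#' Accuracy by thresholding at 0.5, AUC by the rank (Mann-Whitney)
#' statistic with midrank tie handling, sensitivity and specificity with
#' the patient group (label 0) as the positive class, and the full ROC
#' curve over score thresholds.
#'
#' @param labels True labels (0 = PD positive class, 1 = HC).
#' @param score_pd Predicted probability (or score) of class 0.
#' @return A list with `acc`, `auc`, `sensitivity`, `specificity`, and a
#'   `roc` tibble (`threshold`, `tpr`, `fpr`).
#' @export
evaluate_metrics <- function(labels, score_pd) {
  if (length(unique(labels)) < 2) {
    stop_invalid("AUC is undefined for a single-class test set")
  }
  pos <- labels == 0
  pred_pd <- score_pd >= 0.5
  acc <- mean(pred_pd == pos)
  r <- rank(score_pd)
  auc <- (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) /
    (sum(pos) * sum(!pos))
  sens <- mean(pred_pd[pos])
  spec <- mean(!pred_pd[!pos])
  th <- c(Inf, sort(unique(score_pd), decreasing = TRUE), -Inf)
  roc <- tibble::tibble(
    threshold = th,
    tpr = vapply(th, function(t) mean(score_pd[pos] >= t), 0),
    fpr = vapply(th, function(t) mean(score_pd[!pos] >= t), 0)
  )
  list(acc = acc, auc = auc, sensitivity = sens, specificity = spec,
       roc = roc)
}

#' Pairwise model comparison over folds
#'
#' Two-sided Mann-Whitney tests on per-fold metric vectors for every
#' model pair, Bonferroni-corrected over the number of pairs.
#'
#' @param metric_tables Named list of per-fold metric vectors (equal
#'   lengths), or a folds x models data frame / matrix.
#' @return A list with `p` (corrected, symmetric, unit diagonal) and
#'   `p_raw`.
#' @export
compare_models <- function(metric_tables) {
  if (is.data.frame(metric_tables) || is.matrix(metric_tables)) {
    metric_tables <- as.list(as.data.frame(metric_tables))
  }
  k <- length(metric_tables)
  if (k < 2) stop_invalid("need at least two models to compare")
  lens <- lengths(metric_tables)
  if (length(unique(lens)) != 1) stop_invalid("unequal fold counts")
  if (lens[1] < 3) warn("fewer than 3 folds: comparison is underpowered")
  nm <- names(metric_tables) %||% paste0("model", seq_len(k))
  p_raw <- matrix(1, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      p <- suppressWarnings(
        wilcox.test(metric_tables[[i]], metric_tables[[j]],
                    exact = NULL)$p.value)
      if (is.na(p)) p <- 1
      p_raw[i, j] <- p_raw[j, i] <- p
    }
  }
  n_pairs <- k * (k - 1) / 2
  p_adj <- pmin(p_raw * n_pairs, 1)
  diag(p_adj) <- 1
  list(p = p_adj, p_raw = p_raw)
}
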