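#' Guided backpropagation through a trained GCN
#'
#' Backpropagates the gradient of one class logit from the output layer
#' to the node features, overwriting the gradient at every ReLU so that
#' only units with positive forward activation *and* positive upstream
#' gradient pass it on. The returned input-layer gradient highlights the
#' channels driving the class decision without the noise of raw
#' gradients.
#'
#' @param fit A trained `gcn_fit`.
#' @param input One subject input: `list(X = node features, A = adjacency)`.
#' @param class_index Class to explain (1-based column of the softmax
#'   output).
#' @return A list with `input_gradient` (nodes x features) and the plain
#'   (non-guided) `gradient` for comparison.
#' @export
guided_backprop <- function(fit, input, class_index = 1) {
  if (any(!vapply(fit$params, function(p) all(is.finite(p)), TRUE))) {
    stop_state("model parameters are not finite; train the model first")
  }
  check_scalar_num(class_index, "class_index", lower = 1,
                   upper = fit$model$M)
  prep <- gcn_prep_subject(input$X, input$A, fit$model)
  batch <- gcn_make_batch(list(prep), fit$model)
  cache <- gcn_forward(fit$params, batch, fit$model)
  seed <- matrix(0, 1, fit$model$M)
  seed[1, class_index] <- 1
  g_guided <- gcn_backward(fit$params, cache, batch, fit$model,
                           seed_grad = seed, guided = TRUE,
                           input_grad = TRUE)$X
  g_plain <- gcn_backward(fit$params, cache, batch, fit$model,
                          seed_grad = seed, guided = FALSE,
                          input_grad = TRUE)$X
  list(input_gradient = g_guided, gradient = g_plain, probs = cache$probs)
}

#' Node and edge saliency from input gradients
#'
#' Node score: L2 norm of the node's input-gradient row. Edge score:
#' `|g_i| * |g_j| * A_ij`. Both are max-normalized to `[0, 1]`.
#'
#' @param gradient Input-layer gradient (nodes x features), e.g. from
#'   [guided_backprop()].
#' @param adjacency Adjacency matrix used for edge scores.
#' @param channels Optional channel labels.
#' @param top_nodes,top_edges Sizes of the top-k report (defaults 10/20).
#' @return A `saliency_map`: `node_scores` (named, in `[0, 1]`),
#'   `edge_scores` (matrix), `top_nodes`, `top_edges` (tibble).
#' @export
saliency_map <- function(gradient, adjacency, channels = NULL,
                         top_nodes = 10, top_edges = 20) {
  node <- sqrt(rowSums(gradient^2))
  if (max(node) == 0) {
    warn("all-zero gradients: saliency map is all zero")
  } else {
    node <- node / max(node)
  }
  channels <- channels %||% rownames(adjacency) %||%
    paste0("ch", seq_along(node))
  names(node) <- channels
  edge <- (node %o% node) * abs(adjacency)
  if (max(edge) > 0) edge <- edge / max(edge)
  dimnames(edge) <- list(channels, channels)
  ut <- which(upper.tri(edge), arr.ind = TRUE)
  ord <- order(edge[ut], decreasing = TRUE)
  k <- min(top_edges, nrow(ut))
  top_e <- tibble::tibble(
    from = channels[ut[ord[seq_len(k)], 1]],
    to = channels[ut[ord[seq_len(k)], 2]],
    score = edge[ut[ord[seq_len(k)], , drop = FALSE]]
  )
  structure(list(
    node_scores = node, edge_scores = edge,
    top_nodes = names(sort(node, decreasing = TRUE))[seq_len(min(top_nodes,
                                                                 length(node)))],
    top_edges = top_e
  ), class = "saliency_map")
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %d nodes; top: %s\n", length(x$node_scores),
              paste(head(x$top_nodes, 5), collapse = ", ")))
  invisible(x)
}

#' Cohort-level saliency
#'
#' Computes guided-backprop saliency for each subject's trial-averaged
#' input, keeps the correctly classified subjects of the targeted class,
#' and averages their node-gradient norms into one map.
#'
#' @param fit A trained `gcn_fit`.
#' @param inputs Per-subject inputs (as in [gcn_fit()]).
#' @param labels True labels.
#' @param class_label Class to explain (default 0, the patient group).
#' @param adjacency Adjacency for edge scores (default: first subject's).
#' @param perms Optional list of per-subject channel permutation matrices
#'   (from the alignment stage); when given, each subject's gradient is
#'   mapped back to the original montage channel order before averaging.
#' @param channels Optional channel labels for the map.
#' @return A `saliency_map` (averaged), or all-zero map if no subject of
#'   the class is correctly classified.
#' @export
cohort_saliency <- function(fit, inputs, labels, class_label = 0,
                            adjacency = NULL, perms = NULL,
                            channels = NULL) {
  ci <- match(class_label, fit$classes)
  if (is.na(ci)) stop_invalid("class %s not in the model", class_label)
  probs <- predict.gcn_fit(fit, inputs)
  correct <- which(labels == class_label &
                     fit$classes[max.col(probs)] == labels)
  acc_node <- 0
  n_used <- 0L
  for (s in correct) {
    g <- guided_backprop(fit, inputs[[s]], ci)$input_gradient
    ns <- sqrt(rowSums(g^2))
    if (!is.null(perms)) {
      # model node i holds original channel perm[i]; undo the reordering
      pv <- permutation_vector(perms[[s]])
      ns[pv] <- ns
    }
    acc_node <- acc_node + ns
    n_used <- n_used + 1L
  }
  adjacency <- adjacency %||% inputs[[1]]$A
  if (n_used == 0L) {
    warn("no correctly classified subject in the target class")
    return(saliency_map(matrix(0, nrow(adjacency), 1), adjacency,
                        channels = channels))
  }
  g_mat <- matrix(acc_node / n_used, ncol = 1)
  saliency_map(g_mat, adjacency, channels = channels)
}

#' Tidy a saliency map
#'
#' @param x A `saliency_map`.
#' @param ... Unused.
#' @return Tibble with `channel`, `score`, ranked.
#' @method tidy saliency_map
#' @export
tidy.saliency_map <- function(x, ...) {
  tibble::tibble(channel = names(x$node_scores),
                 score = unname(x$node_scores)) |>
    dplyr::arrange(dplyr::desc(.data$score))
}

#' Topographic saliency plot
#'
#' Projects electrode positions to 2-D (azimuthal) and sizes/colors nodes
#' by saliency score.
#'
#' @param object A `saliency_map`.
#' @param montage The `eeg_montage` (for positions).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot saliency_map
#' @export
autoplot.saliency_map <- function(object, montage, ...) {
  pos <- montage_positions(montage)
  theta <- acos(pmin(pmax(pos[, 3], -1), 1))
  r2 <- theta / (pi / 2)
  az <- atan2(pos[, 1], pos[, 2])
  df <- tibble::tibble(
    channel = montage$label,
    px = r2 * sin(az), py = r2 * cos(az),
    score = object$node_scores[montage$label]
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$px, .data$py)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$score,
                                     color = .data$score)) +
    ggplot2::scale_color_gradient(low = "grey80", high = "red3") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, color = "saliency",
                  size = "saliency") +
    ggplot2::theme_void()
}
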