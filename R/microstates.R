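#' Global field power
#'
#' Per-sample standard deviation of the topography across channels
#' (population form, dividing by the channel count).
#'
#' @param erp An `eeg_erp` or channels x samples matrix.
#' @return Numeric vector, one nonnegative value per sample.
#' @export
gfp <- function(erp) {
  m <- if (inherits(erp, "eeg_erp")) erp$data else erp
  if (nrow(m) < 2) stop_invalid("GFP needs at least 2 channels")
  mu <- colMeans(m)
  sqrt(colMeans(sweep(m, 2, mu)^2))
}

gfp_peaks <- function(g) {
  n <- length(g)
  which(g > c(-Inf, g[-n]) & g >= c(g[-1], -Inf))
}

#' Microstate template clustering with Krzanowski-Lai selection
#'
#' Collects the unit-normalized topographies at GFP local maxima of the
#' supplied ERPs, clusters them with (polarity-sensitive) k-means for
#' each candidate k, and selects the number of microstate classes by the
#' Krzanowski-Lai criterion
#' `KL(k) = |DIFF(k)| / |DIFF(k+1)|` with
#' `DIFF(k) = (k-1)^{2/p} W_{k-1} - k^{2/p} W_k`, where `W_k` is the
#' total within-cluster dispersion and `p` the number of channels.
#'
#' @param erps One ERP or a list of ERPs (`eeg_erp` or matrices, same
#'   channels).
#' @param k_range Candidate class counts (default 2:10, within [2, 10]).
#' @param n_init k-means restarts (default 50).
#' @param seed Integer seed.
#' @return An `erp_microstates` object: `templates` (unit-norm channel x
#'   k matrix for the chosen k), `templates_by_k`, `kl_curve` (tibble),
#'   `chosen_k`, `gfp` (per ERP), `peak_maps`.
#' @export
cluster_topographies <- function(erps, k_range = 2:10, n_init = 50,
                                 seed = 1) {
  if (!is.list(erps)) erps <- list(erps)
  if (any(k_range < 2) || any(k_range > 10)) {
    stop_invalid("k_range must lie within [2, 10]")
  }
  mats <- lapply(erps, function(e) if (inherits(e, "eeg_erp")) e$data else e)
  gfps <- lapply(mats, gfp)
  maps <- do.call(cbind, Map(function(m, g) m[, gfp_peaks(g), drop = FALSE],
                             mats, gfps))
  maps <- sweep(maps, 2, sqrt(colSums(maps^2)), "/")
  maps <- maps[, is.finite(colSums(maps)), drop = FALSE]
  k_range <- sort(unique(as.integer(k_range)))
  if (ncol(maps) <= max(k_range) + 1) {
    warn("fewer GFP peak maps than requested clusters; shrinking k_range")
    k_range <- k_range[k_range <= ncol(maps) - 2]
    if (length(k_range) == 0) stop_state("not enough GFP peaks to cluster")
  }
  p <- nrow(maps)
  # dispersion is needed one k beyond each end for the KL differences
  ks <- (min(k_range) - 1):(max(k_range) + 1)
  fits <- list()
  Wk <- numeric(length(ks))
  with_seed(seed, {
    for (i in seq_along(ks)) {
      k <- ks[i]
      if (k == 1) {
        ctr <- rowMeans(maps)
        Wk[i] <- sum((maps - ctr)^2)
      } else {
        km <- kmeans(t(maps), centers = k, nstart = n_init,
                     iter.max = 100)
        Wk[i] <- km$tot.withinss
        fits[[as.character(k)]] <- km
      }
    }
  })
  diffs <- vapply(seq_along(ks)[-1], function(i) {
    (ks[i] - 1)^(2 / p) * Wk[i - 1] - ks[i]^(2 / p) * Wk[i]
  }, 0)
  names(diffs) <- ks[-1]
  kl <- vapply(as.character(k_range), function(kc) {
    k <- as.integer(kc)
    abs(diffs[as.character(k)]) / max(abs(diffs[as.character(k + 1)]), 1e-12)
  }, 0)
  chosen_k <- k_range[which.max(kl)]
  norm_templates <- function(km) {
    tpl <- t(km$centers)
    sweep(tpl, 2, pmax(sqrt(colSums(tpl^2)), 1e-12), "/")
  }
  structure(list(
    templates = norm_templates(fits[[as.character(chosen_k)]]),
    templates_by_k = lapply(fits, norm_templates),
    kl_curve = tibble::tibble(k = k_range, kl = unname(kl)),
    chosen_k = chosen_k,
    gfp = gfps, peak_maps = maps
  ), class = "erp_microstates")
}

#' @export
print.erp_microstates <- function(x, ...) {
  cat(sprintf("<erp_microstates> chosen k = %d from {%s} (%d GFP peak maps)\n",
              x$chosen_k, paste(x$kl_curve$k, collapse = ", "),
              ncol(x$peak_maps)))
  invisible(x)
}

#' Back-fit microstate templates onto an ERP
#'
#' Labels every sample with the template of maximal spatial (Pearson)
#' correlation; runs shorter than `min_duration_ms` are merged into the
#' neighboring state with the stronger boundary correlation. Labels are
#' invariant to global amplitude scaling of the ERP.
#'
#' @param erp An `eeg_erp` or channels x samples matrix.
#' @param templates Unit-norm channel x k template matrix.
#' @param min_duration_ms Minimal accepted run length (default 10 ms).
#' @param fs Sampling rate (taken from the ERP if available).
#' @return A list with `labels` (per sample), `coverage` (tibble of per-
#'   state time coverage in ms and fraction), `correlation` (k x samples).
#' @export
segment_microstates <- function(erp, templates, min_duration_ms = 10,
                                fs = NULL) {
  m <- if (inherits(erp, "eeg_erp")) erp$data else erp
  fs <- fs %||% (if (inherits(erp, "eeg_erp")) erp$fs else
    stop_invalid("`fs` required for matrix input"))
  corr <- suppressWarnings(cor(templates, m))
  corr[!is.finite(corr)] <- 0
  labels <- apply(corr, 2, which.max)
  min_len <- max(1L, round(min_duration_ms * fs / 1000))
  labels <- merge_short_runs(labels, corr, min_len)
  r <- rle(labels)
  dt <- 1000 / fs
  cov <- tibble::tibble(state = sort(unique(labels)))
  cov$time_ms <- vapply(cov$state, function(s) sum(labels == s) * dt, 0)
  cov$fraction <- cov$time_ms / (length(labels) * dt)
  list(labels = labels, coverage = cov, correlation = corr)
}

merge_short_runs <- function(labels, corr, min_len) {
  repeat {
    r <- rle(labels)
    short <- which(r$lengths < min_len)
    # never merge away the longest-run states at the sequence edges
    if (length(short) == 0 || length(r$lengths) == 1) return(labels)
    i <- short[which.min(r$lengths[short])]
    start <- sum(r$lengths[seq_len(i - 1)]) + 1L
    idx <- start:(start + r$lengths[i] - 1L)
    left <- if (i > 1) r$values[i - 1] else NA
    right <- if (i < length(r$values)) r$values[i + 1] else NA
    cand <- stats::na.omit(c(left, right))
    sc <- vapply(cand, function(s) mean(corr[s, idx]), 0)
    labels[idx] <- cand[which.max(sc)]
  }
}

#' Microstate transition summary
#'
#' Lists every label change as `(from, to, time_ms)` in temporal order.
#'
#' @param labels Per-sample state labels from [segment_microstates()].
#' @param times_ms Per-sample times (default: sample index).
#' @return Tibble with `from`, `to`, `time_ms`.
#' @export
transition_summary <- function(labels, times_ms = seq_along(labels)) {
  ch <- which(diff(labels) != 0)
  tibble::tibble(from = labels[ch], to = labels[ch + 1],
                 time_ms = times_ms[ch + 1])
}

#' Group-level microstate analysis
#'
#' Clusters the two group-grand-average ERPs jointly, then back-fits the
#' chosen templates to each group's grand average.
#'
#' @param erp_group0,erp_group1 Grand-average ERPs (`eeg_erp`).
#' @param k_range,n_init,seed Passed to [cluster_topographies()].
#' @param min_duration_ms Passed to [segment_microstates()].
#' @return A `microstate_analysis` list: `clustering`
#'   (`erp_microstates`), `segmentation` (per group), `transitions`
#'   (per group).
#' @export
microstate_analysis <- function(erp_group0, erp_group1, k_range = 2:10,
                                n_init = 50, seed = 1,
                                min_duration_ms = 10) {
  cl <- cluster_topographies(list(erp_group0, erp_group1), k_range,
                             n_init, seed)
  segs <- lapply(list(group0 = erp_group0, group1 = erp_group1),
                 function(e) segment_microstates(e, cl$templates,
                                                 min_duration_ms))
  trans <- lapply(names(segs), function(nm) {
    e <- if (nm == "group0") erp_group0 else erp_group1
    transition_summary(segs[[nm]]$labels, epoch_times(e))
  })
  names(trans) <- names(segs)
  structure(list(clustering = cl, segmentation = segs,
                 transitions = trans),
            class = "microstate_analysis")
}

#' Tidy microstate results
#'
#' @param x An `erp_microstates`.
#' @param ... Unused.
#' @return The Krzanowski-Lai curve as a tibble with the chosen k
#'   flagged.
#' @method tidy erp_microstates
#' @export
tidy.erp_microstates <- function(x, ...) {
  dplyr::mutate(x$kl_curve, chosen = .data$k == x$chosen_k)
}

#' @rdname tidy.erp_microstates
#' @method glance erp_microstates
#' @export
glance.erp_microstates <- function(x, ...) {
  tibble::tibble(chosen_k = x$chosen_k,
                 n_peak_maps = ncol(x$peak_maps),
                 kl_max = max(x$kl_curve$kl))
}

#' Plot the Krzanowski-Lai curve
#'
#' @param object An `erp_microstates`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot erp_microstates
#' @export
autoplot.erp_microstates <- function(object, ...) {
  df <- tidy.erp_microstates(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$k, .data$kl)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$chosen), size = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "red3"),
                                guide = "none") +
    ggplot2::labs(x = "number of microstate classes k",
                  y = "Krzanowski-Lai criterion") +
    ggplot2::theme_minimal()
}
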