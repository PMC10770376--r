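#' Consecutive-pair tie-break counts
#'
#' Scans consecutive label pairs `(y_t, y_{t+1})` of a binary sequence:
#' an equal pair increments the matching label's counter, an unequal pair
#' cancels and increments nothing. For
#' `{0,1,1,0,1,0,0,1,1,0}` this gives `BM0 = 1`, `BM1 = 2`.
#'
#' @param labels Binary (0/1) vector of length >= 2.
#' @return Named integer vector `c(BM0, BM1)`.
#' @export
bm_counts <- function(labels) {
  if (length(labels) < 2) stop_invalid("need at least 2 labels")
  if (!all(labels %in% c(0, 1))) stop_invalid("labels must be 0 or 1")
  a <- labels[-length(labels)]
  b <- labels[-1]
  eq <- a == b
  c(BM0 = sum(eq & a == 0), BM1 = sum(eq & a == 1))
}

#' Hard vote over 10 trial labels
#'
#' Majority decides: more 0s classifies the subject as PD, more 1s as
#' healthy. On a 5-5 tie the consecutive-pair counts of [bm_counts()]
#' break the tie (larger count wins); if those tie as well (e.g. a
#' strictly alternating draw) the decision defaults to healthy, the
#' benign label, and the double tie is flagged.
#'
#' @param labels Exactly 10 binary trial labels, in draw order.
#' @return A `vote_outcome`: `N0`, `N1`, `BM0`, `BM1` (NA unless tied),
#'   `decision` (`"PD"` or `"healthy"`), `path` (`"majority"` or
#'   `"boyer_moore"`), `double_tie`.
#' @export
vote_once <- function(labels) {
  if (length(labels) != 10) stop_invalid("vote_once expects exactly 10 labels")
  if (!all(labels %in% c(0, 1))) stop_invalid("labels must be 0 or 1")
  n0 <- sum(labels == 0)
  n1 <- 10L - n0
  bm <- c(BM0 = NA_integer_, BM1 = NA_integer_)
  double_tie <- FALSE
  if (n0 > n1) {
    decision <- "PD"
    path <- "majority"
  } else if (n1 > n0) {
    decision <- "healthy"
    path <- "majority"
  } else {
    bm <- bm_counts(labels)
    path <- "boyer_moore"
    if (bm["BM0"] > bm["BM1"]) {
      decision <- "PD"
    } else if (bm["BM1"] > bm["BM0"]) {
      decision <- "healthy"
    } else {
      decision <- "healthy"
      double_tie <- TRUE
    }
  }
  structure(list(N0 = n0, N1 = n1, BM0 = bm[["BM0"]], BM1 = bm[["BM1"]],
                 decision = decision, path = path,
                 double_tie = double_tie),
            class = "vote_outcome")
}

#' @export
print.vote_outcome <- function(x, ...) {
  cat(sprintf("<vote_outcome> N0 = %d, N1 = %d -> %s (%s%s)\n",
              x$N0, x$N1, x$decision, x$path,
              if (x$double_tie) ", double tie" else ""))
  invisible(x)
}

#' Posterior verification by repeated trial voting
#'
#' For each repetition, draws `draw` trial labels per subject without
#' replacement, applies [vote_once()], and scores the voted decisions
#' against the true groups; reports the mean and variance of the accuracy
#' over `repeats` repetitions.
#'
#' @param trial_labels List (one element per subject) of per-trial
#'   predicted labels (0/1).
#' @param true_groups True group per subject (0 = PD, 1 = HC).
#' @param repeats Number of repetitions (default 100).
#' @param draw Trials drawn per subject (default 10).
#' @param seed Integer seed.
#' @return A `vote_summary`: `mean`, `variance`, `accuracies` (per
#'   repetition), `n_double_ties`.
#' @export
posterior_verify <- function(trial_labels, true_groups, repeats = 100,
                             draw = 10, seed = 1) {
  if (any(lengths(trial_labels) < draw)) {
    stop_invalid("every subject needs at least %d trial labels", draw)
  }
  truth <- ifelse(true_groups == 0, "PD", "healthy")
  acc <- numeric(repeats)
  ties <- 0L
  with_seed(seed, {
    for (r in seq_len(repeats)) {
      dec <- vapply(trial_labels, function(y) {
        v <- vote_once(sample(y, draw))
        if (v$double_tie) ties <<- ties + 1L
        v$decision
      }, "")
      acc[r] <- mean(dec == truth)
    }
  })
  structure(list(mean = mean(acc), variance = var_pop(acc),
                 accuracies = acc, n_double_ties = ties,
                 repeats = repeats, draw = draw),
            class = "vote_summary")
}

var_pop <- function(x) mean((x - mean(x))^2)

#' @export
print.vote_summary <- function(x, ...) {
  cat(sprintf("<vote_summary> %d repetitions of %d-trial votes: mean accuracy %.3f, variance %.5f\n",
              x$repeats, x$draw, x$mean, x$variance))
  invisible(x)
}

#' @rdname posterior_verify
#' @param x A `vote_summary`.
#' @param ... Unused.
#' @method tidy vote_summary
#' @export
tidy.vote_summary <- function(x, ...) {
  tibble::tibble(repetition = seq_along(x$accuracies),
                 accuracy = x$accuracies)
}

#' @rdname posterior_verify
#' @method glance vote_summary
#' @export
glance.vote_summary <- function(x, ...) {
  tibble::tibble(mean_accuracy = x$mean, variance = x$variance,
                 repeats = x$repeats, draw = x$draw,
                 double_ties = x$n_double_ties)
}
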