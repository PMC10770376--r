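#' Zero-phase band-pass filtering
#'
#' Filters every trial and channel with a Butterworth band-pass applied
#' forward and backward (zero phase, no group delay). The default band
#' (1-20 Hz) is the standard ERP analysis band; [narrowband()] with
#' 4-12 Hz feeds the connectivity stage.
#'
#' @param x An `eeg_epochs` object, or a channels x samples matrix of
#'   continuous data (then `fs` is required).
#' @param low,high Band edges in Hz; `0 < low < high < fs/2`.
#' @param fs Sampling rate, only for matrix input.
#' @param order Butterworth order per band edge (default 2, i.e. a
#'   4th-order band-pass).
#' @return Same type as `x`, filtered.
#' @export
bandpass <- function(x, low = 1, high = 20, fs = NULL, order = 2L) {
  if (inherits(x, "eeg_epochs")) fs <- x$fs
  if (is.null(fs)) stop_invalid("`fs` is required for matrix input")
  check_scalar_num(low, "low", lower = 0, closed_lower = FALSE)
  check_scalar_num(high, "high")
  if (low >= high || high >= fs / 2) {
    stop_invalid("band (%g, %g) Hz must satisfy 0 < low < high < fs/2 = %g",
                 low, high, fs / 2)
  }
  bt <- butter_band(low, high, fs, order)
  if (inherits(x, "eeg_epochs")) {
    x$data <- filter_epoch_array(x$data, bt$b, bt$a)
    x
  } else {
    t(filtfilt_mat(bt$b, bt$a, t(x)))
  }
}

#' @rdname bandpass
#' @details `narrowband()` defaults to a steeper order-3 design: the
#'   connectivity band demands a flatter passband (re-filtering changes
#'   the signal by less than 0.1%) while keeping out-of-band components
#'   attenuated by more than 20 dB.
#' @export
narrowband <- function(x, low = 4, high = 12, fs = NULL, order = 3L) {
  bandpass(x, low, high, fs = fs, order = order)
}

#' Segment continuous data into epochs
#'
#' Cuts a window around each event onset. Windows are half-open
#' `[start, end)` in ms relative to the onset sample; at 1 kHz with the
#' default window of -200..+500 ms each epoch has 700 samples. Onsets whose
#' window would leave the recording are dropped with a warning; the number
#' dropped is recorded in the `n_dropped` attribute.
#'
#' @param continuous Channels x samples numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param onsets Integer sample indices of the events (1-based).
#' @param window_ms Epoch window, ms pair (default `c(-200, 500)`).
#' @param channels Optional channel labels.
#' @param subject_id,group Metadata carried into the result.
#' @return An `eeg_epochs` object; trials ordered by onset.
#' @export
epoch_data <- function(continuous, fs, onsets, window_ms = c(-200, 500),
                       channels = NULL, subject_id = NA_character_,
                       group = NA_integer_) {
  stopifnot(is.matrix(continuous))
  onsets <- sort(as.integer(onsets))
  off <- round(window_ms * fs / 1000)
  len <- off[2] - off[1]
  first <- onsets + off[1]
  ok <- first >= 1L & (first + len - 1L) <= ncol(continuous)
  if (any(!ok)) {
    warn(sprintf("dropped %d of %d onsets with out-of-bounds windows",
                 sum(!ok), length(onsets)))
  }
  keep <- onsets[ok]
  data <- array(0, dim = c(length(keep), nrow(continuous), len))
  for (i in seq_along(keep)) {
    idx <- (keep[i] + off[1]):(keep[i] + off[2] - 1L)
    data[i, , ] <- continuous[, idx]
  }
  channels <- channels %||% rownames(continuous) %||%
    paste0("ch", seq_len(nrow(continuous)))
  out <- eeg_epochs(data, fs, window_ms, channels, subject_id, group)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Peak-to-peak artifact rejection
#'
#' A trial is dropped iff any channel's peak-to-peak amplitude exceeds the
#' threshold. With `p2p_threshold = NULL` the threshold defaults to 6 times
#' the median (across trials) of the per-trial maximum absolute amplitude,
#' a robust scale that passes intact physiological trials while catching
#' high-amplitude steps and drifts.
#'
#' @param epochs An `eeg_epochs` object.
#' @param p2p_threshold Positive peak-to-peak threshold, or `NULL`.
#' @return A list with `epochs` (retained trials) and `keep` (logical mask
#'   over the input trials).
#' @export
reject_artifacts <- function(epochs, p2p_threshold = NULL) {
  mx <- slab_reduce(epochs$data, pmax)
  mn <- slab_reduce(epochs$data, pmin)
  amp <- apply(pmax(abs(mx), abs(mn)), 1, max)
  if (is.null(p2p_threshold)) p2p_threshold <- 6 * median(amp)
  check_scalar_num(p2p_threshold, "p2p_threshold", lower = 0,
                   closed_lower = FALSE)
  p2p <- apply(mx - mn, 1, max)
  keep <- p2p <= p2p_threshold
  if (!any(keep)) {
    stop_state("artifact rejection removed every trial (threshold %g)",
               p2p_threshold)
  }
  epochs$data <- epochs$data[keep, , , drop = FALSE]
  list(epochs = epochs, keep = keep)
}

#' Re-reference to the mastoid average
#'
#' Subtracts, at every sample, the mean of the two mastoid channels from
#' every channel.
#'
#' @param epochs An `eeg_epochs` object.
#' @param montage The bound `eeg_montage` (provides the mastoid labels).
#' @return The re-referenced `eeg_epochs`.
#' @export
rereference_mastoid <- function(epochs, montage) {
  ml <- mastoid_labels(montage)
  idx <- match(ml, epochs$channels)
  if (anyNA(idx)) {
    stop_invalid("mastoid channel(s) %s not present in the data",
                 paste(ml[is.na(idx)], collapse = ", "))
  }
  ref <- (epochs$data[, idx[1], , drop = FALSE] +
            epochs$data[, idx[2], , drop = FALSE]) / 2
  epochs$data <- epochs$data - ref[, rep(1, dim(epochs$data)[2]), ,
                                   drop = FALSE]
  epochs
}

#' Baseline correction
#'
#' Per trial and channel, subtracts the mean over the baseline window
#' (default the full pre-stimulus segment, -200..0 ms, half-open).
#'
#' @param epochs An `eeg_epochs` object.
#' @param baseline_window_ms Window in ms, must lie inside the epoch window.
#' @return The corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, baseline_window_ms = c(-200, 0)) {
  tm <- epoch_times(epochs)
  sel <- tm >= baseline_window_ms[1] & tm < baseline_window_ms[2]
  if (!any(sel)) stop_invalid("baseline window contains no samples")
  if (baseline_window_ms[1] < epochs$window_ms[1] ||
      baseline_window_ms[2] > epochs$window_ms[2]) {
    stop_invalid("baseline window must lie inside the epoch window")
  }
  bl <- rowSums(epochs$data[, , sel, drop = FALSE], dims = 2) / sum(sel)
  epochs$data <- epochs$data - as.vector(bl)  # recycles over samples
  epochs
}

# Reduce a trials x channels x samples array over samples with a binary
# vectorized reducer (pmax/pmin), one C-level pass per sample.
slab_reduce <- function(a, fn) {
  out <- a[, , 1]
  for (s in seq_len(dim(a)[3])[-1]) out <- fn(out, a[, , s])
  out
}

#' Trial average
#'
#' Arithmetic mean across trials.
#'
#' @param epochs An `eeg_epochs` object with at least one trial.
#' @return An [eeg_erp()] object.
#' @export
average_erp <- function(epochs) {
  if (n_trials(epochs) < 1L) stop_state("no trials to average")
  erp <- colMeans(epochs$data)               # over trials
  eeg_erp(erp, epochs$fs, epochs$window_ms, epochs$channels,
          n_trials_used = n_trials(epochs),
          subject_id = epochs$subject_id, group = epochs$group)
}

#' Standard ERP preprocessing chain for one subject
#'
#' Fixed order: band filter, artifact rejection, mastoid re-reference,
#' baseline correction, trial average. (Epoching precedes this chain for
#' continuous input; simulated cohorts are already epoched.)
#'
#' @param epochs An `eeg_epochs` object.
#' @param montage The bound `eeg_montage`.
#' @param band Filter band in Hz (default 1-20).
#' @param baseline Baseline window in ms (default -200..0).
#' @param p2p_threshold Artifact threshold, see [reject_artifacts()].
#' @return A list with `epochs` (clean, corrected trials), `erp`, and
#'   `keep` (the artifact mask over input trials).
#' @export
preprocess_epochs <- function(epochs, montage, band = c(1, 20),
                              baseline = c(-200, 0), p2p_threshold = NULL) {
  x <- bandpass(epochs, band[1], band[2])
  rej <- reject_artifacts(x, p2p_threshold)
  x <- rereference_mastoid(rej$epochs, montage)
  x <- baseline_correct(x, baseline)
  list(epochs = x, erp = average_erp(x), keep = rej$keep)
}
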