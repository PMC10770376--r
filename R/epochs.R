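#' Epoched EEG container
#'
#' An `eeg_epochs` object holds a trials x channels x samples numeric array
#' together with its sampling rate, epoch window (ms relative to the
#' perturbation onset; half-open `[start, end)`), the channel labels of the
#' montage it is bound to, and the subject's identity and group label
#' (0 = patient/PD, 1 = healthy control).
#'
#' @param data Numeric array, trials x channels x samples.
#' @param fs Sampling rate in Hz.
#' @param window_ms Length-2 numeric, epoch start/end in ms (start < 0 < end).
#' @param channels Character vector of channel labels (length = dim 2).
#' @param subject_id Subject identifier.
#' @param group Group label, 0 or 1 (may be `NA` for unlabeled data).
#' @return An `eeg_epochs` object.
#' @export
eeg_epochs <- function(data, fs, window_ms, channels,
                       subject_id = NA_character_, group = NA_integer_) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_invalid("`data` must be a trials x channels x samples array")
  }
  if (anyNA(data)) stop_invalid("epoch data must not contain missing values")
  check_scalar_num(fs, "fs", lower = 0, closed_lower = FALSE)
  if (length(window_ms) != 2L || window_ms[1] >= window_ms[2]) {
    stop_invalid("`window_ms` must be an increasing (start, end) pair")
  }
  n_expected <- round(diff(window_ms) * fs / 1000)
  if (dim(data)[3] != n_expected) {
    stop_invalid("window of %g ms at %g Hz implies %d samples, data has %d",
                 diff(window_ms), fs, n_expected, dim(data)[3])
  }
  if (length(channels) != dim(data)[2]) {
    stop_invalid("%d channel labels for %d channels",
                 length(channels), dim(data)[2])
  }
  structure(
    list(data = data, fs = fs, window_ms = as.numeric(window_ms),
         channels = as.character(channels),
         subject_id = subject_id, group = group),
    class = "eeg_epochs"
  )
}

n_trials <- function(x) dim(x$data)[1]
n_channels_of <- function(x) dim(x$data)[2]
n_samples <- function(x) dim(x$data)[3]

#' Sample times of an epoch window
#'
#' Times in ms for each sample; sample 1 sits at `window_ms[1]`, the window
#' is half-open so `window_ms[2]` itself is not included.
#'
#' @param x An `eeg_epochs` or `eeg_erp` object.
#' @return Numeric vector of length `n_samples`.
#' @export
epoch_times <- function(x) {
  dt <- 1000 / x$fs
  x$window_ms[1] + dt * (seq_len(dim_samples(x)) - 1)
}

dim_samples <- function(x) {
  if (inherits(x, "eeg_epochs")) dim(x$data)[3] else ncol(x$data)
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf(
    "<eeg_epochs> subject %s (group %s): %d trials x %d channels x %d samples @ %g Hz, [%g, %g) ms\n",
    x$subject_id, x$group, n_trials(x), n_channels_of(x), n_samples(x),
    x$fs, x$window_ms[1], x$window_ms[2]))
  invisible(x)
}

#' Trial-averaged ERP container
#'
#' A channels x samples matrix with the provenance of its average.
#'
#' @param data Channels x samples numeric matrix.
#' @param fs,window_ms,channels,subject_id,group As in [eeg_epochs()].
#' @param n_trials_used Number of trials entering the average.
#' @return An `eeg_erp` object.
#' @export
eeg_erp <- function(data, fs, window_ms, channels, n_trials_used,
                    subject_id = NA_character_, group = NA_integer_) {
  stopifnot(is.matrix(data), nrow(data) == length(channels))
  structure(
    list(data = data, fs = fs, window_ms = as.numeric(window_ms),
         channels = as.character(channels), n_trials_used = n_trials_used,
         subject_id = subject_id, group = group),
    class = "eeg_erp"
  )
}

#' @export
print.eeg_erp <- function(x, ...) {
  cat(sprintf("<eeg_erp> subject %s (group %s): %d channels x %d samples, average of %d trials\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data),
              x$n_trials_used))
  invisible(x)
}

#' Tidy an ERP into long format
#'
#' @param x An `eeg_erp`.
#' @param ... Unused.
#' @return A tibble with columns `channel`, `time_ms`, `amplitude`.
#' @method tidy eeg_erp
#' @export
tidy.eeg_erp <- function(x, ...) {
  t_ms <- epoch_times(x)
  tibble::tibble(
    channel = rep(x$channels, times = length(t_ms)),
    time_ms = rep(t_ms, each = length(x$channels)),
    amplitude = as.vector(x$data)
  )
}

#' Butterfly plot of an ERP
#'
#' One line per channel over time; the classic "butterfly" view.
#'
#' @param object An `eeg_erp`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot eeg_erp
#' @export
autoplot.eeg_erp <- function(object, ...) {
  df <- tidy.eeg_erp(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$amplitude,
                                   group = .data$channel)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time (ms)", y = "amplitude (a.u.)") +
    ggplot2::theme_minimal()
}
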