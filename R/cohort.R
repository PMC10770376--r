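#' Configuration for a synthetic voice-ERP cohort
#'
#' Bundles and validates the generator parameters. Defaults describe the
#' emulated study conditions: two groups of subjects, 100 trials per
#' subject, 64-channel recordings at 1 kHz epoched -200..+500 ms around a
#' pitch-perturbation onset (700 samples), with a P1-N1-P2 ERP morphology
#' and a group-enhanced P2 over left fronto-temporal electrodes.
#'
#' `p2_effect` multiplies the P2 amplitude of group 0 (patients); 1.0 is
#' the null condition (groups identically distributed), larger values give
#' a stronger group effect. `noise_scale` scales every stochastic component
#' (1/f background, alpha oscillation, sensor noise, trial- and
#' subject-level jitter), so `noise_scale = 0` produces the deterministic
#' noiseless morphology.
#'
#' @param n_subjects_per_group Subjects per group.
#' @param n_trials Trials per subject (default 100).
#' @param fs Sampling rate in Hz (default 1000).
#' @param epoch_window Epoch window in ms (default `c(-200, 500)`).
#' @param p2_latency P2 peak latency in ms (default 260).
#' @param p2_effect P2 amplitude multiplier for group 0 (default 2.5).
#' @param noise_scale Noise level in the generator's arbitrary units
#'   (default 1).
#' @param artifact_rate Probability that a trial receives a high-amplitude
#'   artifact (default 0.05).
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects_per_group = 10, n_trials = 100,
                          fs = 1000, epoch_window = c(-200, 500),
                          p2_latency = 260, p2_effect = 2.5,
                          noise_scale = 1, artifact_rate = 0.05,
                          seed = 1) {
  check_scalar_num(n_subjects_per_group, "n_subjects_per_group", lower = 1)
  check_scalar_num(n_trials, "n_trials", lower = 1)
  check_scalar_num(fs, "fs", lower = 0, closed_lower = FALSE)
  check_scalar_num(p2_effect, "p2_effect", lower = 0, closed_lower = FALSE)
  check_scalar_num(noise_scale, "noise_scale", lower = 0)
  check_scalar_num(artifact_rate, "artifact_rate", lower = 0, upper = 1,
                   closed_upper = FALSE)
  check_scalar_num(seed, "seed")
  if (length(epoch_window) != 2L || epoch_window[1] >= 0 ||
      epoch_window[2] <= 0) {
    stop_invalid("epoch_window must straddle 0 (start < 0 < end)")
  }
  if (p2_latency <= 0 || p2_latency >= epoch_window[2]) {
    stop_invalid("p2_latency must fall inside the post-onset window")
  }
  structure(list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    n_trials = as.integer(n_trials), fs = fs,
    epoch_window = as.numeric(epoch_window),
    p2_latency = p2_latency, p2_effect = p2_effect,
    noise_scale = noise_scale, artifact_rate = artifact_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Spatial loading of a component: Gaussian in angular distance from a
# focus direction on the electrode sphere.
spatial_gaussian <- function(pos, center, width) {
  center <- center / sqrt(sum(center^2))
  ang <- acos(pmin(1, pmax(-1, pos %*% center)))
  exp(-ang^2 / (2 * width^2))
}

temporal_gaussian <- function(t_ms, mu, sigma) {
  exp(-(t_ms - mu)^2 / (2 * sigma^2))
}

# ERP component table of the generator. Amplitudes are in the generator's
# arbitrary (z-like) units; latencies follow standard vocalization-feedback
# ERP morphology, with P2 weighted toward left fronto-temporal channels.
cohort_components <- function(montage, p2_latency) {
  pos <- montage_positions(montage)
  ft <- montage_left_frontotemporal(montage)
  list(
    P1 = list(mu = 80, sigma = 20, amp = 1.0,
              topo = drop(spatial_gaussian(pos, c(0, 0.25, 0.97), 0.7))),
    N1 = list(mu = 150, sigma = 30, amp = -1.6,
              topo = drop(spatial_gaussian(pos, c(0, 0.4, 0.92), 0.7))),
    P2 = list(mu = p2_latency, sigma = 45, amp = 1.4,
              topo = drop(0.75 * spatial_gaussian(pos, ft, 0.55) +
                            0.45 * spatial_gaussian(pos, c(0, 0.3, 0.95), 0.8)))
  )
}

pink_noise <- function(n, n_series) {
  w <- matrix(rnorm(n * n_series), n, n_series)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)                      # two-sided frequency index
  shape <- 1 / sqrt(pmax(f, 1))
  z <- Re(mvfft(mvfft(w) * shape, inverse = TRUE) / n)
  # unit variance per series
  sweep(z, 2, apply(z, 2, sd), "/")
}

#' Simulate a two-group voice-ERP cohort
#'
#' Each trial is a sum of spatially smooth P1/N1/P2 component topographies
#' times temporal Gaussians at the component latencies, with group 0
#' receiving `p2_effect` times the P2 amplitude, plus spatially correlated
#' 1/f background noise, a 10 Hz oscillation with random phase per trial,
#' sensor noise, and (at `artifact_rate > 0`) occasional high-amplitude
#' step/drift artifacts. Identical `(cfg, montage)` give bit-identical
#' output.
#'
#' @param cfg A [cohort_config()].
#' @param montage An [generate_montage()] result.
#' @return An `erp_cohort`: list with `subjects` (list of [eeg_epochs()]),
#'   `subjects_tbl` (tibble of `subject_id`, `group`), `artifact_mask`
#'   (list of logical trial masks), `montage`, `config`, and
#'   `ground_truth` (planted P2 topography, its top-loading channels, and
#'   component latencies).
#' @export
simulate_cohort <- function(cfg, montage = generate_montage(64)) {
  stopifnot(inherits(cfg, "cohort_config"))
  comps <- cohort_components(montage, cfg$p2_latency)
  nchan <- nrow(montage)
  nsamp <- round(diff(cfg$epoch_window) * cfg$fs / 1000)
  t_ms <- cfg$epoch_window[1] + (seq_len(nsamp) - 1) * 1000 / cfg$fs
  pos <- montage_positions(montage)
  ns <- cfg$noise_scale

  # fixed spatial structure of the background: smooth mixing of a bank of
  # cortical noise sources onto the electrodes
  n_src <- 16L
  k <- seq_len(n_src)
  src_dir <- cbind(sqrt(1 - ((k - 0.5) / n_src)^1) * cos(k * 2.4),
                   sqrt(1 - ((k - 0.5) / n_src)^1) * sin(k * 2.4),
                   (k - 0.5) / n_src)
  src_dir <- src_dir / sqrt(rowSums(src_dir^2))
  mix <- sapply(seq_len(n_src),
                function(j) spatial_gaussian(pos, src_dir[j, ], 0.6))
  alpha_topo <- drop(spatial_gaussian(pos, c(0, -0.75, 0.66), 0.8))

  n_total <- 2L * cfg$n_subjects_per_group
  ids <- sprintf("S%02d", seq_len(n_total))
  groups <- rep(c(0L, 1L), each = cfg$n_subjects_per_group)

  subjects <- vector("list", n_total)
  masks <- vector("list", n_total)
  with_seed(cfg$seed, {
    for (s in seq_len(n_total)) {
      # subject-level morphology variability (scales with noise_scale)
      amp_subj <- exp(rnorm(3, 0, 0.15 * ns))
      lat_subj <- rnorm(3, 0, 8 * ns)
      dat <- array(0, dim = c(cfg$n_trials, nchan, nsamp))
      if (ns > 0) {
        # one batched draw of the background bank for all trials
        bg_all <- pink_noise(nsamp, n_src * cfg$n_trials)
        osc_phase <- runif(cfg$n_trials, 0, 2 * pi)
      }
      for (tr in seq_len(cfg$n_trials)) {
        sig <- matrix(0, nchan, nsamp)
        for (ci in seq_along(comps)) {
          cmp <- comps[[ci]]
          a <- cmp$amp * amp_subj[ci] * max(0, 1 + rnorm(1, 0, 0.2 * ns))
          if (names(comps)[ci] == "P2" && groups[s] == 0L) {
            a <- a * cfg$p2_effect
          }
          mu <- cmp$mu + lat_subj[ci] + rnorm(1, 0, 6 * ns)
          g <- temporal_gaussian(t_ms, mu, cmp$sigma)
          g[t_ms < 0] <- 0                 # components are post-onset
          sig <- sig + a * cmp$topo %o% g
        }
        if (ns > 0) {
          cols <- (tr - 1L) * n_src + seq_len(n_src)
          bg <- mix %*% t(bg_all[, cols, drop = FALSE]) * (0.28 * ns)
          osc <- (0.35 * ns) * alpha_topo %o%
            sin(2 * pi * 10 * t_ms / 1000 + osc_phase[tr])
          sens <- matrix(rnorm(nchan * nsamp, 0, 0.12 * ns), nchan, nsamp)
          sig <- sig + bg + osc + sens
        }
        dat[tr, , ] <- sig
      }
      subjects[[s]] <- eeg_epochs(dat, cfg$fs, cfg$epoch_window,
                                  montage$label, ids[s], groups[s])
      masks[[s]] <- rep(FALSE, cfg$n_trials)
      if (cfg$artifact_rate > 0) {
        inj <- inject_artifacts(subjects[[s]], cfg$artifact_rate,
                                amplitude = 25 * max(ns, 0.2),
                                seed = sample.int(2^31 - 1, 1))
        subjects[[s]] <- inj$epochs
        masks[[s]] <- inj$mask
      }
    }
  })

  p2_topo <- comps$P2$topo
  names(p2_topo) <- montage$label
  structure(list(
    subjects = subjects,
    subjects_tbl = tibble::tibble(subject_id = ids, group = groups),
    artifact_mask = masks,
    montage = montage, config = cfg,
    ground_truth = list(
      p2_topography = p2_topo,
      p2_channels = names(sort(p2_topo, decreasing = TRUE))[1:5],
      p2_focus = names(sort(p2_topo, decreasing = TRUE))[1:3],
      latencies = c(P1 = 80, N1 = 150, P2 = cfg$p2_latency)
    )
  ), class = "erp_cohort")
}

#' @export
print.erp_cohort <- function(x, ...) {
  cat(sprintf("<erp_cohort> %d subjects (%d per group), %d trials each, %d channels\n",
              length(x$subjects), x$config$n_subjects_per_group,
              x$config$n_trials, nrow(x$montage)))
  invisible(x)
}

#' Inject step/drift artifacts into epochs
#'
#' Flags each trial independently with probability `rate` and adds a
#' half-epoch amplitude step plus a linear drift of the given amplitude on
#' a random subset of channels. The returned mask is the ground truth used
#' to validate artifact detection.
#'
#' @param epochs An `eeg_epochs` object.
#' @param rate Flagging probability in `[0, 1)`.
#' @param amplitude Positive artifact amplitude.
#' @param seed Integer seed.
#' @return A list with `epochs` (contaminated) and `mask` (logical).
#' @export
inject_artifacts <- function(epochs, rate, amplitude, seed = 1) {
  check_scalar_num(rate, "rate", lower = 0, upper = 1, closed_upper = FALSE)
  check_scalar_num(amplitude, "amplitude", lower = 0, closed_lower = FALSE)
  nt <- n_trials(epochs)
  nc <- n_channels_of(epochs)
  np <- n_samples(epochs)
  with_seed(seed, {
    mask <- runif(nt) < rate
    for (tr in which(mask)) {
      chans <- sample.int(nc, max(1L, round(nc / 5)))
      onset <- sample.int(np - 1L, 1)
      step <- c(rep(0, onset), rep(amplitude, np - onset))
      drift <- amplitude * seq(0, 1, length.out = np) *
        sample(c(-0.5, 0.5), 1)
      epochs$data[tr, chans, ] <-
        epochs$data[tr, chans, , drop = FALSE][1, , ] +
        rep(step + drift, each = length(chans))
    }
  })
  list(epochs = epochs, mask = mask)
}

#' Write / read a cohort as a plain-text store
#'
#' One directory per cohort: `montage.csv`, `subjects.csv`, `meta.json`,
#' and per subject a CSV matrix with one row per (trial, channel) series.
#'
#' @param cohort An `erp_cohort`.
#' @param dir Directory path.
#' @return `read_cohort()` returns an `erp_cohort` (without ground-truth
#'   annotations, which live only in memory).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_montage(cohort$montage, file.path(dir, "montage.csv"))
  write.csv(as.data.frame(cohort$subjects_tbl),
            file.path(dir, "subjects.csv"), row.names = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(cfg[setdiff(names(cfg), "epoch_window")],
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  jsonlite::write_json(list(epoch_window = cfg$epoch_window),
                       file.path(dir, "window.json"))
  for (ep in cohort$subjects) {
    d <- dim(ep$data)
    flat <- matrix(aperm(ep$data, c(3, 2, 1)), nrow = d[3])
    write.csv(round(t(flat), 6),
              file.path(dir, paste0("epochs_", ep$subject_id, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  montage <- read_montage(file.path(dir, "montage.csv"))
  subj <- read.csv(file.path(dir, "subjects.csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  window <- unlist(jsonlite::read_json(file.path(dir, "window.json"),
                                       simplifyVector = TRUE))
  cfg <- do.call(cohort_config, c(meta[setdiff(names(meta), "epoch_window")],
                                  list(epoch_window = window)))
  subjects <- lapply(seq_len(nrow(subj)), function(i) {
    flat <- as.matrix(read.csv(
      file.path(dir, paste0("epochs_", subj$subject_id[i], ".csv"))))
    nsamp <- ncol(flat)
    nchan <- nrow(montage)
    ntr <- nrow(flat) / nchan
    dat <- aperm(array(t(flat), dim = c(nsamp, nchan, ntr)), c(3, 2, 1))
    eeg_epochs(dat, cfg$fs, cfg$epoch_window, montage$label,
               subj$subject_id[i], subj$group[i])
  })
  structure(list(subjects = subjects,
                 subjects_tbl = tibble::as_tibble(subj),
                 artifact_mask = NULL, montage = montage, config = cfg,
                 ground_truth = NULL),
            class = "erp_cohort")
}
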