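# Shared fixtures. Heavy pipeline runs are computed lazily, once per test
# session, and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

# Random symmetric nonnegative adjacency with zero diagonal.
random_adjacency <- function(n, density = 1) {
  A <- matrix(runif(n * n), n, n)
  if (density < 1) A[A > density] <- 0
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# Enumerate all permutations of 1..n (n small).
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

perm_matrix <- function(p) {
  P <- matrix(0, length(p), length(p))
  P[cbind(seq_along(p), p)] <- 1
  P
}

# A small fast cohort on the 16-channel generic montage for unit tests.
small_cohort <- function(seed = 1, n_per_group = 2, n_trials = 8,
                         noise_scale = 1, p2_effect = 2.5,
                         artifact_rate = 0, n_channels = 16) {
  cfg <- cohort_config(n_subjects_per_group = n_per_group,
                       n_trials = n_trials, p2_effect = p2_effect,
                       noise_scale = noise_scale,
                       artifact_rate = artifact_rate, seed = seed)
  simulate_cohort(cfg, generate_montage(n_channels))
}

# Study-scale pipeline runs shared by the acceptance tests.
strong_run <- function() memo("strong_run", {
  cfg <- run_config(cohort = list(n_subjects_per_group = 20), seed = 101)
  run_pipeline(cfg)
})

null_run <- function() memo("null_run", {
  cfg <- run_config(cohort = list(n_subjects_per_group = 10,
                                  p2_effect = 1.0),
                    stages = list(saliency = FALSE, microstates = FALSE,
                                  vote = FALSE),
                    seed = 202)
  run_pipeline(cfg)
})

tiny_run_config <- function() {
  run_config(cohort = list(n_subjects_per_group = 5, n_trials = 20),
             microstates = list(k_min = 2, k_max = 4), seed = 33)
}

tiny_run <- function() memo("tiny_run", run_pipeline(tiny_run_config()))

manifest_hashes <- function(run) {
  unlist(lapply(run$manifest$stages, function(s) s$hashes))
}
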