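test_that("GFP is the per-sample population standard deviation across channels", {
  m <- matrix(0, 4, 3)
  m[, 2] <- 5                      # spatially constant
  m[1:2, 3] <- c(1, -1)
  g <- gfp(m)
  expect_equal(g[2], 0)
  set.seed(60)
  x <- matrix(rnorm(12 * 50), 12, 50)
  direct <- apply(x, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_lt(max(abs(gfp(x) - direct)), 1e-12)
  two <- matrix(c(1, -1), 2, 1)
  expect_equal(gfp(two), 1)
  # permutation invariance
  expect_equal(gfp(x[sample(12), ]), gfp(x))
  expect_error(gfp(matrix(1, 1, 5)), class = "erpgraph_invalid_argument")
})

planted_maps <- function(seed, k = 3, p = 20, n = 80, noise = 0.1) {
  set.seed(seed)
  tpl <- qr.Q(qr(matrix(rnorm(p * k), p, k)))
  tpl[, sample(k, n, TRUE)] + matrix(rnorm(p * n, 0, noise), p, n)
}

test_that("Krzanowski-Lai selection recovers a planted cluster count", {
  hits <- 0
  for (s in 1:20) {
    cl <- cluster_topographies(planted_maps(s), k_range = 2:6, seed = s)
    hits <- hits + (cl$chosen_k == 3)
  }
  expect_gt(hits, 10)                   # 20-seed majority
  .fixture_cache$kl_hits <- hits
})

test_that("clustering is seeded-deterministic and k = 1 is never scanned", {
  maps <- planted_maps(7)
  a <- cluster_topographies(maps, k_range = 2:5, seed = 3)
  b <- cluster_topographies(maps, k_range = 2:5, seed = 3)
  expect_identical(a$templates, b$templates)
  expect_identical(a$chosen_k, b$chosen_k)
  expect_true(all(a$kl_curve$k >= 2))
  expect_error(cluster_topographies(maps, k_range = 1:5),
               class = "erpgraph_invalid_argument")
  # template normalization
  expect_equal(unname(colSums(a$templates^2)), rep(1, a$chosen_k),
               tolerance = 1e-10)
})

test_that("clustering is invariant (up to relabeling) to ERP scaling", {
  maps <- planted_maps(8)
  a <- cluster_topographies(maps, k_range = 2:5, seed = 1)
  b <- cluster_topographies(maps * 40, k_range = 2:5, seed = 1)
  expect_equal(a$chosen_k, b$chosen_k)
  # unit-normalizing the maps removes the scale entirely
  expect_equal(a$templates, b$templates, tolerance = 1e-8)
})

test_that("segmentation labels by spatial correlation and recovers boundaries", {
  set.seed(61)
  p <- 16
  tpl <- qr.Q(qr(matrix(rnorm(p * 2), p, 2)))
  # template 1 before 250 ms, template 2 after; epoch -200..500 at 1 kHz
  erp <- matrix(0, p, 700)
  tms <- seq(-200, 499)
  erp[, tms < 250] <- tpl[, 1] * 3
  erp[, tms >= 250] <- tpl[, 2] * 2
  erp <- erp + matrix(rnorm(p * 700, 0, 0.05), p, 700)
  seg <- segment_microstates(erp, tpl, fs = 1000)
  # pure template: constant labels
  seg1 <- segment_microstates(tpl[, 1] %o% rep(1, 100) *
                                matrix(rep(seq(1, 2, length.out = 100),
                                           each = p), p), tpl, fs = 1000)
  expect_true(all(seg1$labels == 1))
  expect_equal(seg1$coverage$fraction[1], 1)
  # boundary within +-5 ms of the planted switch
  sw <- which(diff(seg$labels) != 0)
  expect_equal(length(sw), 1)
  expect_lt(abs(tms[sw + 1] - 250), 5 + 1e-9)
  # amplitude scaling leaves labels unchanged
  seg_sc <- segment_microstates(erp * 17, tpl, fs = 1000)
  expect_identical(seg_sc$labels, seg$labels)
})

test_that("short segments are merged into their neighbours", {
  p <- 10
  set.seed(62)
  tpl <- qr.Q(qr(matrix(rnorm(p * 2), p, 2)))
  erp <- tpl[, 1] %o% rep(1, 100)
  erp[, 50:52] <- tpl[, 2] %o% rep(1, 3)   # 3 ms blip at 1 kHz
  seg <- segment_microstates(erp, tpl, min_duration_ms = 10, fs = 1000)
  expect_true(all(seg$labels == 1))
})

test_that("transition summaries list label changes in temporal order", {
  expect_equal(nrow(transition_summary(rep(2, 50))), 0)
  tr <- transition_summary(c(rep(1, 10), rep(3, 5)))
  expect_equal(nrow(tr), 1)
  expect_equal(tr$from, 1)
  expect_equal(tr$to, 3)
  expect_equal(tr$time_ms, 11)
  # a planted five-state sequence is recovered end to end
  set.seed(63)
  p <- 16
  tpl <- qr.Q(qr(matrix(rnorm(p * 5), p, 5)))
  seqs <- c(1, 2, 3, 4, 5, 2)
  erp <- do.call(cbind, lapply(seqs, function(s) tpl[, s] %o% rep(1, 50)))
  seg <- segment_microstates(erp, tpl, fs = 1000)
  tr5 <- transition_summary(seg$labels)
  expect_equal(rle(seg$labels)$values, seqs)
  expect_equal(tr5$from, seqs[-length(seqs)])
  expect_equal(tr5$to, seqs[-1])
})

test_that("group-level analysis back-fits shared templates per group", {
  co <- small_cohort(n_trials = 6, n_channels = 16, seed = 64)
  erp0 <- average_erp(co$subjects[[1]])
  erp1 <- average_erp(co$subjects[[3]])
  ms <- microstate_analysis(erp0, erp1, k_range = 2:4, n_init = 10, seed = 2)
  expect_s3_class(ms$clustering, "erp_microstates")
  expect_length(ms$segmentation, 2)
  expect_equal(length(ms$segmentation$group0$labels), 700)
  expect_true(all(ms$segmentation$group1$labels %in%
                    seq_len(ms$clustering$chosen_k)))
  gl <- glance(ms$clustering)
  expect_equal(gl$chosen_k, ms$clustering$chosen_k)
})
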