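# A self-expressive toy: channel `target` is an exact combination of two
# basis channels, the rest are independent.
planted_toy <- function(n_subj = 2, d = 60, seed = 30) {
  set.seed(seed)
  lapply(seq_len(n_subj), function(i) {
    b <- matrix(rnorm(5 * d), 5, d)
    rbind(b[1, ], b[2, ], b[3, ], b[4, ], b[1, ] + b[2, ])  # ch5 = ch1 + ch2
  })
}

test_that("dictionaries exclude the target electrode", {
  mats <- planted_toy()
  dict <- build_dictionary(mats, 5)
  expect_equal(ncol(dict$X[[1]]), 4)
  expect_equal(dict$dict_index, 1:4)
  expect_equal(dict$X[[1]][, 1], mats[[1]][1, ])
  expect_error(build_dictionary(list(matrix(1, 1, 10)), 1),
               class = "erpgraph_invalid_argument")
})

test_that("pairwise similarities are clipped symmetric correlations", {
  set.seed(31)
  sig <- matrix(rnorm(50 * 3), 50, 3)
  sig[, 3] <- -sig[, 1]
  S <- pairwise_similarities(sig)
  expect_equal(diag(S), rep(1, 3))
  expect_equal(S[1, 3], 0)               # anti-correlation clips to zero
  expect_true(isSymmetric(S))
  Sg <- pairwise_similarities(sig, "group", block = c(1, 1, 2))
  expect_equal(Sg[1, 3], 0)
  expect_equal(Sg[2, 1], S[2, 1])
})

test_that("the objective matches an independent term-by-term evaluation", {
  set.seed(32)
  mats <- planted_toy(3)
  dict <- build_dictionary(mats, 5)
  W <- matrix(rnorm(4 * 3), 4, 3)
  lam <- c(0.3, 0.2, 0.1, 0.05)
  Sg <- pairwise_similarities(sapply(mats, function(m) m[5, ]))
  St <- Sg * 0.5; diag(St) <- 1
  got <- sparse_objective(W, dict, lam, Sg = Sg, St = St)
  # independent evaluation
  recon <- sum(vapply(1:3, function(i) {
    0.5 * sum((mats[[i]][5, ] - t(mats[[i]][-5, ]) %*% W[, i])^2)
  }, 0))
  l21 <- (lam[1] + lam[3]) * sum(sqrt(rowSums(W^2)))
  quad <- function(S, l) {
    acc <- 0
    for (i in 1:3) for (j in 1:3) acc <- acc + S[i, j] * sum((W[, i] - W[, j])^2)
    l * acc
  }
  expect_lt(abs(got - (recon + l21 + quad(Sg, lam[2]) + quad(St, lam[4]))),
            1e-10)
  expect_error(sparse_objective(W, dict, c(-1, 0, 0, 0)),
               class = "erpgraph_invalid_argument")
  # zero weights, zero data
  zdict <- build_dictionary(list(matrix(0, 3, 10)), 1)
  expect_equal(sparse_objective(matrix(0, 2, 1), zdict, c(0, 0, 0, 0)), 0)
})

test_that("lambda = 0 fit reproduces per-subject least squares", {
  mats <- planted_toy(2, d = 50, seed = 33)
  # add noise so the LS problem is well conditioned but nontrivial
  mats <- lapply(mats, function(m) m + matrix(rnorm(length(m), 0, 0.2),
                                              nrow(m)))
  dict <- build_dictionary(mats, 5)
  fit <- fit_sparse_graph(dict, lambdas = c(0, 0, 0, 0), tol = 1e-14,
                          max_iter = 20000)
  for (i in 1:2) {
    ls <- qr.solve(dict$X[[i]], dict$x[[i]])
    expect_lt(sqrt(sum((fit$W[, i] - ls)^2)), 1e-6)
  }
  expect_true(all(diff(fit$objective_trace) <= 1e-10))
})

test_that("the noiseless self-expressive toy is reconstructed exactly", {
  dict <- build_dictionary(planted_toy(1), 5)
  fit <- fit_sparse_graph(dict, lambdas = c(0, 0, 0, 0), tol = 0,
                          max_iter = 30000)
  r <- dict$x[[1]] - dict$X[[1]] %*% fit$W[, 1]
  expect_lt(sqrt(sum(r^2)), 1e-8)
  # true generating edges (ch1, ch2) carry nearly all the weight
  mass <- abs(fit$W[, 1])
  expect_gte(sum(mass[1:2]) / sum(mass), 0.9)
})

test_that("heavy l2,1 shrinkage drives all weights to zero", {
  dict <- build_dictionary(planted_toy(2), 5)
  fit <- fit_sparse_graph(dict, lambdas = c(1e5, 0, 0, 0))
  expect_lt(max(sqrt(rowSums(fit$W^2))), 1e-6)
})

test_that("the proximal fit reaches a generic convex solver's optimum", {
  set.seed(34)
  mats <- lapply(1:2, function(i) matrix(rnorm(3 * 25), 3, 25))
  dict <- build_dictionary(mats, 3)
  lam <- c(0.5, 0.1, 0, 0)
  Sg <- pairwise_similarities(sapply(mats, function(m) m[3, ]))
  fit <- fit_sparse_graph(dict, lam, Sg = Sg, tol = 1e-14, max_iter = 50000)
  obj <- function(w) sparse_objective(matrix(w, 2, 2), dict, lam, Sg = Sg)
  ref <- optim(rnorm(4, 0, 0.1), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  ref2 <- optim(ref$par, obj, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
  expect_lt(obj(as.vector(fit$W)) - min(ref$value, ref2$value), 1e-4)
})

test_that("the solution path is continuous in lambda", {
  dict <- build_dictionary(planted_toy(2, seed = 35), 5)
  f1 <- fit_sparse_graph(dict, c(0.05, 0, 0, 0), tol = 1e-12,
                         max_iter = 20000)
  f2 <- fit_sparse_graph(dict, c(0.051, 0, 0, 0), tol = 1e-12,
                         max_iter = 20000)
  expect_lt(max(abs(f1$W - f2$W)), 0.05)
})

test_that("sparse-graph reweighting is symmetric and prunes zero rows", {
  mats <- planted_toy(2, seed = 36)
  st <- sparse_graph_stage(mats, groups = c(0, 1),
                           lambdas = c(0.05, 0, 0, 0))
  expect_true(isSymmetric(st$A))
  expect_equal(diag(st$A), rep(0, 5))
  zero_fit <- st$models
  for (e in seq_along(zero_fit)) zero_fit[[e]]$W[] <- 0
  A0 <- apply_sparse_graph(zero_fit, matrix(0, 5, 5))
  expect_equal(max(abs(A0)), 0)
  expect_error(apply_sparse_graph(st$models[1:3], matrix(0, 5, 5)),
               class = "erpgraph_invalid_argument")
})

test_that("row support recovery is precise on planted sparse data", {
  # several subjects share the same generating support (ch1, ch2)
  mats <- planted_toy(4, d = 80, seed = 37)
  mats <- lapply(mats, function(m) m + matrix(rnorm(length(m), 0, 0.05),
                                              nrow(m)))
  dict <- build_dictionary(mats, 5)
  # lambda calibrated to the planted weight scale (row norms ~2) vs the
  # 0.05 noise floor
  fit <- fit_sparse_graph(dict, c(3, 0, 0, 0), tol = 1e-12,
                          max_iter = 20000)
  sel <- which(sqrt(rowSums(fit$W^2)) > 1e-3)
  expect_gt(length(sel), 0)
  precision <- length(intersect(sel, 1:2)) / length(sel)
  expect_gte(precision, 0.8)
})
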