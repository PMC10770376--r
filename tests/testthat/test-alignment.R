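test_that("matching objective vanishes exactly on isomorphic graphs", {
  set.seed(20)
  A1 <- random_adjacency(5)
  expect_equal(matching_objective(diag(5), A1, A1), 0)
  p <- c(3, 1, 4, 5, 2)
  P <- perm_matrix(p)
  A2 <- t(P) %*% A1 %*% P
  expect_equal(matching_objective(P, A1, A2), 0, tolerance = 1e-20)
  expect_error(matching_objective(diag(4), A1, A1),
               class = "erpgraph_invalid_argument")
})

test_that("exhaustive permutation search confirms the objective's minimizer (n <= 5)", {
  set.seed(21)
  for (n in 3:5) {
    A1 <- random_adjacency(n)
    p_true <- sample(n)
    P_true <- perm_matrix(p_true)
    A2 <- t(P_true) %*% A1 %*% P_true
    vals <- vapply(all_perms(n), function(p) {
      matching_objective(perm_matrix(p), A1, A2)
    }, 0)
    expect_equal(min(vals), 0, tolerance = 1e-18)
    expect_equal(matching_objective(P_true, A1, A2), 0, tolerance = 1e-18)
    # non-isomorphic perturbation: no permutation reaches zero
    A2b <- A2
    A2b[1, 2] <- A2b[2, 1] <- A2b[1, 2] + 1
    vals_b <- vapply(all_perms(n), function(p) {
      matching_objective(perm_matrix(p), A1, A2b)
    }, 0)
    expect_gt(min(vals_b), 1e-6)
  }
})

test_that("the prior encodes cross-group row similarity and normalizes", {
  set.seed(22)
  A <- random_adjacency(4)
  pr <- build_prior(A, A)
  expect_equal(sum(pr$H), 1)
  expect_true(all(diag(pr$H) >= apply(pr$H, 1, max) - 1e-12))
  # orthogonal rows give zero before normalization
  M0 <- rbind(c(0, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 0, 1), c(0, 0, 1, 0))
  M1 <- rbind(c(0, 0, 1, 0), c(0, 0, 0, 1), c(1, 0, 0, 0), c(0, 1, 0, 0))
  pr2 <- build_prior(M0 * 1.0, M1 * 1.0)
  expect_equal(pr2$H[1, 1], 0)
  expect_warning(pu <- build_prior(matrix(0, 3, 3), matrix(0, 3, 3)),
                 "uniform")
  expect_equal(pu$H, matrix(1 / 9, 3, 3))
})

test_that("Kronecker fixed point matches the dense linear solve on toys", {
  set.seed(23)
  for (n in 2:4) {
    A1 <- random_adjacency(n)
    A2 <- random_adjacency(n)
    h <- runif(n^2)
    h <- h / sum(h)
    fp <- kronecker_fixed_point(A1, A2, h, alpha = 0.5, tol = 1e-12)
    P1 <- erpgraph:::row_normalize(A1)
    P2 <- erpgraph:::row_normalize(A2)
    ref <- solve(diag(n^2) - 0.5 * kronecker(P1, P2), 0.5 * h)
    expect_lt(max(abs(fp$s - ref)), 1e-8)
    expect_true(all(fp$s >= 0))
  }
  # alpha = 0 collapses to the prior
  A <- random_adjacency(3)
  h <- runif(9)
  expect_equal(kronecker_fixed_point(A, A, h, alpha = 0)$s, h)
})

test_that("the combined objective behaves like a descent criterion", {
  set.seed(24)
  A0 <- matrix(0, 3, 3)
  h <- runif(9)
  expect_equal(ineat_objective(h, A0, A0, h, 0.5), 0)
  for (i in 1:10) {
    A1 <- random_adjacency(3)
    A2 <- random_adjacency(3)
    h <- runif(9); h <- h / sum(h)
    # D - A1 (x) A2 of row-normalized kernels is PSD-like here: check the
    # objective is nonnegative at arbitrary s when the eigenvalues say so
    D <- kronecker(diag(rowSums(abs(A1))), diag(rowSums(abs(A2))))
    Mq <- D - kronecker(A1, A2)
    if (min(eigen(Mq, symmetric = TRUE, only.values = TRUE)$values) > -1e-10) {
      s <- runif(9)
      expect_gte(ineat_objective(s, A1, A2, h, 1.0), -1e-10)
    }
    fp <- kronecker_fixed_point(A1, A2, h, 0.5)
    expect_lte(ineat_objective(fp$s, A1, A2, h, 0.5),
               ineat_objective(h, A1, A2, h, 0.5) + 1e-10)
  }
})

test_that("permutation extraction solves the assignment exactly (brute force n <= 5)", {
  expect_equal(extract_permutation(diag(4)), diag(4))
  P0 <- perm_matrix(c(2, 3, 1))
  expect_equal(extract_permutation(P0), P0)
  set.seed(25)
  for (i in 1:10) {
    n <- sample(3:5, 1)
    S <- matrix(runif(n * n), n, n)
    P <- extract_permutation(S)
    best <- max(vapply(all_perms(n), function(p) sum(S[cbind(1:n, p)]), 0))
    expect_equal(sum(S * P), best, tolerance = 1e-12)
    expect_equal(colSums(P), rep(1, n))
    expect_equal(rowSums(P), rep(1, n))
  }
})

test_that("channel reorganization round-trips and commutes with connectivity", {
  co <- small_cohort(n_trials = 3, n_channels = 8)
  ep <- co$subjects[[1]]
  set.seed(26)
  P <- perm_matrix(sample(8))
  expect_equal(reorganize_channels(ep, diag(8))$data, ep$data)
  back <- reorganize_channels(reorganize_channels(ep, P), t(P))
  expect_equal(back$data, ep$data)
  expect_equal(back$channels, ep$channels)
  W_then_perm <- reorganize_channels(unname(pcc_matrix(ep)), P)
  perm_then_W <- unname(pcc_matrix(reorganize_channels(ep, P)))
  expect_lt(max(abs(W_then_perm - perm_then_W)), 1e-10)
  expect_error(reorganize_channels(ep, diag(5)),
               class = "erpgraph_invalid_argument")
})

test_that("self-alignment under the diagonal-dominant prior is the identity", {
  set.seed(27)
  W <- random_adjacency(10)
  g <- connectivity_graph(W, k1 = 2, k2 = 5)
  pr <- build_prior(abs(g$A2), abs(g$A2))
  al <- align_subject(g, pr)
  expect_equal(al$P, diag(10))
  expect_lt(al$residual, 1e-8)
})
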