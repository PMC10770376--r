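test_that("Laplacians match their textbook forms", {
  K3 <- matrix(1, 3, 3) - diag(3)
  L <- graph_laplacian(K3, normalized = FALSE)
  expect_equal(diag(L), rep(2, 3))
  expect_equal(L[1, 2], -1)
  set.seed(40)
  A <- random_adjacency(7)
  expect_equal(rowSums(graph_laplacian(A, normalized = FALSE)), rep(0, 7),
               tolerance = 1e-12)
  # path graph P3, normalized: eigenvalues {0, 1, 2}
  P3 <- matrix(0, 3, 3)
  P3[1, 2] <- P3[2, 1] <- P3[2, 3] <- P3[3, 2] <- 1
  ev <- graph_spectrum(P3)$lambda
  expect_equal(ev, c(0, 1, 2), tolerance = 1e-10)
  # eigenvalue range and PSD
  sp <- graph_spectrum(A)
  expect_true(all(sp$lambda >= -1e-10 & sp$lambda <= 2 + 1e-10))
  expect_lt(max(abs(crossprod(sp$U) - diag(7))), 1e-8)
  expect_error(graph_laplacian(matrix(runif(9), 3, 3)),
               class = "erpgraph_invalid_argument")
})

test_that("graph Fourier transform is an exact orthonormal transform", {
  set.seed(41)
  sp <- graph_spectrum(random_adjacency(6))
  x <- rnorm(6)
  chi <- graph_fourier(x, sp$U)
  expect_equal(as.vector(inverse_graph_fourier(chi, sp$U)), x,
               tolerance = 1e-10)
  expect_equal(sqrt(sum(chi^2)), sqrt(sum(x^2)), tolerance = 1e-10)
  e0 <- graph_fourier(sp$U[, 1], sp$U)
  expect_equal(as.vector(e0), c(1, rep(0, 5)), tolerance = 1e-10)
  expect_error(graph_fourier(rnorm(5), sp$U),
               class = "erpgraph_invalid_argument")
})

test_that("Chebyshev recursion equals spectral-domain filtering on random graphs", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(4:10, 1)
    K <- sample(1:5, 1)
    sp <- graph_spectrum(random_adjacency(n))
    theta <- rnorm(K)
    x <- rnorm(n)
    y <- cheb_filter(x, sp$L_tilde, theta)
    lam <- 2 * sp$lambda / max(sp$lambda) - 1
    g <- vapply(lam, function(l) {
      tk <- c(1, l)
      out <- theta[1]
      if (K >= 2) out <- out + theta[2] * l
      if (K >= 3) for (k in 3:K) {
        tk <- c(tk[2], 2 * l * tk[2] - tk[1])
        out <- out + theta[k] * tk[2]
      }
      out
    }, 0)
    y_ref <- sp$U %*% (g * crossprod(sp$U, x))
    expect_lt(max(abs(y - y_ref)), 1e-8)
  }
  # closed forms
  sp <- graph_spectrum(random_adjacency(5))
  x <- rnorm(5)
  expect_equal(cheb_filter(x, sp$L_tilde, 2.5), 2.5 * x)
  expect_equal(cheb_filter(x, sp$L_tilde, c(0, 1)),
               as.vector(sp$L_tilde %*% x), tolerance = 1e-12)
  expect_error(cheb_filter(x, sp$L_tilde, numeric(0)),
               class = "erpgraph_invalid_argument")
})

test_that("architecture parameter counts follow the audit formulas", {
  expect_equal(unname(model_param_counts(build_model(K1 = 3, K2 = 3))[3]),
               1056)
  for (K1 in 1:5) for (K2 in 1:5) {
    pc <- model_param_counts(build_model(K1 = K1, K2 = K2))
    expect_equal(unname(pc["conv1"]), 4096 * K1 + 64)
    expect_equal(unname(pc["conv2"]), 2048 * K2 + 32)
    expect_equal(unname(pc["fc"]), 1056)
  }
  expect_equal(unname(model_param_counts(build_model(K1 = 3, K2 = 3))[1]),
               12352)
  expect_equal(unname(model_param_counts(build_model(K1 = 3, K2 = 3))[2]),
               6176)
  expect_error(build_model(K1 = 0), class = "erpgraph_invalid_argument")
  expect_error(build_model(n_nodes = 10), class = "erpgraph_invalid_argument")
})

test_that("cross-entropy matches closed forms and hand computation", {
  expect_equal(cross_entropy(c(0, 1), rbind(c(1, 0), c(0, 1))), 0,
               tolerance = 1e-10)
  expect_equal(cross_entropy(c(0, 1), matrix(0.5, 2, 2)), log(2),
               tolerance = 1e-12)
  p <- rbind(c(0.8, 0.2), c(0.3, 0.7))
  hand <- -(log(0.8) + log(0.7)) / 2
  expect_lt(abs(cross_entropy(c(0, 1), p) - hand), 1e-10)
  expect_error(cross_entropy(c(0, 1), rbind(c(0.9, 0.3), c(0.5, 0.5))),
               class = "erpgraph_invalid_argument")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(43)
  n <- 8
  model <- build_model(K1 = 3, K2 = 2, M = 2, n_nodes = n, n_features = n,
                       f1 = 6, f2 = 4, fc = 4, dropout = 0)
  inputs <- lapply(1:4, function(i) list(X = matrix(rnorm(n * n), n, n),
                                         A = random_adjacency(n)))
  Y <- erpgraph:::onehot(c(0, 0, 1, 1))
  preps <- erpgraph:::gcn_prep_inputs(inputs, model)
  batch <- erpgraph:::gcn_make_batch(preps, model)
  params <- erpgraph:::gcn_init_params(model)
  cache <- erpgraph:::gcn_forward(params, batch, model)
  grads <- erpgraph:::gcn_backward(params, cache, batch, model, Y)
  lossfn <- function(p) {
    erpgraph:::cross_entropy(Y, erpgraph:::gcn_forward(p, batch, model)$probs)
  }
  eps <- 1e-6
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in idx) {
      p2 <- params
      p2[[nm]][i] <- params[[nm]][i] + eps
      up <- lossfn(p2)
      p2[[nm]][i] <- params[[nm]][i] - eps
      dn <- lossfn(p2)
      expect_lt(abs((up - dn) / (2 * eps) - grads[[nm]][i]),
                1e-6 * max(1, abs(grads[[nm]][i])))
    }
  }
})

test_that("training is deterministic and the loss decreases on separable data", {
  set.seed(44)
  n <- 8
  mk_inputs <- function(seed) {
    set.seed(seed)
    lapply(1:12, function(i) {
      shift <- if (i <= 6) 1 else -1
      list(X = matrix(rnorm(n * n), n, n) + shift,
           A = random_adjacency(n))
    })
  }
  labels <- rep(c(0, 1), each = 6)
  for (s in 1:3) {
    inputs <- mk_inputs(s)
    fit <- gcn_fit(inputs, labels,
                   build_model(K1 = 2, K2 = 2, M = 2, n_nodes = n,
                               n_features = n, f1 = 6, f2 = 4, fc = 4,
                               dropout = 0),
                   seed = s, epochs = 12, patience = 50)
    expect_lt(fit$loss_trace[10], fit$loss_trace[1])
  }
  inputs <- mk_inputs(1)
  f1 <- gcn_fit(inputs, labels, seed = 5, epochs = 15)
  f2 <- gcn_fit(inputs, labels, seed = 5, epochs = 15)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$loss_trace, f2$loss_trace)
})

test_that("cross-validation folds are stratified, subject-level and reproducible", {
  labels <- rep(c(0, 1), each = 10)
  f <- erpgraph:::make_folds(labels, 5, seed = 1)
  expect_identical(f, erpgraph:::make_folds(labels, 5, seed = 1))
  for (k in 1:5) {
    expect_equal(sum(f == k & labels == 0), 2)
    expect_equal(sum(f == k & labels == 1), 2)
    expect_length(intersect(which(f == k), which(f != k)), 0)
  }
  expect_error(erpgraph:::make_folds(c(0, rep(1, 9)), 5, 1),
               class = "erpgraph_invalid_state")
})

test_that("evaluation metrics match brute-force definitions", {
  ev <- evaluate_metrics(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(ev$acc, 1)
  expect_equal(ev$auc, 1)
  ev_rev <- evaluate_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(ev_rev$auc, 0)
  # one error out of four
  ev1 <- evaluate_metrics(c(0, 0, 1, 1), c(0.9, 0.3, 0.2, 0.1))
  expect_equal(ev1$acc, 0.75)
  # AUC equals the pairwise concordance enumeration
  set.seed(45)
  labels <- rep(c(0, 1), times = c(6, 7))
  scores <- runif(13)
  ev2 <- evaluate_metrics(labels, scores)
  pairs <- expand.grid(p = which(labels == 0), n = which(labels == 1))
  conc <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                      ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
  expect_equal(ev2$auc, conc, tolerance = 1e-12)
  expect_error(evaluate_metrics(c(0, 0), c(0.1, 0.9)),
               class = "erpgraph_invalid_argument")
})

test_that("model comparison applies exact Mann-Whitney tests with Bonferroni", {
  same <- list(a = c(0.8, 0.8, 0.8, 0.8, 0.8), b = c(0.8, 0.8, 0.8, 0.8, 0.8))
  expect_equal(compare_models(same)$p[1, 2], 1)
  disj <- list(lo = 1:5 / 10, hi = 6:10 / 10)
  cm <- compare_models(disj)
  expect_equal(cm$p_raw[1, 2], 2 / choose(10, 5), tolerance = 1e-12)
  three <- list(a = 1:5, b = 6:10, c = 11:15)
  cm3 <- compare_models(three)
  expect_true(isSymmetric(cm3$p))
  expect_equal(unname(diag(cm3$p)), rep(1, 3))
  expect_equal(cm3$p[1, 2], min(1, cm3$p_raw[1, 2] * 3))
  expect_warning(compare_models(list(a = 1:2, b = 3:4)), "underpowered")
})
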