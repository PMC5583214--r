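test_that("pearson network matches the correlation quotient and its limits", {
  t <- 30
  set.seed(15)
  base <- rnorm(t)
  X <- cbind(base, base, -base, rnorm(t), rnorm(t))
  s <- standardize_columns(X)
  net <- pearson_network(s)
  expect_equal(net$W[1, 2], 1, tolerance = 1e-12)   # identical columns
  expect_equal(net$W[1, 3], -1, tolerance = 1e-12)  # anti-correlated
  # brute-force quotient oracle over every pair
  for (i in 1:5) {
    for (j in 1:5) {
      if (i == j) next
      ci <- X[, i] - mean(X[, i]); cj <- X[, j] - mean(X[, j])
      expect_equal(net$W[i, j], sum(ci * cj) / sqrt(sum(ci^2) * sum(cj^2)),
                   tolerance = 1e-12)
    }
  }
  expect_equal(unname(diag(net$W)), rep(0, 5))  # self-loops removed
  expect_lt(max(abs(net$W - t(net$W))), 1e-12)
  expect_error(pearson_network(matrix(rnorm(50), 10, 5)), "standardized")
})

test_that("hard thresholding keeps exactly the strongest pairs", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.9
  W[1, 3] <- W[3, 1] <- -0.5
  W[2, 3] <- W[3, 2] <- 0.1
  # k = round(33.3% of 3 pairs) = 1: only the 0.9 pair survives
  thr <- hard_threshold_network(W, 100 / 3)
  expect_equal(thr$W[1, 2], 0.9)
  expect_equal(thr$W[1, 3], 0)
  expect_equal(thr$W[2, 3], 0)
  expect_equal(edge_count(thr), 1L)
  # 100% leaves the off-diagonal untouched
  full <- hard_threshold_network(W, 100)
  expect_equal(full$W, fbn_network(W)$W)
  # signed ranking drops strong negative edges first
  sgn <- hard_threshold_network(W, 100 / 3, signed = TRUE)
  expect_equal(sgn$W[1, 3], 0)
  expect_equal(sgn$W[1, 2], 0.9)
  expect_error(hard_threshold_network(W, 0), "sparsity_percent")
  expect_error(hard_threshold_network(W, 101), "sparsity_percent")
})

test_that("hard-threshold supports are nested across sparsity levels", {
  for (seed in 1:3) {
    W <- rand_sym_sparse(12, 0.9, seed)
    levels <- c(10, 25, 50, 75, 100)
    supports <- lapply(levels, function(p) {
      abs(hard_threshold_network(W, p)$W) > 1e-12
    })
    nnz <- sum(abs(W[upper.tri(W)]) > 1e-12)
    counts <- vapply(levels, function(p) {
      min(round(p / 100 * 66), nnz)  # kept pairs that are zero carry no edge
    }, numeric(1))
    for (k in seq_along(levels)) {
      expect_equal(edge_count(hard_threshold_network(W, levels[k])),
                   as.integer(counts[k]))
      if (k > 1) expect_true(all(supports[[k - 1]] <= supports[[k]]))
    }
  }
})

test_that("soft thresholding implements elementwise shrinkage", {
  expect_equal(soft_threshold(0, 0.7), 0)
  expect_equal(soft_threshold(0.9, 0.3), 0.6)
  expect_equal(soft_threshold(-0.9, 0.3), -0.6)
  expect_equal(soft_threshold(-0.2, 0.5), 0)
  expect_error(soft_threshold(1, -0.1), "tau")
})

test_that("weighted soft thresholding reduces correctly and matches scalars", {
  set.seed(8)
  W <- matrix(rnorm(36), 6, 6)
  G1 <- matrix(1, 6, 6)
  expect_equal(weighted_soft_threshold(W, 0.3, G1), soft_threshold(W, 0.3))
  G0 <- matrix(0, 6, 6)
  expect_equal(weighted_soft_threshold(W, 5, G0), W)  # zero weight: no shrink
  G <- matrix(runif(36), 6, 6)
  out <- weighted_soft_threshold(W, 0.4, G)
  for (i in 1:6) {
    for (j in 1:6) {
      expect_equal(out[i, j],
                   sign(W[i, j]) * max(abs(W[i, j]) - 0.4 * G[i, j], 0),
                   tolerance = 1e-15)
    }
  }
  expect_error(weighted_soft_threshold(W, 0.4, G[1:3, 1:3]), "shape")
  expect_error(weighted_soft_threshold(W, 0.4, -G), ">= 0")
})

test_that("the sparse estimator equals the closed-form soft threshold", {
  for (seed in 1:5) {
    xs <- rand_std(40, 8, seed)
    S <- crossprod(xs$values)
    for (lambda in c(0.05, 0.2, 0.4, 0.7, 1)) {
      net <- estimate_pc_sparsity(xs, lambda)
      ref <- soft_threshold(S, lambda / 2)
      diag(ref) <- 0
      expect_lt(max(abs(net$W - ref)), 1e-8)
      expect_true(net$converged)
    }
  }
  # an undamped step size still converges to the same minimizer
  xs <- rand_std(40, 8, 99)
  S <- crossprod(xs$values)
  slow <- estimate_pc_sparsity(xs, 0.4,
                               cfg = solver_config(step_alpha = 0.3,
                                                   tol = 1e-12))
  ref <- soft_threshold(S, 0.2); diag(ref) <- 0
  expect_lt(max(abs(slow$W - ref)), 1e-8)
  expect_gt(slow$iterations, 1L)
})

test_that("sparsity estimator limits: lambda 0 recovers PC, large lambda empties", {
  xs <- rand_std(30, 6, 42)
  expect_equal(estimate_pc_sparsity(xs, 0)$W, pearson_network(xs)$W)
  S <- crossprod(xs$values)
  lam_kill <- 2 * max(abs(S[upper.tri(S)])) + 1e-6
  expect_equal(edge_count(estimate_pc_sparsity(xs, lam_kill)), 0L)
  # edge count is monotone non-increasing in lambda
  counts <- vapply(seq(0.05, 1, by = 0.05), function(l) {
    edge_count(estimate_pc_sparsity(xs, l))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # symmetry of the solution
  net <- estimate_pc_sparsity(xs, 0.3)
  expect_lt(max(abs(net$W - t(net$W))), 1e-10)
})

test_that("gamma weights follow the degree formula", {
  # degrees 1 and 3 at the (1,2) entry
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1
  W[2, 3] <- W[3, 2] <- 2
  G <- gamma_weights(W, epsilon = 1e-4)
  expect_equal(G[1, 2], exp(-(1 / 1.0001 + 1 / 3.0001)), tolerance = 1e-12)
  expect_equal(G, t(G))
  # monotonically increasing in the shared degree
  ds <- c(0.5, 1, 2, 5, 20)
  gs <- vapply(ds, function(d) {
    Wd <- matrix(c(0, d, d, 0), 2, 2)
    gamma_weights(Wd, 1e-4)[1, 2]
  }, numeric(1))
  expect_equal(gs, exp(-2 / (ds + 1e-4)), tolerance = 1e-12)
  expect_true(all(diff(gs) > 0))
  # empty network: exp(-2/epsilon) underflows to exactly zero
  expect_equal(max(gamma_weights(matrix(0, 4, 4), 1e-4)), 0)
  expect_error(gamma_weights(W, epsilon = 0), "epsilon")
})

test_that("scale-free estimator reduces to PC and to the sparse estimator", {
  xs <- rand_std(35, 7, 13)
  expect_equal(estimate_pc_scale_free(xs, 0)$W, pearson_network(xs)$W)
  tight <- solver_config(step_alpha = 0.25, tol = 1e-12,
                         outer_max_iter = 5000L)
  frozen <- estimate_pc_scale_free(xs, 0.4, cfg = tight,
                                   update_gamma = FALSE)
  expect_lt(max(abs(frozen$W - estimate_pc_sparsity(xs, 0.4)$W)), 1e-8)
})

test_that("scale-free solver converges with monotone per-step descent", {
  xs <- hub_subject(301)
  net <- estimate_pc_scale_free(xs, 0.5)
  expect_true(net$converged)
  expect_true(net$monotone_descent)
  expect_lt(max(abs(net$W - t(net$W))), 1e-10)
  expect_gt(edge_count(net), 0L)
  expect_lt(edge_count(net), choose(116, 2))
  # smaller problems across lambda values
  xs2 <- rand_std(60, 12, 77)
  for (lambda in c(0.1, 0.3, 0.6)) {
    n2 <- suppressWarnings(estimate_pc_scale_free(xs2, lambda))
    expect_true(n2$monotone_descent)
    expect_lt(max(abs(n2$W - t(n2$W))), 1e-10)
  }
})

test_that("SR returns zero for orthogonal designs and tracks its objective", {
  xs <- orthogonal_std(30, 6, 5)
  net <- estimate_sr(xs, 0.2)
  expect_equal(max(abs(net$W)), 0)
  # objective non-increasing along iterations
  xs2 <- rand_std(30, 10, 6)
  net2 <- estimate_sr(xs2, 0.1, cfg = solver_config(tol = 1e-8))
  expect_true(all(diff(net2$objective) <= 1e-10))
  expect_true(net2$symmetrized)
})

test_that("SR on a duplicated column matches the scalar lasso solution", {
  set.seed(23)
  u <- rnorm(40)
  xs <- standardize_columns(cbind(u, u))
  lambda <- 0.3
  net <- estimate_sr(xs, lambda, cfg = solver_config(tol = 1e-10))
  # each regression decouples: min (1-w)^2 + lambda |w| -> w = 1 - lambda/2
  expect_equal(net$W[1, 2], 1 - lambda / 2, tolerance = 1e-6)
  expect_equal(net$W[2, 1], 1 - lambda / 2, tolerance = 1e-6)
})

test_that("sparse estimator recovers a known support at the oracle lambda", {
  gt <- make_ground_truth(10, "random_sparse", density = 0.2, seed = 31)
  ts <- simulate_timeseries(gt, t = 2000, noise_sd = 0.2, seed = 32)
  xs <- standardize_columns(ts)
  truth <- abs(gt$W_true[upper.tri(gt$W_true)]) > 0
  f1 <- vapply(seq(0.05, 1, by = 0.05), function(lambda) {
    est <- abs(estimate_pc_sparsity(xs, lambda)$W[upper.tri(gt$W_true)]) >
      1e-12
    tp <- sum(est & truth)
    if (tp == 0) return(0)
    prec <- tp / sum(est)
    rec <- tp / sum(truth)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  expect_gte(max(f1), 0.9)
})
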