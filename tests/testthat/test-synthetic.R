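test_that("generators are pure functions of their seeds", {
  g1 <- make_ground_truth(20, "hub", density = 0.1, hub_count = 3, seed = 9)
  g2 <- make_ground_truth(20, "hub", density = 0.1, hub_count = 3, seed = 9)
  expect_identical(g1, g2)
  t1 <- simulate_timeseries(g1, t = 50, seed = 10)
  t2 <- simulate_timeseries(g1, t = 50, seed = 10)
  expect_identical(t1$values, t2$values)
  c1 <- make_cohort(g1, n_pos = 3, n_neg = 3, differential_edges = 4,
                    effect = 0.4, t = 40, seed = 11)
  c2 <- make_cohort(g1, n_pos = 3, n_neg = 3, differential_edges = 4,
                    effect = 0.4, t = 40, seed = 11)
  expect_identical(lapply(c1$subjects, `[[`, "values"),
                   lapply(c2$subjects, `[[`, "values"))
  # seeded calls do not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(make_ground_truth(10, seed = 5)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("ground-truth construction honours topology and weight contracts", {
  full <- make_ground_truth(10, "random_sparse", density = 1, seed = 1)
  expect_equal(edge_count(fbn_network(full$W_true)), 45L)
  sp <- make_ground_truth(40, "random_sparse", density = 0.1, seed = 2)
  w <- abs(sp$W_true[abs(sp$W_true) > 0])
  expect_true(all(w >= 0.2 & w <= 0.8))
  expect_equal(unname(diag(sp$W_true)), rep(0, 40))
  expect_equal(sp$W_true, t(sp$W_true))
  hub <- make_ground_truth(116, "hub", density = 0.05, hub_count = 5,
                           seed = 3)
  d <- node_degrees(hub$W_true)
  top5 <- order(d, decreasing = TRUE)[1:5]
  expect_setequal(top5, hub$hub_nodes)
  expect_gt(min(d[hub$hub_nodes]), max(d[-hub$hub_nodes]))
})

test_that("simulated series converge to the implied population correlation", {
  # null network: population correlation is the identity
  null_ts <- simulate_timeseries(matrix(0, 6, 6), t = 20000, noise_sd = 0.4,
                                 seed = 21)
  C <- cor(null_ts$values)
  expect_lt(max(abs(C[upper.tri(C)])), 0.03)
  # single strong edge: sign and magnitude recovered at large t
  W1 <- matrix(0, 4, 4); W1[1, 2] <- W1[2, 1] <- 0.6
  pop <- population_correlation(W1, noise_sd = 0.3)
  ts1 <- simulate_timeseries(W1, t = 5000, noise_sd = 0.3, seed = 22)
  C1 <- cor(ts1$values)
  expect_gt(C1[1, 2], 0)
  expect_lt(max(abs(C1 - pop)), 3 / sqrt(5000))
  # random sparse truth, elementwise error below 3/sqrt(t)
  gt <- make_ground_truth(10, density = 0.25, seed = 23)
  popg <- population_correlation(gt, noise_sd = 0.5)
  tsg <- simulate_timeseries(gt, t = 4000, noise_sd = 0.5, seed = 24)
  expect_lt(max(abs(cor(tsg$values) - popg)), 3 / sqrt(4000))
})

test_that("diagonal loading keeps the covariance well conditioned", {
  gt <- make_ground_truth(30, "hub", density = 0.1, hub_count = 3, seed = 31)
  pop <- population_correlation(gt, noise_sd = 0)
  ev <- eigen(pop, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("cohorts inject the group effect only at the recorded edges", {
  gt <- make_ground_truth(12, density = 0.2, seed = 41)
  coh <- make_cohort(gt, n_pos = 3, n_neg = 4, differential_edges = 6,
                     effect = 0.5, t = 30, seed = 42)
  expect_equal(as.integer(table(coh$labels)), c(4L, 3L))  # negative, positive
  diffs <- coh$truth$W_positive - gt$W_true
  hit <- which(abs(diffs) > 0 & upper.tri(diffs), arr.ind = TRUE)
  expect_equal(nrow(hit), 6L)
  recorded <- as.matrix(coh$truth$differential)
  expect_setequal(paste(hit[, 1], hit[, 2]),
                  paste(recorded[, 1], recorded[, 2]))
  expect_true(all(abs(diffs[abs(diffs) > 0] - 0.5) < 1e-12))
  # effect = 0 leaves the two group covariances identical
  null_coh <- make_cohort(gt, n_pos = 3, n_neg = 3, differential_edges = 6,
                          effect = 0, t = 30, seed = 43)
  expect_equal(null_coh$truth$W_positive, gt$W_true)
})
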