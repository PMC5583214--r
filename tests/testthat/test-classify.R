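test_that("feature extraction walks the upper triangle row-major", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.1
  W[1, 3] <- W[3, 1] <- 0.2
  W[2, 3] <- W[3, 2] <- 0.3
  expect_equal(extract_features(W), c(0.1, 0.2, 0.3))
  idx <- feature_index(3)
  expect_equal(idx$i, c(1, 1, 2))
  expect_equal(idx$j, c(2, 3, 3))
  # length for the 116-ROI atlas
  W116 <- matrix(0, 116, 116)
  expect_length(extract_features(W116), 116 * 115 / 2)
  # reconstruction round-trip
  set.seed(2)
  Wr <- rand_sym_sparse(9, 0.5, 2)
  expect_equal(features_to_network(extract_features(Wr))$W,
               fbn_network(Wr)$W)
  Wa <- Wr; Wa[1, 2] <- Wa[1, 2] + 1
  expect_error(extract_features(Wa), "asymmetric")
})

test_that("t-test screen selects planted effects and drops degenerate features", {
  set.seed(101)
  n1 <- 20; n2 <- 20
  X <- cbind(
    c(rnorm(n1, 5), rnorm(n2, 0)),  # huge effect
    rnorm(n1 + n2),                 # null
    rep(1.5, n1 + n2)               # zero variance
  )
  labels <- c(rep("positive", n1), rep("negative", n2))
  res <- ttest_filter(X, labels, alpha = 0.05)
  expect_true(res$mask[1])
  expect_false(res$mask[3])
  expect_true(is.na(res$p_values[3]))
  # matches stats::t.test with pooled variance
  ref <- t.test(X[1:n1, 1], X[(n1 + 1):(n1 + n2), 1], var.equal = TRUE)
  expect_equal(res$p_values[1], ref$p.value, tolerance = 1e-12)
  refw <- t.test(X[1:n1, 2], X[(n1 + 1):(n1 + n2), 2])
  resw <- ttest_filter(X, labels, var_equal = FALSE)
  expect_equal(resw$p_values[2], refw$p.value, tolerance = 1e-12)
  expect_error(ttest_filter(X, rep("positive", 40)), "both classes")
})

test_that("an empty screen falls back to the single best feature", {
  set.seed(102)
  X <- matrix(rnorm(30 * 40), 30, 40)
  labels <- rep(c("positive", "negative"), 15)
  res <- ttest_filter(X, labels, alpha = 1e-9)
  expect_true(res$fallback_used)
  expect_equal(res$n_selected, 1L)
  expect_equal(which(res$mask), which.min(res$p_values))
})

test_that("classification metrics implement the three ratios with NA guards", {
  m <- classification_metrics(confusion_counts(1, 0, 1, 0))
  expect_equal(c(m$accuracy, m$sensitivity, m$specificity), c(1, 1, 1))
  m2 <- classification_metrics(confusion_counts(0, 2, 3, 5))
  expect_equal(m2$sensitivity, 0)
  m3 <- classification_metrics(confusion_counts(0, 0, 5, 0))
  expect_true(is.na(m3$sensitivity))  # no positives: undefined, not zero
  expect_equal(m3$specificity, 1)
  # accuracy * N identity on random integer counts
  set.seed(5)
  for (k in 1:10) {
    c4 <- as.list(sample(0:30, 4, replace = TRUE))
    if (sum(unlist(c4)) == 0) next
    mm <- classification_metrics(do.call(confusion_counts, c4))
    expect_equal(mm$accuracy * sum(unlist(c4)), c4[[1]] + c4[[3]])
  }
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")
})

test_that("nested LOO separates a strong-effect cohort and is deterministic", {
  gt <- make_ground_truth(10, density = 0.2, seed = 61)
  coh <- make_cohort(gt, n_pos = 6, n_neg = 6, differential_edges = 8,
                     effect = 0.9, t = 120, seed = 62)
  rep1 <- loo_evaluate(coh, "pc-sparsity", grid = c(0.2, 0.6))
  expect_equal(rep1$metrics$accuracy, 1)
  rep2 <- loo_evaluate(coh, "pc-sparsity", grid = c(0.2, 0.6))
  expect_identical(rep1$folds, rep2$folds)
  expect_identical(rep1$metrics$counts, rep2$metrics$counts)
  expect_true(all(rep1$folds$parameter %in% c(0.2, 0.6)))
})

test_that("per-fold feature selection is a function of training subjects only", {
  gt <- make_ground_truth(8, density = 0.3, seed = 71)
  coh <- make_cohort(gt, n_pos = 5, n_neg = 5, differential_edges = 5,
                     effect = 0.8, t = 80, seed = 72)
  rep <- loo_evaluate(coh, "pc_sparsity", grid = c(0.3, 0.7))
  labels <- as.character(coh$labels)
  # recompute each fold's screen from scratch, held-out subject excluded
  for (o in c(1, 4, 8)) {
    lam <- rep$folds$parameter[o]
    feats <- t(vapply(coh$subjects, function(s) {
      extract_features(estimate_pc_sparsity(standardize_columns(s), lam))
    }, numeric(choose(8, 2))))
    train <- setdiff(seq_len(10), o)
    screen <- ttest_filter(feats[train, ], labels[train], alpha = 0.05)
    expect_identical(rep$selected[[o]], which(screen$mask))
  }
})

test_that("the parameter sweep returns one accuracy per grid value", {
  gt <- make_ground_truth(8, density = 0.3, seed = 81)
  coh <- make_cohort(gt, n_pos = 4, n_neg = 4, differential_edges = 5,
                     effect = 0.9, t = 80, seed = 82)
  sweep <- parameter_sweep(coh, "pc_threshold", grid = c(30, 60, 90))
  expect_equal(sweep$parameter, c(30, 60, 90))
  expect_true(all(sweep$accuracy >= 0 & sweep$accuracy <= 1))
})
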