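# Shared fixtures, built in code at test time.

# Random standardized time series (pure function of the seed).
rand_std <- function(t, n, seed) {
  set.seed(seed)
  standardize_columns(matrix(rnorm(t * n), t, n))
}

# Random symmetric zero-diagonal matrix with approximately the given
# density of nonzero (upper-triangle) entries.
rand_sym_sparse <- function(n, density, seed) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  nz <- ut[runif(length(ut)) < density]
  W[nz] <- runif(length(nz), -1, 1)
  W + t(W)
}

# Standardized matrix with mutually orthogonal columns: QR of a centered
# random matrix gives orthonormal columns that stay orthogonal to the
# 1-vector (hence centered) with unit norm.
orthogonal_std <- function(t, n, seed) {
  set.seed(seed)
  M <- scale(matrix(rnorm(t * n), t, n), center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(M))[, seq_len(n), drop = FALSE]
  fbn_timeseries(Q, standardized = TRUE)
}

# A small deterministic hub-cohort standardized subject for estimator tests.
hub_subject <- function(seed, n = 116, t = 170) {
  gt <- make_ground_truth(n, "hub", seed = seed)
  standardize_columns(simulate_timeseries(gt, t = t, seed = seed + 5000))
}
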