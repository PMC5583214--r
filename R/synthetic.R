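# Synthetic cohorts with known ground truth. Defaults mirror the scale of a
# typical single-site resting-state study: 170 time points x 116 ROIs and
# 45 positive / 47 negative subjects.

#' Generate a ground-truth network
#'
#' `"random_sparse"` places edges uniformly at random at the requested
#' density (Erdos-Renyi support). `"hub"` first designates `hub_count` hub
#' nodes and wires each to `hub_multiple` times the mean degree implied by
#' `density`, then fills the remaining edge budget among non-hub pairs, so
#' the designated hubs carry the largest degrees by construction. Edge
#' weights are uniform in magnitude on `weight_range` with random sign;
#' the diagonal is zero.
#'
#' @param n number of nodes (>= 2); default 116 ROIs.
#' @param topology `"random_sparse"` or `"hub"`.
#' @param density fraction of the n(n-1)/2 node pairs carrying an edge, in
#'   (0, 1\].
#' @param hub_count number of hub nodes (hub topology), < n.
#' @param hub_multiple hub degree as a multiple of the mean degree
#'   `density * (n - 1)`.
#' @param weight_range magnitude range for edge weights.
#' @param seed integer seed; the result is a pure function of the
#'   arguments.
#' @return object of class `fbn_ground_truth`: list with `W_true`,
#'   `topology`, `hub_nodes`, `density` (achieved), `seed`.
#' @export
make_ground_truth <- function(n = 116, topology = c("random_sparse", "hub"),
                              density = 0.05, hub_count = 8,
                              hub_multiple = 6, weight_range = c(0.2, 0.8),
                              seed = NULL) {
  topology <- match.arg(topology)
  if (n < 2) stop_fbn("n must be >= 2")
  if (density <= 0 || density > 1) stop_fbn("density must be in (0, 1]")
  if (topology == "hub" && hub_count >= n) stop_fbn("hub_count must be < n")
  with_seed(seed, {
    pairs <- upper_pairs(n)
    m_total <- max(1L, round(density * nrow(pairs)))
    hub_nodes <- integer(0)
    if (topology == "random_sparse") {
      chosen <- sample.int(nrow(pairs), m_total)
    } else {
      hub_nodes <- sort(sample.int(n, hub_count))
      target <- min(n - 1L, max(1L, round(hub_multiple * density * (n - 1))))
      sel <- matrix(FALSE, n, n)
      for (h in hub_nodes) {
        others <- setdiff(seq_len(n), h)
        partners <- others[sample.int(length(others), target)]
        sel[cbind(pmin(h, partners), pmax(h, partners))] <- TRUE
      }
      # fill any remaining budget among non-hub pairs
      remaining <- m_total - sum(sel)
      if (remaining > 0) {
        nonhub <- which(!(pairs[, 1L] %in% hub_nodes) &
                          !(pairs[, 2L] %in% hub_nodes) &
                          !sel[pairs])
        chosen_fill <- nonhub[sample.int(length(nonhub),
                                         min(remaining, length(nonhub)))]
        sel[pairs[chosen_fill, , drop = FALSE]] <- TRUE
      }
      chosen <- which(sel[pairs])
    }
    W <- matrix(0, n, n)
    m <- length(chosen)
    w <- runif(m, weight_range[1L], weight_range[2L]) *
      sample(c(-1, 1), m, replace = TRUE)
    ij <- pairs[chosen, , drop = FALSE]
    W[ij] <- w
    W[ij[, c(2L, 1L), drop = FALSE]] <- w
    structure(
      list(W_true = W, topology = topology, hub_nodes = hub_nodes,
           density = m / nrow(pairs), seed = seed),
      class = "fbn_ground_truth"
    )
  })
}

#' @export
print.fbn_ground_truth <- function(x, ...) {
  cat(sprintf("ground-truth network [%s]: %d nodes, %d edges (density %.3f)",
              x$topology, ncol(x$W_true),
              sum(abs(upper_values(x$W_true)) > 0), x$density))
  if (length(x$hub_nodes) > 0) {
    cat(", hubs:", paste(x$hub_nodes, collapse = " "))
  }
  cat("\n")
  invisible(x)
}

# Diagonal loading that makes W + delta * I positive definite with smallest
# eigenvalue >= min_eigen. W has zero diagonal (trace 0), so its smallest
# eigenvalue is <= 0 and delta is always positive.
conditioning_delta <- function(W, min_eigen = 0.1) {
  lmin <- min(eigen(W, symmetric = TRUE, only.values = TRUE)$values)
  min_eigen - min(lmin, 0)
}

# Signal covariance implied by a ground-truth network.
signal_covariance <- function(net, delta = NULL, min_eigen = 0.1) {
  W <- if (inherits(net, "fbn_ground_truth")) net$W_true else as.matrix(net)
  if (is.null(delta)) delta <- conditioning_delta(W, min_eigen)
  list(sigma = W + delta * diag(ncol(W)), delta = delta)
}

#' Population correlation of the simulated signal
#'
#' Closed-form correlation matrix of the data generated by
#' [simulate_timeseries()]: cov2cor(W_true + delta I + noise_sd^2 I). This
#' is the quantity the sample Pearson network converges to as t grows, and
#' serves as the oracle in generator-validation tests.
#'
#' @param net an `fbn_ground_truth` (or symmetric zero-diagonal matrix).
#' @param noise_sd observation-noise standard deviation used in the
#'   simulation.
#' @param delta diagonal loading; computed from the smallest eigenvalue
#'   (floor 0.1) when `NULL`, matching [simulate_timeseries()].
#' @return n x n correlation matrix.
#' @export
population_correlation <- function(net, noise_sd = 0.5, delta = NULL) {
  sc <- signal_covariance(net, delta)
  stats::cov2cor(sc$sigma + noise_sd^2 * diag(ncol(sc$sigma)))
}

#' Simulate an ROI time series from a ground-truth network
#'
#' Draws `t` samples from a zero-mean multivariate normal with covariance
#' Sigma = W_true + delta I, where delta lifts the smallest eigenvalue to
#' 0.1 (diagonal loading keeps Sigma well conditioned so the implied
#' population correlations are stable oracles), then adds independent
#' N(0, noise_sd^2) observation noise. Samples are independent in time by
#' default — every estimator in the package is a function of the sample
#' covariance only, so temporal autocorrelation would add realism but no
#' test power; `ar` > 0 applies an AR(1) filter (stationary marginal
#' covariance preserved) for users who want BOLD-like smoothness.
#'
#' @param net an `fbn_ground_truth` (or symmetric zero-diagonal matrix).
#' @param t number of time points; default 170.
#' @param noise_sd observation-noise standard deviation; default 0.5.
#' @param seed integer seed; output is a pure function of arguments.
#' @param delta override the automatic diagonal loading (used by
#'   [make_cohort()] to share one loading across groups).
#' @param ar AR(1) coefficient in \[0, 1); 0 disables temporal filtering.
#' @param subject_id identifier for the returned series.
#' @return an [fbn_timeseries] (raw, not standardized).
#' @export
simulate_timeseries <- function(net, t = 170, noise_sd = 0.5, seed = NULL,
                                delta = NULL, ar = 0,
                                subject_id = "synthetic") {
  if (t < 2) stop_fbn("t must be >= 2")
  if (noise_sd < 0) stop_fbn("noise_sd must be >= 0")
  if (ar < 0 || ar >= 1) stop_fbn("ar must be in [0, 1)")
  sc <- signal_covariance(net, delta)
  n <- ncol(sc$sigma)
  with_seed(seed, {
    signal <- MASS::mvrnorm(t, mu = rep(0, n), Sigma = sc$sigma)
    if (ar > 0) {
      # AR(1) with innovations scaled so the marginal covariance stays Sigma
      innov <- signal * sqrt(1 - ar^2)
      for (k in 2L:t) signal[k, ] <- ar * signal[k - 1L, ] + innov[k, ]
    }
    noise <- matrix(rnorm(t * n, sd = noise_sd), t, n)
    fbn_timeseries(signal + noise, subject_id = subject_id)
  })
}

#' Simulate a two-group cohort with differential edges
#'
#' The negative (control) group is simulated from `base_net`; the positive
#' group from a copy in which `effect` is added to `differential_edges`
#' randomly chosen node pairs. Both groups share a single diagonal loading
#' (computed from whichever group covariance is worse conditioned), so
#' non-differential covariance entries are identical across groups and the
#' only systematic group difference lies in the chosen edges. The chosen
#' pairs are recorded for power analyses. With `effect = 0` the groups are
#' exchangeable and downstream classification accuracy is at chance.
#'
#' @param base_net an `fbn_ground_truth` for the control group.
#' @param n_pos,n_neg group sizes; defaults 45 / 47.
#' @param differential_edges number of node pairs receiving the group
#'   effect; default 30.
#' @param effect weight added to each differential edge in the positive
#'   group; default 0.5.
#' @param t time points per subject; default 170.
#' @param noise_sd observation-noise standard deviation; default 0.5.
#' @param seed integer seed; the cohort is a pure function of arguments.
#' @return an `fbn_cohort` whose `truth` element records `base_net`,
#'   `W_positive`, `differential` (data frame of i, j pairs), `effect`,
#'   `delta`, `noise_sd`, `seed`.
#' @export
make_cohort <- function(base_net, n_pos = 45, n_neg = 47,
                        differential_edges = 30, effect = 0.5, t = 170,
                        noise_sd = 0.5, seed = NULL) {
  stopifnot(inherits(base_net, "fbn_ground_truth"))
  W_neg <- base_net$W_true
  n <- ncol(W_neg)
  pairs <- upper_pairs(n)
  if (differential_edges < 0 || differential_edges > nrow(pairs)) {
    stop_fbn("differential_edges must be between 0 and n(n-1)/2")
  }
  with_seed(seed, {
    sel <- if (differential_edges > 0) {
      sample.int(nrow(pairs), differential_edges)
    } else {
      integer(0)
    }
    W_pos <- W_neg
    ij <- pairs[sel, , drop = FALSE]
    W_pos[ij] <- W_pos[ij] + effect
    W_pos[ij[, c(2L, 1L), drop = FALSE]] <-
      W_pos[ij[, c(2L, 1L), drop = FALSE]] + effect
    # one loading for both groups: group membership must not show up in the
    # diagonal, only in the differential edges
    delta <- max(conditioning_delta(W_neg), conditioning_delta(W_pos))
    if (min(eigen(W_pos + delta * diag(n), symmetric = TRUE,
                  only.values = TRUE)$values) <= 0) {
      stop_fbn("effect breaks positive definiteness even after loading; ",
               "reduce effect or differential_edges")
    }
    ids <- c(sprintf("POS_%03d", seq_len(n_pos)),
             sprintf("NEG_%03d", seq_len(n_neg)))
    labels <- c(rep("positive", n_pos), rep("negative", n_neg))
    nets <- c(rep(list(W_pos), n_pos), rep(list(W_neg), n_neg))
    subjects <- lapply(seq_along(ids), function(k) {
      simulate_timeseries(nets[[k]], t = t, noise_sd = noise_sd,
                          delta = delta, subject_id = ids[k])
    })
    names(subjects) <- ids
    truth <- list(base_net = base_net, W_positive = W_pos,
                  differential = as.data.frame(ij), effect = effect,
                  delta = delta, noise_sd = noise_sd, seed = seed)
    fbn_cohort(subjects, labels, truth = truth)
  })
}
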