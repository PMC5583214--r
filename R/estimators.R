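#' Solver configuration for the proximal estimators
#'
#' @param step_alpha gradient step size in (0, 1]. The data-fidelity term
#'   ||W - S||_F^2 has gradient 2(W - S); a step of `step_alpha` contracts
#'   the iterate towards S by a factor |1 - 2 * step_alpha|, so the default
#'   1/2 lands on S in a single step and the proximal fixed point is the
#'   exact minimizer.
#' @param tol convergence tolerance on the relative Frobenius change between
#'   successive iterates.
#' @param max_iter maximum inner (proximal-gradient) iterations.
#' @param epsilon degree regularizer for [gamma_weights()]; keeps the
#'   denominators 1/(d_i + epsilon) finite for isolated nodes. Default
#'   0.0001.
#' @param outer_max_iter maximum outer alternations for
#'   [estimate_pc_scale_free()].
#' @param legacy_prox logical; if `TRUE`, apply the proximal shrinkage with
#'   parameter `lambda` itself each iteration (the literal pseudocode
#'   convention) rather than `step_alpha * lambda`. The fixed point is then
#'   the soft threshold at `lambda` instead of `lambda/2`; equivalent to
#'   rescaling the grid by 2. Off by default: the default convention solves
#'   the stated objective exactly.
#' @param seed optional integer seed recorded for provenance (the solvers
#'   themselves are deterministic).
#' @return a list of class `fbn_solver_config`.
#' @export
solver_config <- function(step_alpha = 0.5, tol = 1e-6, max_iter = 1000L,
                          epsilon = 1e-4, outer_max_iter = 50L,
                          legacy_prox = FALSE, seed = NULL) {
  if (!is.numeric(step_alpha) || step_alpha <= 0 || step_alpha > 1) {
    stop_fbn("step_alpha must be in (0, 1]")
  }
  if (!is.numeric(tol) || tol <= 0) stop_fbn("tol must be > 0")
  if (max_iter < 1L) stop_fbn("max_iter must be >= 1")
  if (!is.numeric(epsilon) || epsilon <= 0) stop_fbn("epsilon must be > 0")
  if (outer_max_iter < 1L) stop_fbn("outer_max_iter must be >= 1")
  structure(
    list(step_alpha = step_alpha, tol = tol, max_iter = as.integer(max_iter),
         epsilon = epsilon, outer_max_iter = as.integer(outer_max_iter),
         legacy_prox = isTRUE(legacy_prox), seed = seed),
    class = "fbn_solver_config"
  )
}

# Symmetrize, clamp correlations into [-1, 1] (float dust only), zero the
# diagonal. Shared finalizer for the PC-family estimators.
finalize_pc_matrix <- function(W) {
  W <- (W + t(W)) / 2
  W <- pmin(pmax(W, -1), 1)
  diag(W) <- 0
  W
}

#' Pearson correlation network
#'
#' For column-standardized data the correlation matrix is W = X'X, which is
#' also the minimizer of ||W - X'X||_F^2 — the optimization view that the
#' penalized estimators build on. The diagonal (self-correlation) is zeroed
#' on output.
#'
#' @param xs standardized time series (output of [standardize_columns()]).
#' @return an [fbn_network] with estimator tag `"pc"`.
#' @examples
#' xs <- standardize_columns(matrix(rnorm(200), 50, 4))
#' net <- pearson_network(xs)
#' max(abs(net$W - t(net$W)))  # symmetric
#' @export
pearson_network <- function(xs) {
  xs <- assert_standardized(xs)
  W <- finalize_pc_matrix(crossprod(xs$values))
  fbn_network(W, estimator = "pc", roi_labels = xs$roi_labels,
              iterations = 0L, converged = TRUE)
}

#' Hard-threshold sparsification of a network
#'
#' Keeps the `sparsity_percent`\% strongest edges and zeroes the rest,
#' leaving the surviving weights untouched. "Strongest" means largest
#' |W_ij| by default, so strong negative correlations survive; with
#' `signed = TRUE` edges are ranked by their signed value instead, which
#' deletes all negative edges at high sparsification (the literal
#' "W_ij > threshold" convention). A sparsity level of 90 means the weakest
#' 10\% of edges are filtered out. Exactly
#' k = round(sparsity_percent/100 * n(n-1)/2) unordered pairs are retained;
#' rank ties are broken by (i, j) lexicographic order for reproducibility.
#'
#' @param net an [fbn_network] or symmetric matrix.
#' @param sparsity_percent percentage of edges to keep, in (0, 100].
#' @param signed rank by signed value instead of absolute value.
#' @return an [fbn_network] with estimator tag `"pc_threshold"`.
#' @export
hard_threshold_network <- function(net, sparsity_percent, signed = FALSE) {
  if (!is.numeric(sparsity_percent) || length(sparsity_percent) != 1L ||
      sparsity_percent <= 0 || sparsity_percent > 100) {
    stop_fbn("sparsity_percent must be in (0, 100]")
  }
  net <- as_connectivity(net)
  W <- net$W
  n <- ncol(W)
  pairs <- upper_pairs(n)
  vals <- upper_values(W)
  key <- if (signed) vals else abs(vals)
  k <- round(sparsity_percent / 100 * nrow(pairs))
  keep <- head(order(-key, pairs[, 1L], pairs[, 2L]), k)
  out <- matrix(0, n, n)
  ik <- pairs[keep, , drop = FALSE]
  out[ik] <- vals[keep]
  out[ik[, c(2L, 1L), drop = FALSE]] <- vals[keep]
  fbn_network(out, estimator = "pc_threshold", roi_labels = net$roi_labels,
              threshold = sparsity_percent, iterations = 0L, converged = TRUE)
}

#' Soft-threshold (L1 proximal) operator
#'
#' Elementwise shrinkage sgn(w) * max(|w| - tau, 0): the proximal operator
#' of the L1 norm and the exact solution of the scalar penalized problem
#' min_x (x - w)^2 + 2 tau |x|.
#'
#' @param W numeric matrix (or vector).
#' @param tau threshold, >= 0.
#' @return object of the same shape as `W`.
#' @examples
#' soft_threshold(c(-0.9, 0.2, 0.9), 0.3)
#' @export
soft_threshold <- function(W, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) {
    stop_fbn("tau must be a single number >= 0")
  }
  sign(W) * pmax(abs(W) - tau, 0)
}

#' Weighted soft-threshold operator
#'
#' Elementwise sgn(w_ij) * max(|w_ij| - tau * gamma_ij, 0): the proximal
#' operator of the weighted L1 penalty sum gamma_ij |W_ij|. With all
#' weights 1 it reduces to [soft_threshold()]; a zero weight passes the
#' entry through unshrunk.
#'
#' @param W numeric matrix.
#' @param tau threshold, >= 0.
#' @param gamma non-negative weight matrix, same shape as `W`.
#' @return matrix of the same shape as `W`.
#' @export
weighted_soft_threshold <- function(W, tau, gamma) {
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0) {
    stop_fbn("tau must be a single number >= 0")
  }
  gamma <- as.matrix(gamma)
  if (!identical(dim(as.matrix(W)), dim(gamma))) {
    stop_fbn("gamma must have the same shape as W")
  }
  if (any(gamma < 0)) stop_fbn("gamma weights must be >= 0")
  sign(W) * pmax(abs(W) - tau * gamma, 0)
}

# Proximal-gradient loop for min ||W - S||_F^2 + penalty, with shrinkage
# given by prox(W, tau). Shared by the sparsity and (inner step of the)
# scale-free estimators.
prox_gradient_pc <- function(S, cfg, prox_tau, prox_fun) {
  W <- S
  a <- cfg$step_alpha
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    W_new <- prox_fun((1 - 2 * a) * W + 2 * a * S, prox_tau)
    if (rel_frobenius_change(W_new, W) < cfg$tol) {
      W <- W_new
      converged <- TRUE
      break
    }
    W <- W_new
    if (iter >= cfg$max_iter) break
  }
  list(W = W, iterations = iter, converged = converged)
}

#' Sparse correlation network (L1-penalized Pearson)
#'
#' Solves min_W ||W - X'X||_F^2 + lambda ||W||_1 by proximal gradient
#' descent (gradient step on the quadratic fidelity, then elementwise soft
#' thresholding). The problem is separable, so the minimizer has the closed
#' form soft_threshold(X'X, lambda/2); the iterative solver converges to it
#' and is retained because it generalizes to the weighted penalty of
#' [estimate_pc_scale_free()]. At lambda = 0 the estimator reduces exactly
#' to [pearson_network()].
#'
#' With `cfg$legacy_prox = TRUE` the per-iteration shrinkage uses `lambda`
#' rather than `step_alpha * lambda`, reproducing the looser pseudocode
#' convention whose fixed point is soft_threshold(X'X, lambda); this merely
#' rescales the lambda grid by 2.
#'
#' @param xs standardized time series.
#' @param lambda L1 penalty weight, >= 0; larger values give sparser
#'   networks.
#' @param cfg a [solver_config()].
#' @return an [fbn_network] with estimator tag `"pc_sparsity"`; `converged`
#'   is `FALSE` (with a warning) if `max_iter` was exhausted.
#' @examples
#' xs <- standardize_columns(matrix(rnorm(400), 50, 8))
#' net <- estimate_pc_sparsity(xs, lambda = 0.4)
#' max(abs(net$W - soft_threshold(crossprod(xs$values), 0.2)) *
#'     (1 - diag(8)))  # closed form, off-diagonal
#' @export
estimate_pc_sparsity <- function(xs, lambda, cfg = solver_config()) {
  xs <- assert_standardized(xs)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop_fbn("lambda must be a single number >= 0")
  }
  S <- crossprod(xs$values)
  tau <- if (cfg$legacy_prox) lambda else cfg$step_alpha * lambda
  fit <- prox_gradient_pc(S, cfg, tau, soft_threshold)
  if (!fit$converged) {
    warning("PC-sparsity solver did not converge in ", cfg$max_iter,
            " iterations", call. = FALSE)
  }
  W <- finalize_pc_matrix(fit$W)
  S0 <- S
  diag(S0) <- 0  # objective reported over the off-diagonal (diagonal fixed 0)
  obj <- norm(W - S0, "F")^2 + lambda * sum(abs(W))
  fbn_network(W, estimator = "pc_sparsity", roi_labels = xs$roi_labels,
              lambda = lambda, iterations = fit$iterations,
              converged = fit$converged, objective = obj)
}

#' Degree-based penalty weights for the scale-free prior
#'
#' Computes gamma_ij = exp(-(1/(d_i + epsilon) + 1/(d_j + epsilon))) where
#' d_i = sum_\{z != i\} |W_iz| is the weighted degree of node i (diagonal
#' excluded: a self-connection is not a connection). The weights couple the
#' per-edge shrinkage of [estimate_pc_scale_free()] to the current degree
#' sequence, which is what lets the alternation reshape the degree
#' distribution rather than shrink every edge uniformly.
#'
#' @details As a function of degree the weight is monotonically increasing
#' (gamma -> 1 as d -> Inf, gamma -> exp(-2/epsilon), which underflows to
#' exactly 0 at the default epsilon = 0.0001, as d -> 0). Entries therefore
#' lie in \[0, 1), are symmetric by construction, and an all-zero network
#' yields gamma identically 0 — "shrink nothing next iteration". Isolated
#' nodes thus escape shrinkage entirely; epsilon is the only guard on that
#' behaviour, exactly as specified by the weight formula.
#'
#' @param net an [fbn_network] or square matrix.
#' @param epsilon small positive constant guarding the 1/d denominators;
#'   default 0.0001.
#' @return symmetric n x n weight matrix with attribute `"epsilon"`.
#' @examples
#' W <- matrix(c(0, .5, .5, 0), 2, 2)
#' gamma_weights(W)  # exp(-2 / (0.5 + 1e-4)) on the off-diagonal
#' @export
gamma_weights <- function(net, epsilon = 1e-4) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
    stop_fbn("epsilon must be a single number > 0")
  }
  W <- as_connectivity(net)$W
  d <- rowSums(abs(W)) - abs(diag(W))  # weighted degree, diagonal excluded
  inv <- 1 / (d + epsilon)
  G <- exp(-outer(inv, inv, "+"))
  attr(G, "epsilon") <- epsilon
  G
}

#' Scale-free correlation network (degree-reweighted L1)
#'
#' Solves min_W ||W - X'X||_F^2 + lambda * sum_ij gamma_ij |W_ij| where the
#' weights gamma_ij are a function of the node degrees of W itself
#' ([gamma_weights()]), so the penalty adapts to the degree sequence of the
#' solution. The target is a self-consistent pair: W* minimizes the
#' weighted problem at gamma* = gamma_weights(W*).
#'
#' The naive alternation — full weighted-soft-threshold solve, then gamma
#' refresh — is an undamped fixed-point iteration and falls into a
#' period-2 dense/sparse oscillation whenever thresholding collapses the
#' weighted-degree scale (small degrees push gamma toward 0, which
#' resurrects every edge, which pushes gamma back up). The solver here is
#' the damped form: each iteration takes a single proximal-gradient step
#' (gradient step on the fidelity at `cfg$step_alpha` < 1/2, then weighted
#' soft thresholding at `step_alpha * lambda * gamma`), followed by a gamma
#' refresh from the new iterate. Because the iterate retains memory of its
#' predecessor, the scheme converges to the same self-consistent fixed
#' points that the full alternation orbits around. With gamma frozen, a
#' step never increases the penalized objective (step size <= 1/L for the
#' quadratic fidelity); the `monotone_descent` field records that this held
#' along the whole trajectory.
#'
#' At lambda = 0 the estimator reduces exactly to [pearson_network()];
#' with `update_gamma = FALSE` the weights stay at their all-ones
#' initialization and the estimator coincides with
#' [estimate_pc_sparsity()] at the same lambda.
#'
#' @inheritParams estimate_pc_sparsity
#' @param cfg a [solver_config()]; the scale-free default uses
#'   `step_alpha = 0.25` (damping requires < 1/2; at exactly 1/2 the
#'   gradient step erases the iterate's memory and the scheme degenerates
#'   to the oscillating alternation). Iterations are capped at
#'   `cfg$outer_max_iter` (each iteration is one cheap O(n^2) update).
#' @param update_gamma refresh the degree weights each iteration (default);
#'   `FALSE` freezes gamma at all ones.
#' @return an [fbn_network] with estimator tag `"pc_scale_free"`, an
#'   `objective` trace (penalized objective of each iterate under the
#'   gamma in force when it was produced), and a `monotone_descent` flag.
#' @export
estimate_pc_scale_free <- function(xs, lambda,
                                   cfg = solver_config(step_alpha = 0.25,
                                                       outer_max_iter = 300L),
                                   update_gamma = TRUE) {
  xs <- assert_standardized(xs)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop_fbn("lambda must be a single number >= 0")
  }
  S <- crossprod(xs$values)
  diag(S) <- 0  # solve over off-diagonal entries; diagonal is fixed at 0
  n <- ncol(S)
  a <- cfg$step_alpha
  tau0 <- if (cfg$legacy_prox) lambda else a * lambda
  obj_at <- function(W, gamma) {
    norm(W - S, "F")^2 + lambda * sum(gamma * abs(W))
  }
  gamma <- matrix(1, n, n)
  W <- S
  converged <- FALSE
  monotone <- TRUE
  objective <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    W_new <- weighted_soft_threshold((1 - 2 * a) * W + 2 * a * S, tau0, gamma)
    diag(W_new) <- 0
    if (obj_at(W_new, gamma) > obj_at(W, gamma) + 1e-10) monotone <- FALSE
    objective <- c(objective, obj_at(W_new, gamma))
    if (rel_frobenius_change(W_new, W) < cfg$tol) {
      W <- W_new
      converged <- TRUE
      break
    }
    W <- W_new
    if (iter >= cfg$outer_max_iter) break
    if (update_gamma && lambda > 0) gamma <- gamma_weights(W, cfg$epsilon)
  }
  if (!converged) {
    warning("PC-scale-free solver did not converge in ",
            cfg$outer_max_iter, " iterations (oscillating weights); ",
            "returning the last iterate", call. = FALSE)
  }
  W <- finalize_pc_matrix(W)
  net <- fbn_network(W, estimator = "pc_scale_free",
                     roi_labels = xs$roi_labels, lambda = lambda,
                     iterations = iter, converged = converged,
                     objective = objective)
  net$monotone_descent <- monotone
  net
}

#' Sparse representation (regression-based) network
#'
#' Solves the lasso-style regression model
#' min_W ||X - XW||_F^2 + lambda ||W||_1 subject to W_ii = 0, in which each
#' ROI's time course is sparsely represented by the others — a
#' partial-correlation-flavoured alternative to the correlation-based
#' estimators. Solved by proximal gradient with step 1/(2 * sigma_max(X'X))
#' (the inverse Lipschitz constant of the fidelity gradient 2 X'(XW - X)),
#' soft thresholding, and re-projection of the diagonal to zero after every
#' step; the objective is monotone non-increasing along the iterations.
#'
#' The raw solution is asymmetric (W_ij is a regression coefficient of ROI
#' j on ROI i). Because the downstream pipeline expects symmetric
#' networks, the output is symmetrized as (W + W')/2 by default and flagged
#' via the `symmetrized` field; set `symmetrize = FALSE` to inspect the raw
#' coefficients.
#'
#' @inheritParams estimate_pc_sparsity
#' @param lambda L1 penalty weight; lambda > 0 is strongly recommended (the
#'   unpenalized problem is ill-posed whenever t < n).
#' @param symmetrize return (W + W')/2 (default) or the raw asymmetric
#'   solution.
#' @return an [fbn_network] with estimator tag `"sr"` and an `objective`
#'   trace (one value per iteration).
#' @export
estimate_sr <- function(xs, lambda, cfg = solver_config(),
                        symmetrize = TRUE) {
  xs <- assert_standardized(xs)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop_fbn("lambda must be a single number >= 0")
  }
  X <- xs$values
  S <- crossprod(X)
  n <- ncol(S)
  L <- 2 * max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  step <- 1 / L
  sr_objective <- function(W) {
    norm(X - X %*% W, "F")^2 + lambda * sum(abs(W))
  }
  W <- matrix(0, n, n)
  objective <- sr_objective(W)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    grad <- 2 * (S %*% W - S)
    W_new <- soft_threshold(W - step * grad, step * lambda)
    diag(W_new) <- 0
    objective <- c(objective, sr_objective(W_new))
    if (rel_frobenius_change(W_new, W) < cfg$tol) {
      W <- W_new
      converged <- TRUE
      break
    }
    W <- W_new
    if (iter >= cfg$max_iter) break
  }
  if (!converged) {
    warning("SR solver did not converge in ", cfg$max_iter, " iterations",
            call. = FALSE)
  }
  if (symmetrize) W <- (W + t(W)) / 2
  diag(W) <- 0
  fbn_network(W, estimator = "sr", roi_labels = xs$roi_labels,
              lambda = lambda, iterations = iter, converged = converged,
              symmetrized = symmetrize, objective = objective)
}
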