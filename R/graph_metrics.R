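#' Node degrees of a network
#'
#' Binary mode counts, per node, the off-diagonal entries with
#' |W_ij| > `zero_tol`; weighted mode sums |W_ij| over z != i. The diagonal
#' never contributes.
#'
#' @param net an [fbn_network] or square matrix.
#' @param mode `"binary"` or `"weighted"`.
#' @param zero_tol magnitude below which an entry counts as zero (binary
#'   mode).
#' @return named numeric vector of length n with attribute `"mode"`.
#' @export
node_degrees <- function(net, mode = c("binary", "weighted"),
                         zero_tol = 1e-12) {
  mode <- match.arg(mode)
  net <- as_connectivity(net)
  W <- net$W
  A <- abs(W)
  diag(A) <- 0
  d <- if (mode == "binary") rowSums(A > zero_tol) else rowSums(A)
  names(d) <- net$roi_labels
  attr(d, "mode") <- mode
  d
}

#' s-metric: degree assortativity mass of a graph
#'
#' S(W) = sum over edges (i, j), each unordered edge counted once, of
#' d_i * d_j, where d is the binary degree on the thresholded support
#' (|W_ij| > `zero_tol`). Among graphs with the same number of edges, S is
#' maximal when high-degree nodes connect to each other, so a larger
#' s-metric indicates more hub-concentrated, scale-free-like wiring.
#' Because S depends on the support only, networks should be compared at a
#' matched edge count (see [match_edge_count()]).
#'
#' @inheritParams node_degrees
#' @return a single non-negative number.
#' @examples
#' tri <- matrix(1, 3, 3) - diag(3)
#' s_metric(tri)  # 3 edges, all degrees 2 -> 12
#' @export
s_metric <- function(net, zero_tol = 1e-12) {
  W <- as_connectivity(net)$W
  A <- abs(W) > zero_tol
  diag(A) <- FALSE
  A <- A | t(A)  # guard: treat any asymmetric dust as undirected support
  d <- rowSums(A)
  sum(A * outer(d, d)) / 2
}

#' Pooled degree distribution and complementary CDF
#'
#' Pools node degrees over subjects and returns, per unique degree value d,
#' the count of nodes and the empirical complementary CDF P(D >= d) (weak
#' inequality, so the cCDF at the smallest observed degree is exactly 1).
#' Use [as.data.frame()] on the result for a plottable table;
#' `loglog = TRUE` drops zero-degree nodes, whose log-coordinate is
#' undefined, from the export (they still count in the cCDF denominator).
#'
#' @param degrees a numeric vector of degrees, a single [fbn_network], or a
#'   list of either (pooled across subjects).
#' @param mode passed to [node_degrees()] when networks are supplied.
#' @param zero_tol passed to [node_degrees()].
#' @return object of class `fbn_degree_dist`: list with `support`, `counts`,
#'   `ccdf`, `n_pooled`.
#' @examples
#' d <- degree_ccdf(c(1, 1, 2))
#' d$ccdf  # P(D >= 1) = 1, P(D >= 2) = 1/3
#' @export
degree_ccdf <- function(degrees, mode = "binary", zero_tol = 1e-12) {
  if (!is.list(degrees)) degrees <- list(degrees)
  pool <- unlist(lapply(degrees, function(x) {
    if (inherits(x, "fbn_network") || is.matrix(x)) {
      as.numeric(node_degrees(x, mode = mode, zero_tol = zero_tol))
    } else {
      as.numeric(x)
    }
  }), use.names = FALSE)
  if (length(pool) == 0L) stop_fbn("empty degree pool")
  support <- sort(unique(pool))
  counts <- vapply(support, function(d) sum(pool == d), numeric(1))
  # P(D >= d): reverse cumulative share of nodes
  ccdf <- rev(cumsum(rev(counts))) / length(pool)
  structure(
    list(support = support, counts = counts, ccdf = ccdf,
         n_pooled = length(pool)),
    class = "fbn_degree_dist"
  )
}

#' @param x an `fbn_degree_dist`.
#' @param loglog drop zero degrees (undefined in log coordinates) from the
#'   exported table.
#' @param ... unused.
#' @rdname degree_ccdf
#' @export
as.data.frame.fbn_degree_dist <- function(x, ..., loglog = FALSE) {
  df <- data.frame(degree = x$support, count = x$counts, ccdf = x$ccdf)
  if (loglog) df <- df[df$degree > 0, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.fbn_degree_dist <- function(x, ...) {
  cat(sprintf("degree distribution: %d nodes pooled, %d distinct degrees\n",
              x$n_pooled, length(x$support)))
  print(as.data.frame(x))
  invisible(x)
}

#' Match the edge count of a sparse correlation network
#'
#' Finds the largest lambda at which [estimate_pc_sparsity()] retains at
#' least `reference_count` edges, with the achieved count as close to the
#' reference as attainable. Used to compare estimators on an equal footing:
#' the s-metric depends on the number of edges, so topology comparisons
#' (e.g. against [estimate_pc_scale_free()]) are only meaningful at a
#' matched count. The closed-form solution soft(X'X, lambda/2) makes the
#' edge count a non-increasing, piecewise-constant function of lambda with
#' breakpoints at 2|correlation|; the boundary is located by bisection.
#' Ties in |correlation| can make an exact match unattainable, in which
#' case the closest attainable count from above is returned.
#'
#' @param xs standardized time series.
#' @param reference_count target number of edges, between 0 and n(n-1)/2.
#' @param cfg a [solver_config()].
#' @param zero_tol magnitude below which an entry counts as zero.
#' @return list with `lambda`, `network` (the matched [fbn_network]),
#'   `achieved_count`, `reference_count`.
#' @export
match_edge_count <- function(xs, reference_count, cfg = solver_config(),
                             zero_tol = 1e-12) {
  xs <- assert_standardized(xs)
  S <- crossprod(xs$values)
  a <- abs(upper_values(S))
  m <- length(a)
  if (reference_count < 0 || reference_count > m) {
    stop_fbn("reference_count must be between 0 and n(n-1)/2 = ", m)
  }
  count_at <- function(lambda) sum(a - lambda / 2 > zero_tol)
  max_count <- count_at(0)
  if (reference_count > max_count) {
    stop_fbn("reference_count ", reference_count,
             " exceeds the attainable maximum ", max_count,
             " (pairs with nonzero correlation)")
  }
  if (reference_count == 0L) {
    lambda <- 2 * max(a)
  } else {
    # count_at is non-increasing in lambda; bisect for the boundary of
    # {lambda : count >= reference}, then return its inside endpoint.
    lo <- 0
    hi <- 2 * max(a) + 1
    for (k in seq_len(200L)) {
      mid <- (lo + hi) / 2
      if (count_at(mid) >= reference_count) lo <- mid else hi <- mid
    }
    lambda <- lo
  }
  fit <- estimate_pc_sparsity(xs, lambda = lambda, cfg = cfg)
  list(lambda = lambda, network = fit,
       achieved_count = edge_count(fit, zero_tol = zero_tol),
       reference_count = as.integer(reference_count))
}
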