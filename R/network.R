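#' Construct a connectivity-matrix object
#'
#' Wraps an n x n estimated network with metadata about the estimator that
#' produced it. All estimators in this package return networks with zero
#' diagonal: self-connections carry no information and must not contribute
#' to degrees, the s-metric, or classification features.
#'
#' @param W numeric n x n matrix, finite entries.
#' @param estimator short tag, e.g. `"pc"`, `"pc_sparsity"`.
#' @param roi_labels optional character vector of length n.
#' @param lambda,threshold regularization / sparsity parameter used, if any.
#' @param iterations number of solver iterations run.
#' @param converged logical convergence flag.
#' @param symmetrized logical; `TRUE` if an asymmetric solution (SR) was
#'   symmetrized as (W + W')/2 on output.
#' @param objective optional numeric trace of the penalized objective.
#' @return object of class `fbn_network`.
#' @export
fbn_network <- function(W, estimator = "manual", roi_labels = NULL,
                        lambda = NA_real_, threshold = NA_real_,
                        iterations = NA_integer_, converged = NA,
                        symmetrized = FALSE, objective = NULL) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) {
    stop_fbn("connectivity matrix must be square, got ",
             nrow(W), " x ", ncol(W))
  }
  if (!all(is.finite(W))) stop_fbn("connectivity matrix has non-finite entries")
  if (is.null(roi_labels)) {
    roi_labels <- colnames(W)
    if (is.null(roi_labels)) roi_labels <- default_roi_labels(ncol(W))
  }
  dimnames(W) <- list(roi_labels, roi_labels)
  structure(
    list(W = W, roi_labels = as.character(roi_labels), estimator = estimator,
         lambda = lambda, threshold = threshold,
         iterations = iterations, converged = converged,
         symmetrized = symmetrized, objective = objective),
    class = "fbn_network"
  )
}

#' @export
print.fbn_network <- function(x, ...) {
  nz <- edge_count(x)
  cat(sprintf("fbn_network [%s]: %d ROIs, %d edges", x$estimator,
              ncol(x$W), nz))
  if (!is.na(x$lambda)) cat(sprintf(", lambda = %g", x$lambda))
  if (!is.na(x$threshold)) cat(sprintf(", sparsity = %g%%", x$threshold))
  if (!is.na(x$iterations)) {
    cat(sprintf(", %d iterations (%s)", x$iterations,
                if (isTRUE(x$converged)) "converged" else "not converged"))
  }
  cat("\n")
  invisible(x)
}

# Accept fbn_network or bare matrix wherever a network is expected.
as_connectivity <- function(x) {
  if (inherits(x, "fbn_network")) return(x)
  fbn_network(x)
}

#' Number of edges in a network
#'
#' Counts unordered node pairs (i < j) whose absolute weight exceeds
#' `zero_tol`.
#'
#' @param net an [fbn_network] or square matrix.
#' @param zero_tol magnitude below which an entry counts as zero.
#' @return integer edge count.
#' @export
edge_count <- function(net, zero_tol = 1e-12) {
  W <- as_connectivity(net)$W
  sum(abs(upper_values(W)) > zero_tol)
}
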