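# Internal helpers shared across modules.

# Default tolerance below which an entry is treated as a structural zero.
# Proximal updates produce exact zeros, but file round-trips and BLAS
# reorderings can leave float dust of order 1e-15.
.zero_tol_default <- 1e-12

#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so that
#' seeded generators behave as pure functions of their arguments without
#' clobbering the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Relative Frobenius change between successive iterates; the convergence
# criterion used by all iterative solvers. Denominator guarded for W = 0.
rel_frobenius_change <- function(w_new, w_old) {
  denom <- max(norm(w_old, type = "F"), .Machine$double.eps)
  norm(w_new - w_old, type = "F") / denom
}

# Indices (i, j), i < j, of the strictly-upper triangle in row-major order:
# (1,2), (1,3), ..., (1,n), (2,3), ... This is the canonical feature order.
upper_pairs <- function(n) {
  stopifnot(n >= 2)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n), use.names = FALSE)
  cbind(i = i, j = j)
}

# Extract strictly-upper-triangle values in row-major order.
upper_values <- function(W) {
  tW <- t(W)
  tW[lower.tri(tW)]
}

default_roi_labels <- function(n) paste0("ROI_", seq_len(n))

stop_fbn <- function(...) stop(..., call. = FALSE)
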