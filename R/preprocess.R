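#' Center and unit-norm scale each ROI time course
#'
#' Subtracts the column mean and divides by the Euclidean norm of the
#' centered column, x_i <- (x_i - mean(x_i)) / ||x_i - mean(x_i)||_2. With
#' this convention the Gram matrix X'X is exactly the Pearson correlation
#' matrix: unit diagonal, off-diagonal entries in \[-1, 1\]. Note the scaling
#' is unit *norm*, not unit variance; unit-variance scaling would give
#' X'X = (t-1) R instead of R.
#'
#' A constant column has zero norm after centering and cannot be scaled.
#' With `degenerate_policy = "error"` (the default) this aborts naming the
#' ROI; `"zero"` maps the column to all zeros and warns. The zero policy
#' silently makes all correlations of that ROI zero, which shifts feature
#' ranks downstream, hence it is opt-in.
#'
#' @param x an [fbn_timeseries] or a t x n numeric matrix.
#' @param degenerate_policy `"error"` or `"zero"`; handling of constant
#'   columns.
#' @return an [fbn_timeseries] with `standardized = TRUE`. Columns flagged
#'   degenerate (policy `"zero"`) are recorded in attribute
#'   `"degenerate_rois"`.
#' @examples
#' x <- standardize_columns(matrix(rnorm(60), 20, 3))
#' round(colSums(x$values), 12)          # centered
#' round(colSums(x$values^2), 12)        # unit norm
#' @export
standardize_columns <- function(x, degenerate_policy = c("error", "zero")) {
  degenerate_policy <- match.arg(degenerate_policy)
  ts <- as_timeseries(x)
  v <- ts$values
  centered <- sweep(v, 2L, colMeans(v), "-")
  norms <- sqrt(colSums(centered^2))
  degenerate <- norms < .zero_tol_default
  if (any(degenerate)) {
    bad <- ts$roi_labels[degenerate]
    if (degenerate_policy == "error") {
      stop_fbn("constant (degenerate) ROI column(s): ",
               paste(bad, collapse = ", "),
               "; rerun with degenerate_policy = \"zero\" to zero them out")
    }
    warning("degenerate ROI column(s) set to zero: ",
            paste(bad, collapse = ", "), call. = FALSE)
    norms[degenerate] <- 1  # divide by 1; centered values are already ~0
    centered[, degenerate] <- 0
  }
  out <- sweep(centered, 2L, norms, "/")
  res <- fbn_timeseries(out, roi_labels = ts$roi_labels,
                        subject_id = ts$subject_id, standardized = TRUE)
  attr(res, "degenerate_rois") <- ts$roi_labels[degenerate]
  res
}

# Accept either a standardized fbn_timeseries or a matrix that is verified
# numerically to be column-centered with unit norms. Estimators require this
# so that crossprod(X) is the correlation matrix.
assert_standardized <- function(x, tol = 1e-6) {
  if (inherits(x, "fbn_timeseries")) {
    if (!isTRUE(x$standardized)) {
      stop_fbn("input time series is not standardized; ",
               "call standardize_columns() first")
    }
    return(x)
  }
  v <- as.matrix(x)
  norms <- colSums(v^2)
  ok <- all(abs(colSums(v)) < tol) &
    all(abs(norms - 1) < tol | norms < tol^2)
  if (!ok) {
    stop_fbn("matrix input is not column-standardized ",
             "(centered, unit Euclidean norm); call standardize_columns()")
  }
  fbn_timeseries(v, standardized = TRUE)
}
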