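#' Construct an ROI time-series object
#'
#' Bundles a t x n matrix of regional signals (rows = time points, columns =
#' ROIs) with its ROI labels and a subject identifier. The orientation is
#' fixed: rows are always time. Callers holding transposed data must
#' transpose explicitly (see `transpose` in [read_timeseries()]); the package
#' never guesses orientation, because a silent transpose corrupts every
#' downstream correlation.
#'
#' @param values numeric t x n matrix, t >= 2 time points, n >= 2 ROIs, all
#'   entries finite.
#' @param roi_labels character vector of length n; defaults to
#'   `ROI_1 ... ROI_n`.
#' @param subject_id single string identifying the subject.
#' @param standardized logical; `TRUE` only for output of
#'   [standardize_columns()].
#' @return an object of class `fbn_timeseries` with elements `values`,
#'   `roi_labels`, `subject_id`, `standardized`.
#' @examples
#' ts <- fbn_timeseries(matrix(rnorm(40), 10, 4))
#' dim(ts$values)
#' @export
fbn_timeseries <- function(values, roi_labels = NULL, subject_id = "subject",
                           standardized = FALSE) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop_fbn("time-series values must be numeric")
  }
  if (nrow(values) < 2L) {
    stop_fbn("time series needs at least 2 time points, got ", nrow(values))
  }
  if (ncol(values) < 2L) {
    stop_fbn("time series needs at least 2 ROIs, got ", ncol(values))
  }
  if (!all(is.finite(values))) {
    stop_fbn("time series contains non-finite entries")
  }
  if (is.null(roi_labels)) {
    roi_labels <- colnames(values)
    if (is.null(roi_labels)) roi_labels <- default_roi_labels(ncol(values))
  }
  if (length(roi_labels) != ncol(values)) {
    stop_fbn("roi_labels length (", length(roi_labels),
             ") does not match ROI count (", ncol(values), ")")
  }
  dimnames(values) <- list(NULL, roi_labels)
  structure(
    list(values = values, roi_labels = as.character(roi_labels),
         subject_id = as.character(subject_id),
         standardized = isTRUE(standardized)),
    class = "fbn_timeseries"
  )
}

#' @export
print.fbn_timeseries <- function(x, ...) {
  cat(sprintf("ROI time series '%s': %d time points x %d ROIs%s\n",
              x$subject_id, nrow(x$values), ncol(x$values),
              if (x$standardized) " (standardized)" else ""))
  invisible(x)
}

#' @export
dim.fbn_timeseries <- function(x) dim(x$values)

# Coerce a matrix or fbn_timeseries to fbn_timeseries.
as_timeseries <- function(x, subject_id = "subject") {
  if (inherits(x, "fbn_timeseries")) return(x)
  fbn_timeseries(x, subject_id = subject_id)
}
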