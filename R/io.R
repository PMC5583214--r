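# Text I/O for time series, networks, and cohort manifests. All formats are
# plain delimited UTF-8 with "." as the decimal separator; numeric output
# uses 10 significant digits so that write/read round-trips are stable.

.print_digits <- 10L

format_num <- function(x) sprintf("%.10g", x)

# Parse a delimited numeric table with strict shape/parse errors. Returns
# list(values, labels) where labels is NULL when no header was present.
parse_numeric_table <- function(path, delimiter, what = "table") {
  if (!file.exists(path)) stop_fbn(what, " file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_fbn("empty ", what, " file: ", path)
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop_fbn("ragged ", what, " file: row ", bad, " has ", widths[bad],
             " fields, expected ", widths[1L])
  }
  first <- suppressWarnings(as.numeric(cells[[1L]]))
  labels <- NULL
  if (anyNA(first)) {  # header row of labels
    labels <- trimws(cells[[1L]])
    cells <- cells[-1L]
    if (length(cells) == 0L) stop_fbn(what, " file has a header but no data")
  }
  nr <- length(cells)
  nc <- widths[1L]
  values <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    row <- suppressWarnings(as.numeric(cells[[r]]))
    if (anyNA(row)) {
      c0 <- which(is.na(row))[1L]
      stop_fbn("non-numeric cell at data row ", r, ", column ", c0,
               ": '", cells[[r]][c0], "'")
    }
    values[r, ] <- row
  }
  list(values = values, labels = labels)
}

#' Read an ROI time-series matrix from a delimited text file
#'
#' Rows are time points and columns are ROIs; an optional single header row
#' provides ROI labels (absent labels default to `ROI_1 ... ROI_n`). Files
#' stored in the transposed orientation must be flagged explicitly with
#' `transpose = TRUE`; orientation is never inferred from the shape.
#'
#' @param path path to a TSV/CSV file.
#' @param delimiter field separator, default tab.
#' @param subject_id subject identifier; defaults to the file name without
#'   extension.
#' @param transpose set `TRUE` if the file stores ROIs as rows.
#' @return an [fbn_timeseries].
#' @export
read_timeseries <- function(path, delimiter = "\t", subject_id = NULL,
                            transpose = FALSE) {
  parsed <- parse_numeric_table(path, delimiter, what = "time-series")
  v <- parsed$values
  labels <- parsed$labels
  if (transpose) v <- t(v)
  if (nrow(v) < 2L) {
    stop_fbn("time-series file has ", nrow(v), " time point(s); need >= 2")
  }
  if (ncol(v) < 2L) {
    stop_fbn("time-series file has ", ncol(v), " ROI(s); need >= 2")
  }
  if (!is.null(labels) && length(labels) != ncol(v)) {
    stop_fbn("header has ", length(labels), " labels for ", ncol(v), " ROIs")
  }
  if (is.null(subject_id)) {
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  }
  fbn_timeseries(v, roi_labels = labels, subject_id = subject_id)
}

#' Write an ROI time-series matrix to a delimited text file
#'
#' Writes a header row of ROI labels followed by one row per time point,
#' at 10 significant digits.
#'
#' @param ts an [fbn_timeseries] (or t x n matrix).
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, delimiter = "\t") {
  ts <- as_timeseries(ts)
  rows <- apply(ts$values, 1L, function(r) {
    paste(format_num(r), collapse = delimiter)
  })
  writeLines(c(paste(ts$roi_labels, collapse = delimiter), rows), path)
  invisible(path)
}

#' Write a connectivity matrix to text
#'
#' `format = "matrix"` writes the full n x n table with an ROI-label
#' header. `format = "edge_list"` writes one line per unordered pair
#' (i < j) whose weight exceeds `zero_tol` in magnitude, as
#' `label_i, label_j, weight`; an empty network yields a file with only the
#' header line.
#'
#' @param net an [fbn_network] or square matrix.
#' @param path output path.
#' @param format `"matrix"` or `"edge_list"`.
#' @param delimiter field separator, default tab.
#' @param zero_tol magnitude below which an edge is omitted from the edge
#'   list.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("matrix", "edge_list"),
                          delimiter = "\t", zero_tol = 1e-12) {
  format <- match.arg(format)
  net <- as_connectivity(net)
  W <- net$W
  if (format == "matrix") {
    rows <- apply(W, 1L, function(r) paste(format_num(r), collapse = delimiter))
    writeLines(c(paste(net$roi_labels, collapse = delimiter), rows), path)
  } else {
    pairs <- upper_pairs(ncol(W))
    vals <- upper_values(W)
    keep <- abs(vals) > zero_tol
    header <- paste(c("roi_i", "roi_j", "weight"), collapse = delimiter)
    lines <- if (any(keep)) {
      paste(net$roi_labels[pairs[keep, 1L]],
            net$roi_labels[pairs[keep, 2L]],
            format_num(vals[keep]), sep = delimiter)
    } else {
      character(0)
    }
    writeLines(c(header, lines), path)
  }
  invisible(path)
}

#' Read a connectivity matrix from text
#'
#' Inverse of [write_network()]. Edge-list files reconstruct a symmetric
#' matrix; supply `roi_labels` to fix the node set (required when some
#' nodes are isolated, since they never appear in the list).
#'
#' @param path input path.
#' @param format `"matrix"` or `"edge_list"`.
#' @param delimiter field separator.
#' @param roi_labels node label set for edge-list input; inferred from the
#'   labels present when omitted.
#' @return an [fbn_network].
#' @export
read_network <- function(path, format = c("matrix", "edge_list"),
                         delimiter = "\t", roi_labels = NULL) {
  format <- match.arg(format)
  if (format == "matrix") {
    parsed <- parse_numeric_table(path, delimiter, what = "network")
    W <- parsed$values
    if (nrow(W) != ncol(W)) {
      stop_fbn("network matrix is not square: ", nrow(W), " x ", ncol(W))
    }
    return(fbn_network(W, estimator = "file", roi_labels = parsed$labels))
  }
  if (!file.exists(path)) stop_fbn("network file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric"))
  if (is.null(roi_labels)) {
    roi_labels <- sort(unique(c(df[[1L]], df[[2L]])))
    if (length(roi_labels) < 2L) {
      stop_fbn("cannot infer node set from edge list; supply roi_labels")
    }
  }
  n <- length(roi_labels)
  W <- matrix(0, n, n, dimnames = list(roi_labels, roi_labels))
  unknown <- setdiff(unique(c(df[[1L]], df[[2L]])), roi_labels)
  if (length(unknown) > 0L) {
    stop_fbn("edge list refers to unknown ROI(s): ",
             paste(unknown, collapse = ", "))
  }
  for (r in seq_len(nrow(df))) {
    W[df[r, 1L], df[r, 2L]] <- df[r, 3L]
    W[df[r, 2L], df[r, 1L]] <- df[r, 3L]
  }
  fbn_network(W, estimator = "file", roi_labels = roi_labels)
}

# Default label normalization for cohort manifests. Maps common tokens to
# the internal positive/negative coding; extend via the label_map argument.
default_label_map <- c(
  positive = "positive", pos = "positive", "1" = "positive",
  case = "positive", patient = "positive", asd = "positive",
  negative = "negative", neg = "negative", "0" = "negative",
  control = "negative", nc = "negative", hc = "negative"
)

#' Read a cohort manifest and load its subjects
#'
#' The manifest is a delimited file with a header and columns
#' `subject_id`, `path`, `label`. Relative paths are resolved against the
#' manifest's directory. Labels are normalized to positive/negative via
#' `label_map`; unknown tokens, duplicate subject ids, and missing files are
#' errors naming the offending subject.
#'
#' @param path manifest path.
#' @param delimiter field separator; default tab, or comma for `.csv`.
#' @param label_map named character vector mapping lower-cased label tokens
#'   to `"positive"` / `"negative"`.
#' @return an `fbn_cohort`: list with `subjects` (list of
#'   [fbn_timeseries]), `labels` (factor with levels negative, positive),
#'   `subject_ids`, `paths`.
#' @export
read_cohort_manifest <- function(path, delimiter = NULL,
                                 label_map = default_label_map) {
  if (!file.exists(path)) stop_fbn("manifest file not found: ", path)
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  df <- tryCatch(
    utils::read.table(path, sep = delimiter, header = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e) stop_fbn("cannot parse manifest: ", conditionMessage(e))
  )
  if (nrow(df) == 0L) stop_fbn("manifest contains no subjects")
  need <- c("subject_id", "path", "label")
  if (!all(need %in% names(df))) {
    stop_fbn("manifest must have columns: ", paste(need, collapse = ", "))
  }
  ids <- as.character(df$subject_id)
  if (anyDuplicated(ids)) {
    stop_fbn("duplicate subject_id in manifest: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  tokens <- tolower(trimws(as.character(df$label)))
  unknown <- setdiff(unique(tokens), names(label_map))
  if (length(unknown) > 0L) {
    stop_fbn("unknown label token(s): ", paste(unknown, collapse = ", "),
             "; extend label_map to cover them")
  }
  labels <- unname(label_map[tokens])
  paths <- as.character(df$path)
  rel <- !grepl("^(/|[A-Za-z]:)", paths)
  paths[rel] <- file.path(dirname(path), paths[rel])
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop_fbn("time-series file missing for subject(s): ",
             paste(ids[missing], collapse = ", "))
  }
  subjects <- mapply(function(p, id) read_timeseries(p, subject_id = id),
                     paths, ids, SIMPLIFY = FALSE)
  names(subjects) <- ids
  fbn_cohort(subjects, labels)
}

#' Construct a cohort object
#'
#' @param subjects named list of [fbn_timeseries], one per subject.
#' @param labels character or factor of `"positive"` / `"negative"`, one
#'   per subject.
#' @param truth optional ground-truth record (see [make_cohort()]).
#' @return object of class `fbn_cohort`.
#' @export
fbn_cohort <- function(subjects, labels, truth = NULL) {
  stopifnot(is.list(subjects), length(subjects) == length(labels))
  labels <- factor(as.character(labels), levels = c("negative", "positive"))
  if (anyNA(labels)) stop_fbn("labels must be 'positive' or 'negative'")
  ids <- names(subjects)
  if (is.null(ids)) {
    ids <- vapply(subjects, function(s) s$subject_id, character(1))
    names(subjects) <- ids
  }
  structure(
    list(subjects = subjects, labels = labels, subject_ids = ids,
         truth = truth),
    class = "fbn_cohort"
  )
}

#' @export
print.fbn_cohort <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("fbn_cohort: %d subjects (%d positive / %d negative)\n",
              length(x$subjects), tab[["positive"]], tab[["negative"]]))
  invisible(x)
}

#' Write a cohort to time-series files plus a manifest
#'
#' One file per subject (`<subject_id>.tsv`) and a `manifest.tsv` with
#' columns `subject_id`, `path`, `label`, readable back with
#' [read_cohort_manifest()].
#'
#' @param cohort an `fbn_cohort`.
#' @param dir output directory (created if needed).
#' @param delimiter field separator.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, delimiter = "\t") {
  stopifnot(inherits(cohort, "fbn_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0(cohort$subject_ids, ".tsv")
  for (k in seq_along(cohort$subjects)) {
    write_timeseries(cohort$subjects[[k]], file.path(dir, files[k]),
                     delimiter = delimiter)
  }
  manifest <- file.path(dir, "manifest.tsv")
  lines <- c(paste("subject_id", "path", "label", sep = "\t"),
             paste(cohort$subject_ids, files, as.character(cohort$labels),
                   sep = "\t"))
  writeLines(lines, manifest)
  invisible(manifest)
}
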