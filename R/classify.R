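#' Vectorize a symmetric network into edge features
#'
#' Returns the strictly-upper-triangle entries in row-major order
#' ((1,2), (1,3), ..., (2,3), ...), the canonical feature layout: length
#' n(n-1)/2, i.e. 6670 features for the 116-ROI atlas. Asymmetric input is
#' an error — symmetrize explicitly upstream (e.g. [estimate_sr()] with
#' `symmetrize = TRUE`) so the choice is visible.
#'
#' @param net an [fbn_network] or square matrix.
#' @param tol maximum tolerated |W_ij - W_ji|.
#' @return numeric feature vector; see [feature_index()] for the
#'   (i, j) -> position map.
#' @export
extract_features <- function(net, tol = 1e-8) {
  W <- as_connectivity(net)$W
  if (max(abs(W - t(W))) > tol) {
    stop_fbn("network is asymmetric beyond tolerance; symmetrize upstream")
  }
  upper_values(W)
}

#' Feature-position map for the upper-triangle layout
#'
#' @param n number of nodes.
#' @return data frame with columns `i`, `j` (i < j); row k gives the node
#'   pair of feature k in [extract_features()] order.
#' @export
feature_index <- function(n) {
  as.data.frame(upper_pairs(n))
}

#' Rebuild a symmetric zero-diagonal network from a feature vector
#'
#' Inverse of [extract_features()].
#'
#' @param features numeric vector of length n(n-1)/2.
#' @param roi_labels optional node labels (length n).
#' @return an [fbn_network].
#' @export
features_to_network <- function(features, roi_labels = NULL) {
  p <- length(features)
  n <- (1 + sqrt(1 + 8 * p)) / 2
  if (abs(n - round(n)) > 1e-9) {
    stop_fbn("feature length ", p, " is not n(n-1)/2 for integer n")
  }
  n <- as.integer(round(n))
  W <- matrix(0, n, n)
  pairs <- upper_pairs(n)
  W[pairs] <- features
  W[pairs[, c(2L, 1L), drop = FALSE]] <- features
  fbn_network(W, estimator = "features", roi_labels = roi_labels)
}

# Vectorized two-sample two-tailed t-test over feature columns.
# Returns p-values; NA for features whose (pooled or Welch) variance
# vanishes. Pooled variance is the default variant.
col_ttest_p <- function(X, positive, var_equal = TRUE) {
  X1 <- X[positive, , drop = FALSE]
  X2 <- X[!positive, , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  v1 <- colSums(sweep(X1, 2L, m1)^2) / (n1 - 1)
  v2 <- colSums(sweep(X2, 2L, m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2, length(se2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  }
  p <- rep(NA_real_, ncol(X))
  ok <- se2 > 0 & is.finite(df) & df > 0
  tt <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
  p[ok] <- 2 * pt(-abs(tt), df[ok])
  p
}

#' Univariate t-test feature screen
#'
#' Two-sample two-tailed t-test per feature on the supplied (training)
#' subjects; selects features with p < `alpha`. Zero-variance features have
#' an undefined t statistic and are never selected. If nothing passes the
#' screen — common in small inner folds at strong regularization, where
#' most edge features are exactly zero — the single smallest-p feature is
#' selected instead of aborting, and the fallback is flagged.
#'
#' @param features numeric subjects x p matrix (training subjects only:
#'   running the screen on data that includes test subjects leaks labels).
#' @param labels factor/character of positive/negative, length = subjects.
#' @param alpha selection threshold on the p-value, in (0, 1).
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @return list with `mask` (logical length p), `p_values`,
#'   `fallback_used`, `n_selected`.
#' @export
ttest_filter <- function(features, labels, alpha = 0.05, var_equal = TRUE) {
  features <- as.matrix(features)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_fbn("alpha must be in (0, 1)")
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(features)) {
    stop_fbn("labels length must equal the number of subject rows")
  }
  positive <- labels == "positive"
  if (all(positive) || !any(positive)) {
    stop_fbn("t-test screen needs both classes in the training set")
  }
  if (sum(positive) < 2L || sum(!positive) < 2L) {
    stop_fbn("t-test screen needs >= 2 subjects per class")
  }
  p <- col_ttest_p(features, positive, var_equal = var_equal)
  mask <- !is.na(p) & p < alpha
  fallback <- FALSE
  if (!any(mask)) {
    if (all(is.na(p))) {
      stop_fbn("all features are degenerate (zero variance); cannot screen")
    }
    mask[which.min(p)] <- TRUE
    fallback <- TRUE
  }
  list(mask = mask, p_values = p, fallback_used = fallback,
       n_selected = sum(mask))
}

#' Confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer counts (positives = patients).
#' @return object of class `fbn_confusion`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_fbn("confusion counts must be non-negative integers")
  }
  counts <- as.list(counts)
  counts[] <- lapply(counts, as.integer)
  structure(counts, class = "fbn_confusion")
}

#' Accuracy, sensitivity, and specificity from confusion counts
#'
#' accuracy = (TP + TN) / (TP + FP + TN + FN); sensitivity = TP / (TP + FN),
#' the true-positive rate among patients; specificity = TN / (TN + FP), the
#' true-negative rate among controls. A metric with a zero denominator is
#' reported as `NA` (undefined), never as 0.
#'
#' @param counts an [confusion_counts()] object, or `tp` given as the first
#'   of four counts.
#' @param fp,tn,fn counts when `counts` is given as `tp`.
#' @return list of class `fbn_metrics` with elements `accuracy`,
#'   `sensitivity`, `specificity` (fractions in \[0, 1\]) and `counts`; the
#'   print method also renders percentages.
#' @examples
#' classification_metrics(confusion_counts(tp = 38, fp = 10, tn = 37, fn = 7))
#' @export
classification_metrics <- function(counts, fp = NULL, tn = NULL, fn = NULL) {
  if (!inherits(counts, "fbn_confusion")) {
    counts <- confusion_counts(counts, fp, tn, fn)
  }
  total <- counts$tp + counts$fp + counts$tn + counts$fn
  if (total < 1L) stop_fbn("confusion counts are all zero")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  structure(
    list(accuracy = safe_div(counts$tp + counts$tn, total),
         sensitivity = safe_div(counts$tp, counts$tp + counts$fn),
         specificity = safe_div(counts$tn, counts$tn + counts$fp),
         counts = counts),
    class = "fbn_metrics"
  )
}

#' @export
print.fbn_metrics <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("accuracy    %s\nsensitivity %s\nspecificity %s\n",
              pct(x$accuracy), pct(x$sensitivity), pct(x$specificity)))
  cat(sprintf("(tp=%d fp=%d tn=%d fn=%d)\n", x$counts$tp, x$counts$fp,
              x$counts$tn, x$counts$fn))
  invisible(x)
}

# Estimate a network for one standardized subject at one parameter value.
# cfg = NULL lets each estimator use its own solver defaults (the
# scale-free solver needs a damped step, the others a plain one).
network_for_method <- function(xs, method, value, cfg = NULL) {
  switch(method,
    pc = pearson_network(xs),
    pc_threshold = hard_threshold_network(pearson_network(xs), value),
    pc_sparsity = if (is.null(cfg)) {
      estimate_pc_sparsity(xs, lambda = value)
    } else {
      estimate_pc_sparsity(xs, lambda = value, cfg = cfg)
    },
    pc_scale_free = suppressWarnings(if (is.null(cfg)) {
      estimate_pc_scale_free(xs, lambda = value)
    } else {
      estimate_pc_scale_free(xs, lambda = value, cfg = cfg)
    }),
    sr = if (is.null(cfg)) {
      estimate_sr(xs, lambda = value)
    } else {
      estimate_sr(xs, lambda = value, cfg = cfg)
    },
    stop_fbn("unknown method: ", method)
  )
}

normalize_method <- function(method) {
  m <- gsub("-", "_", tolower(method))
  valid <- c("pc", "pc_threshold", "pc_sparsity", "pc_scale_free", "sr")
  if (!m %in% valid) {
    stop_fbn("method must be one of: ", paste(valid, collapse = ", "))
  }
  m
}

# Feature matrices (subjects x p), one per grid value, for a cohort.
cohort_feature_matrices <- function(cohort, method, grid, cfg) {
  std <- lapply(cohort$subjects, function(s) {
    tryCatch(standardize_columns(s),
             error = function(e) {
               stop_fbn("estimator failed for subject ", s$subject_id, ": ",
                        conditionMessage(e))
             })
  })
  lapply(grid, function(g) {
    feats <- lapply(seq_along(std), function(k) {
      net <- tryCatch(network_for_method(std[[k]], method, g, cfg),
                      error = function(e) {
                        stop_fbn("estimator failed for subject ",
                                 cohort$subject_ids[k], ": ",
                                 conditionMessage(e))
                      })
      extract_features(net)
    })
    do.call(rbind, feats)
  })
}

# Screen on train, fit linear SVM (cost C, no rescaling: correlation
# features already live in [-1, 1]), predict test rows. When every feature
# is degenerate (e.g. the estimator returned empty networks for the whole
# training set at an extreme grid value), no classifier can be fit; the
# fold degrades to the training-majority prediction so that grid search
# scores, rather than aborts on, such parameter values.
fit_and_predict <- function(train_X, train_y, test_X, alpha, cost,
                            var_equal = TRUE) {
  mu <- colMeans(train_X)
  spread <- colSums(train_X^2) / nrow(train_X) - mu^2
  if (all(spread < .Machine$double.eps)) {
    tab <- table(factor(train_y, levels = c("negative", "positive")))
    majority <- names(tab)[which.max(tab)]
    return(list(prediction = rep(majority, nrow(test_X)),
                selected = integer(0), fallback_used = NA))
  }
  screen <- ttest_filter(train_X, train_y, alpha = alpha,
                         var_equal = var_equal)
  idx <- which(screen$mask)
  y <- factor(train_y, levels = c("negative", "positive"))
  fit <- e1071::svm(train_X[, idx, drop = FALSE], y, kernel = "linear",
                    cost = cost, scale = FALSE)
  pred <- predict(fit, test_X[, idx, drop = FALSE])
  list(prediction = as.character(pred), selected = idx,
       fallback_used = screen$fallback_used)
}

#' Nested leave-one-out evaluation of a network estimator
#'
#' The standard connectome-classification protocol: each subject is held
#' out once (outer LOO); on the remaining subjects an inner LOO is run for
#' every candidate parameter value, and the value with the highest inner
#' accuracy is chosen (ties go to the smallest value, deterministically).
#' The t-test screen and linear SVM (C = `cost`) are then refit on the full
#' outer-training set at the chosen value and the held-out subject is
#' predicted. Feature selection always happens inside the training
#' partition, so no label information leaks into the evaluation. Confusion
#' counts are aggregated over all outer folds.
#'
#' Typical parameter grids: lambda in `seq(0.05, 1, 0.05)` for the
#' penalized estimators and SR; sparsity levels `seq(5, 100, 5)` (percent
#' of edges kept) for the hard-threshold baseline.
#'
#' @param cohort an `fbn_cohort` with >= 2 subjects per class.
#' @param method `"pc"`, `"pc_threshold"`, `"pc_sparsity"`,
#'   `"pc_scale_free"`, or `"sr"` (hyphens accepted).
#' @param grid numeric vector of candidate parameter values (ignored for
#'   `"pc"`, which has none).
#' @param alpha t-test screening level, default 0.05.
#' @param cost linear-SVM regularization parameter C, default 1.
#' @param cfg a [solver_config()] passed to every estimator call, or
#'   `NULL` (default) to let each estimator use its own solver defaults.
#' @param var_equal pooled-variance t-test (default) or Welch.
#' @return object of class `fbn_report`: `metrics` (an `fbn_metrics`),
#'   `folds` (per-subject data frame with the chosen parameter and
#'   prediction), `selected` (per-fold selected feature indices, for
#'   leakage audits), plus the call settings.
#' @export
loo_evaluate <- function(cohort, method, grid = seq(0.05, 1, by = 0.05),
                         alpha = 0.05, cost = 1, cfg = NULL,
                         var_equal = TRUE) {
  stopifnot(inherits(cohort, "fbn_cohort"))
  method <- normalize_method(method)
  labels <- as.character(cohort$labels)
  if (sum(labels == "positive") < 2L || sum(labels == "negative") < 2L) {
    stop_fbn("need >= 2 subjects per class")
  }
  if (method == "pc") grid <- NA_real_
  grid <- sort(grid)
  N <- length(cohort$subjects)
  feats <- cohort_feature_matrices(cohort, method, grid, cfg)

  chosen <- numeric(N)
  predictions <- character(N)
  selected <- vector("list", N)
  fallbacks <- logical(N)
  for (o in seq_len(N)) {
    train <- setdiff(seq_len(N), o)
    best_acc <- -Inf
    best_g <- 1L
    if (length(grid) > 1L) {
      for (gi in seq_along(grid)) {
        Fg <- feats[[gi]]
        correct <- 0L
        for (i in train) {
          inner_train <- setdiff(train, i)
          res <- fit_and_predict(Fg[inner_train, , drop = FALSE],
                                 labels[inner_train],
                                 Fg[i, , drop = FALSE], alpha, cost,
                                 var_equal)
          correct <- correct + (res$prediction == labels[i])
        }
        acc <- correct / length(train)
        if (acc > best_acc + 1e-12) {  # strict improvement: ties keep the
          best_acc <- acc              # smallest grid value
          best_g <- gi
        }
      }
    }
    Fg <- feats[[best_g]]
    res <- fit_and_predict(Fg[train, , drop = FALSE], labels[train],
                           Fg[o, , drop = FALSE], alpha, cost, var_equal)
    chosen[o] <- grid[best_g]
    predictions[o] <- res$prediction
    selected[[o]] <- res$selected
    fallbacks[o] <- res$fallback_used
  }

  tp <- sum(predictions == "positive" & labels == "positive")
  fn <- sum(predictions == "negative" & labels == "positive")
  tn <- sum(predictions == "negative" & labels == "negative")
  fp <- sum(predictions == "positive" & labels == "negative")
  metrics <- classification_metrics(confusion_counts(tp, fp, tn, fn))
  folds <- data.frame(subject_id = cohort$subject_ids, label = labels,
                      prediction = predictions, parameter = chosen,
                      fallback_used = fallbacks, stringsAsFactors = FALSE)
  structure(
    list(metrics = metrics, folds = folds, selected = selected,
         method = method, grid = grid, alpha = alpha, cost = cost),
    class = "fbn_report"
  )
}

#' @export
print.fbn_report <- function(x, ...) {
  cat(sprintf("nested-LOO report [%s], %d subjects\n", x$method,
              nrow(x$folds)))
  print(x$metrics)
  invisible(x)
}

#' Leave-one-out accuracy per parameter value
#'
#' For each grid value, runs a plain (non-nested) LOO with the parameter
#' held fixed and reports the resulting accuracy — the accuracy-vs-parameter
#' sensitivity curve. Unlike [loo_evaluate()] this does not select
#' parameters, so the curve describes sensitivity, not an unbiased
#' performance estimate.
#'
#' @inheritParams loo_evaluate
#' @return data frame with columns `parameter` and `accuracy`.
#' @export
parameter_sweep <- function(cohort, method, grid = seq(0.05, 1, by = 0.05),
                            alpha = 0.05, cost = 1, cfg = NULL,
                            var_equal = TRUE) {
  stopifnot(inherits(cohort, "fbn_cohort"))
  method <- normalize_method(method)
  labels <- as.character(cohort$labels)
  grid <- sort(grid)
  N <- length(cohort$subjects)
  feats <- cohort_feature_matrices(cohort, method, grid, cfg)
  acc <- vapply(seq_along(grid), function(gi) {
    Fg <- feats[[gi]]
    correct <- 0L
    for (o in seq_len(N)) {
      train <- setdiff(seq_len(N), o)
      res <- fit_and_predict(Fg[train, , drop = FALSE], labels[train],
                             Fg[o, , drop = FALSE], alpha, cost, var_equal)
      correct <- correct + (res$prediction == labels[o])
    }
    correct / N
  }, numeric(1))
  data.frame(parameter = grid, accuracy = acc)
}
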