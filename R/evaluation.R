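# Confidence-thresholded evaluation with an "others" rejection class.
#
# A prediction is accepted under its arg-max class only when the gap between
# the two highest class probabilities reaches the confidence threshold k;
# otherwise the example is relegated to the reserved "others" label.
# Outcomes are counted one-vs-rest over the final (post-threshold) labels
# with "others" treated as a first-class label, and metrics are averaged
# over classes with weights proportional to class test-set sizes.

#' Apply the confidence-threshold rule to predicted probabilities
#'
#' Let `p1` and `p2` be the highest and second-highest predicted class
#' probabilities for an example. The example keeps its arg-max label iff
#' `p1 - p2 >= k`; otherwise it is labeled [others_label()]. Arg-max ties
#' are broken by class (column) order, so a tie gives `p1 - p2 = 0` and is
#' rejected whenever `k > 0`.
#'
#' @param probabilities Numeric matrix (rows = examples, named columns =
#'   classes) or a single probability vector with >= 2 named entries.
#' @param k Confidence threshold in \[0, 1\].
#' @return A `data.frame` with columns `argmax_label`, `p1`, `p2`,
#'   `final_label`.
#' @export
#' @examples
#' thresholded_predict(c(a = 0.6, b = 0.3, c = 0.1), k = 0.2)  # accepted: a
#' thresholded_predict(c(a = 0.6, b = 0.3, c = 0.1), k = 0.4)  # rejected
thresholded_predict <- function(probabilities, k) {
  if (is.null(dim(probabilities))) {
    probabilities <- matrix(probabilities, nrow = 1L,
                            dimnames = list(NULL, names(probabilities)))
  }
  if (ncol(probabilities) < 2L) {
    stop("need probabilities for at least two classes", call. = FALSE)
  }
  if (is.null(colnames(probabilities))) {
    stop("probability columns must be named with class labels", call. = FALSE)
  }
  if (!is.numeric(k) || length(k) != 1L || k < 0 || k > 1) {
    stop("k must be a single value in [0, 1]", call. = FALSE)
  }
  top <- apply(probabilities, 1L, function(p) {
    i1 <- which.max(p)               # first max: ties go to class order
    p1 <- p[i1]
    p2 <- max(p[-i1])
    c(i1, p1, p2)
  })
  argmax <- colnames(probabilities)[top[1L, ]]
  p1 <- unname(top[2L, ])
  p2 <- unname(top[3L, ])
  accepted <- (p1 - p2) >= k
  data.frame(
    argmax_label = argmax, p1 = p1, p2 = p2,
    final_label = ifelse(accepted, argmax, OTHERS_LABEL),
    stringsAsFactors = FALSE
  )
}

#' Count one-vs-rest outcomes at a threshold
#'
#' For every class `c` (including [others_label()]), counts true/false
#' positives/negatives of the final labels against the truths: TP = truth
#' and prediction both `c`; FP = prediction `c`, truth not; FN = truth `c`,
#' prediction not; TN = the rest. An example whose truth is "others" and
#' that the threshold relegates to "others" therefore counts as a true
#' positive for the "others" class.
#'
#' @param truths Character vector of true labels (may include
#'   [others_label()]).
#' @param predictions Character vector of final (post-threshold) labels.
#' @param class_order Character vector of trained classes;
#'   [others_label()] is appended automatically.
#' @return An object of class `outcome_counts`: `data.frame` with columns
#'   `class`, `n`, `tp`, `fp`, `tn`, `fn`, plus attribute `N`.
#' @export
count_outcomes <- function(truths, predictions, class_order) {
  if (length(truths) != length(predictions)) {
    stop("truths and predictions must have equal length", call. = FALSE)
  }
  classes <- unique(c(class_order, OTHERS_LABEL))
  unknown <- setdiff(unique(c(truths, predictions)), classes)
  if (length(unknown)) {
    stop(sprintf("label(s) outside the class order: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  N <- length(truths)
  rows <- lapply(classes, function(cl) {
    tp <- sum(truths == cl & predictions == cl)
    fp <- sum(truths != cl & predictions == cl)
    fn <- sum(truths == cl & predictions != cl)
    data.frame(class = cl, n = tp + fn, tp = tp, fp = fp,
               tn = N - tp - fp - fn, fn = fn, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "N") <- N
  class(out) <- c("outcome_counts", class(out))
  out
}

safe_ratio <- function(num, den) ifelse(den > 0, num / den, 0)

#' Class-size-weighted metrics from outcome counts
#'
#' Weighted precision, recall, specificity and F1: each per-class ratio is
#' weighted by `n_c / N`, the class's share of the test set, and summed over
#' all classes including [others_label()]. A per-class ratio with a zero
#' denominator contributes 0.
#'
#' @param counts An `outcome_counts` object.
#' @return A list of class `metric_report` with fields
#'   `weighted_precision`, `weighted_recall`, `weighted_specificity`,
#'   `weighted_f1` and `per_class` (the per-class ratio table).
#' @export
weighted_metrics <- function(counts) {
  stopifnot(inherits(counts, "outcome_counts"))
  N <- attr(counts, "N")
  if (N == 0L) {
    stop("cannot compute metrics for an empty test set", call. = FALSE)
  }
  precision <- safe_ratio(counts$tp, counts$tp + counts$fp)
  recall <- safe_ratio(counts$tp, counts$tp + counts$fn)
  specificity <- safe_ratio(counts$tn, counts$tn + counts$fp)
  f1 <- safe_ratio(2 * precision * recall, precision + recall)
  per_class <- data.frame(class = counts$class, n = counts$n,
                          precision = precision, recall = recall,
                          specificity = specificity, f1 = f1,
                          stringsAsFactors = FALSE)
  structure(list(
    weighted_precision = sum(counts$n * precision) / N,
    weighted_recall = sum(counts$n * recall) / N,
    weighted_specificity = sum(counts$n * specificity) / N,
    weighted_f1 = sum(counts$n * f1) / N,
    per_class = per_class
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(paste0("Weighted metrics: precision %.4f | recall %.4f | ",
                     "specificity %.4f | F1 %.4f\n"),
              x$weighted_precision, x$weighted_recall,
              x$weighted_specificity, x$weighted_f1))
  invisible(x)
}

#' Metrics across a grid of confidence thresholds
#'
#' Applies [thresholded_predict()], [count_outcomes()] and
#' [weighted_metrics()] at each threshold of the grid (default 0 to 1 in
#' steps of 0.1; the 0 endpoint disables rejection entirely).
#'
#' @param truths Character vector of true labels (incl. [others_label()]).
#' @param probabilities Probability matrix with named class columns.
#' @param k_grid Numeric vector of thresholds in \[0, 1\].
#' @return A `data.frame` with one row per threshold: `k`, the four
#'   weighted metrics and `n_others` (examples finally labeled
#'   [others_label()]); the full `metric_report`s are attached as the
#'   `reports` attribute.
#' @export
metrics_over_thresholds <- function(truths, probabilities,
                                    k_grid = seq(0, 1, by = 0.1)) {
  if (!length(k_grid)) {
    stop("threshold grid must be non-empty", call. = FALSE)
  }
  class_order <- colnames(probabilities)
  reports <- vector("list", length(k_grid))
  rows <- vector("list", length(k_grid))
  for (i in seq_along(k_grid)) {
    k <- k_grid[i]
    pred <- thresholded_predict(probabilities, k)
    counts <- count_outcomes(truths, pred$final_label, class_order)
    rep_i <- weighted_metrics(counts)
    reports[[i]] <- rep_i
    rows[[i]] <- data.frame(
      k = k,
      weighted_precision = rep_i$weighted_precision,
      weighted_recall = rep_i$weighted_recall,
      weighted_specificity = rep_i$weighted_specificity,
      weighted_f1 = rep_i$weighted_f1,
      n_others = sum(pred$final_label == OTHERS_LABEL)
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}

#' Evaluate a trained model on a test partition
#'
#' @param model An `rbp_model`.
#' @param test Labeled example `data.frame` (may contain
#'   [others_label()] truths).
#' @param k_grid Thresholds passed to [metrics_over_thresholds()].
#' @return See [metrics_over_thresholds()].
#' @export
evaluate_model <- function(model, test, k_grid = seq(0, 1, by = 0.1)) {
  probs <- predict_proba(model, test)
  metrics_over_thresholds(test$label, probs, k_grid)
}
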