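# Multiclass design construction: restriction to the most frequent host
# genera, the in-set/out-of-set (D1/D2) partition, a per-class stratified
# 70/30 split, and the "others"-augmented test set.
#
# A labeled example set is a data.frame with columns `protein_id`, `label`
# and one numeric column per feature component.

example_feature_cols <- function(examples) {
  setdiff(names(examples), c("protein_id", "label"))
}

#' Labeled example table
#'
#' @param protein_id Character vector of example identifiers.
#' @param label Character vector of host-genus labels.
#' @param features Numeric matrix or data.frame of feature values (one row
#'   per example).
#' @return A `data.frame` with `protein_id`, `label` and feature columns.
#' @export
labeled_examples <- function(protein_id, label, features) {
  features <- as.data.frame(features)
  if (!all(vapply(features, is.numeric, logical(1)))) {
    stop("all feature columns must be numeric", call. = FALSE)
  }
  cbind(data.frame(protein_id = as.character(protein_id),
                   label = as.character(label), stringsAsFactors = FALSE),
        features)
}

#' Select the most frequent classes
#'
#' Ranks genera by example count (descending, ties broken lexicographically)
#' and keeps the first `floor(fraction * n_genera)`.
#'
#' @param class_counts Named integer vector, genus -> example count.
#' @param fraction Fraction of genera to keep, in (0, 1\].
#' @return Character vector of retained genera, most frequent first.
#' @export
#' @examples
#' select_top_classes(c(A = 10, B = 5, C = 2, D = 1), 0.25)
select_top_classes <- function(class_counts, fraction = 0.25) {
  if (!length(class_counts)) {
    stop("class_counts must be non-empty", call. = FALSE)
  }
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  ord <- order(-as.numeric(class_counts), names(class_counts))
  n_keep <- floor(fraction * length(class_counts))
  names(class_counts)[ord][seq_len(n_keep)]
}

# Per-class training allocation: round half-up of train_fraction * n.
train_allocation <- function(n, train_fraction) {
  as.integer(floor(train_fraction * n + 0.5))
}

#' Stratified train/test split
#'
#' Allocates, for every class with `n_c` examples, exactly
#' `round(train_fraction * n_c)` examples (round half-up) to the training
#' set and the remainder to the test set. Within-class membership is
#' pseudo-random from the seed; per-class counts depend only on the class
#' sizes.
#'
#' @param examples Labeled example `data.frame`.
#' @param train_fraction Training fraction in (0, 1); default 0.7.
#' @param seed Integer seed controlling within-class assignment.
#' @param group Optional vector (same length as `nrow(examples)`, e.g. the
#'   phage id) forcing all members of a group into the same partition;
#'   `NULL` (the default) splits at the example level.
#'
#' @return A list with `train` and `test` example `data.frame`s.
#' @export
stratified_split <- function(examples, train_fraction = 0.7, seed = 1,
                             group = NULL) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must lie in (0, 1)", call. = FALSE)
  }
  counts <- table(examples$label)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    stop(sprintf("class(es) with fewer than 2 examples: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  train_idx <- integer(0)
  classes <- sort(names(counts))
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    idx <- which(examples$label == cl)
    n_train <- train_allocation(length(idx), train_fraction)
    picked <- with_seed(derive_seed(seed, ci), {
      if (is.null(group)) {
        sample(idx, n_train)
      } else {
        # keep whole groups together; fill train greedily in random group order
        g <- split(idx, as.character(group[idx]))
        ord <- sample(length(g))
        chosen <- integer(0)
        for (j in ord) {
          if (length(chosen) >= n_train) break
          chosen <- c(chosen, g[[j]])
        }
        chosen
      }
    })
    train_idx <- c(train_idx, picked)
  }
  list(train = examples[sort(train_idx), , drop = FALSE],
       test = examples[setdiff(seq_len(nrow(examples)), train_idx), ,
                       drop = FALSE])
}

#' Assemble the evaluation design
#'
#' Appends the out-of-set examples (hosts outside the retained class set) to
#' the test partition under the reserved [others_label()]; the training
#' partition is untouched.
#'
#' @param d1_split Result of [stratified_split()] on the in-set examples.
#' @param d2 Labeled example `data.frame` of out-of-set examples (labels
#'   disjoint from the class set); may have zero rows.
#' @param class_set Ordered character vector of trained classes; defaults to
#'   the distinct training labels.
#'
#' @return An object of class `dataset_split`: list with `train`, `test`,
#'   `class_set`, `d1_size`, `d2_size`.
#' @export
assemble_design <- function(d1_split, d2 = NULL, class_set = NULL) {
  train <- d1_split$train
  test <- d1_split$test
  if (is.null(class_set)) {
    class_set <- sort(unique(train$label))
  }
  if (OTHERS_LABEL %in% class_set) {
    stop(sprintf("class set may not contain the reserved label '%s'",
                 OTHERS_LABEL), call. = FALSE)
  }
  d1_size <- nrow(train) + nrow(test)
  d2_size <- 0L
  if (!is.null(d2) && nrow(d2)) {
    if (any(d2$label %in% class_set)) {
      stop("out-of-set labels must be disjoint from the class set", call. = FALSE)
    }
    if (any(d2$protein_id %in% train$protein_id)) {
      stop("out-of-set examples overlap the training set", call. = FALSE)
    }
    d2$label <- OTHERS_LABEL
    test <- rbind(test, d2)
    d2_size <- nrow(d2)
  }
  structure(list(train = train, test = test, class_set = class_set,
                 d1_size = d1_size, d2_size = d2_size),
            class = "dataset_split")
}

#' Build the full design from labeled examples
#'
#' Convenience wrapper: computes class counts, retains the top `fraction`
#' genera, splits the in-set examples 70/30 stratified, and appends the rest
#' of the corpus to the test set as [others_label()].
#'
#' @param examples Labeled example `data.frame` over all host genera.
#' @param fraction Fraction of genera to retain (default 0.25).
#' @param train_fraction Training fraction (default 0.7).
#' @param seed Split seed.
#' @return A `dataset_split` (see [assemble_design()]).
#' @export
build_design <- function(examples, fraction = 0.25, train_fraction = 0.7,
                         seed = 1) {
  counts <- table(examples$label)
  keep <- select_top_classes(stats::setNames(as.integer(counts), names(counts)),
                             fraction)
  d1 <- examples[examples$label %in% keep, , drop = FALSE]
  d2 <- examples[!(examples$label %in% keep), , drop = FALSE]
  split <- stratified_split(d1, train_fraction, seed)
  assemble_design(split, d2, class_set = keep)
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf(
    "Dataset split: %d train / %d test (%d classes, %d in-set, %d '%s')\n",
    nrow(x$train), nrow(x$test), length(x$class_set), x$d1_size, x$d2_size,
    OTHERS_LABEL))
  invisible(x)
}
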