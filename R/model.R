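# Class-weighted random-forest modelling: misclassification penalties for
# minority classes, the hyperparameter grid search under stratified
# cross-validation, probability prediction and Gini-importance ranking.
#
# The forest itself is ranger (probability forests, impurity importance);
# the class-weighting scheme, grid, CV protocol and importance contract are
# defined here.

#' Class misclassification weights
#'
#' For a training set of `T` examples over classes `C` with `t_c` examples
#' in class `c`, the misclassification penalty is
#' `w_c = T / (t_c * |C|)`, which inflates minority classes and satisfies
#' the conservation identity `sum_c t_c * w_c = T`. Balanced classes get
#' unit weights, and scaling every count by a constant leaves the weights
#' unchanged.
#'
#' @param class_counts Named integer vector of training counts per class
#'   (all counts >= 1).
#' @return An object of class `class_weight_table`: list with `total`,
#'   `counts` and `weights` (named numeric vectors).
#' @export
#' @examples
#' class_weights(c(a = 8, b = 2))$weights  # 0.625, 2.5
class_weights <- function(class_counts) {
  counts <- class_counts
  if (!length(counts) || is.null(names(counts))) {
    stop("class_counts must be a non-empty named vector", call. = FALSE)
  }
  counts <- stats::setNames(as.numeric(counts), names(counts))
  if (any(counts < 1)) {
    stop("every class must have at least one training example", call. = FALSE)
  }
  total <- sum(counts)
  w <- total / (counts * length(counts))
  structure(list(total = total, counts = counts, weights = w),
            class = "class_weight_table")
}

#' The forest hyperparameter grid
#'
#' All 96 combinations of trees (50, 100, 150, 200), split-feature rule
#' (log2 or square root of the feature count), minimum samples to split a
#' node (2, 3, 4) and minimum samples per leaf (1, 2, 3, 4).
#'
#' @return A `data.frame` with columns `n_trees`, `split_features`,
#'   `min_split`, `min_leaf`.
#' @export
default_grid <- function() {
  expand.grid(n_trees = c(50L, 100L, 150L, 200L),
              split_features = c("log2", "sqrt"),
              min_split = 2:4, min_leaf = 1:4,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Default hyperparameters
#'
#' The grid-search optimum used when tuning is skipped: 150 trees, square
#' root split features, minimum split 2, minimum leaf 1.
#'
#' @return A one-row `data.frame` in [default_grid()] layout.
#' @export
default_hyperparameters <- function() {
  data.frame(n_trees = 150L, split_features = "sqrt", min_split = 2L,
             min_leaf = 1L, stringsAsFactors = FALSE)
}

mtry_for <- function(rule, p) {
  m <- switch(rule, sqrt = floor(sqrt(p)), log2 = floor(log2(p)),
              stop(sprintf("unknown split-feature rule '%s'", rule),
                   call. = FALSE))
  max(1L, as.integer(m))
}

#' Train a class-weighted random forest
#'
#' Fits a probability forest on labeled examples with per-class
#' misclassification weights (see [class_weights()]); reproducible given
#' the seed.
#'
#' @param examples Labeled example `data.frame` (training partition).
#' @param hyper One-row hyperparameter `data.frame`
#'   (default [default_hyperparameters()]).
#' @param weights A `class_weight_table`, or `NULL` to compute Eq-style
#'   weights from the training counts.
#' @param seed Integer seed for forest randomness.
#'
#' @return An object of class `rbp_model`: list with the fitted forest,
#'   `classes` (training class order), `importance` (Gini importances
#'   normalized to sum to 1), `hyper`, `weights`, `seed` and
#'   `feature_names`.
#' @export
train_model <- function(examples, hyper = default_hyperparameters(),
                        weights = NULL, seed = 1) {
  feats <- example_feature_cols(examples)
  y <- factor(examples$label)
  if (nlevels(y) < 2L) {
    stop("training requires at least two classes", call. = FALSE)
  }
  if (is.null(weights)) {
    weights <- class_weights(table(examples$label))
  }
  stopifnot(inherits(weights, "class_weight_table"))
  cw <- weights$weights[levels(y)]
  if (anyNA(cw)) {
    stop("weight table does not cover every training class", call. = FALSE)
  }
  x <- examples[, feats, drop = FALSE]
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = hyper$n_trees,
    mtry = mtry_for(hyper$split_features, length(feats)),
    min.node.size = hyper$min_split,
    min.bucket = hyper$min_leaf,
    class.weights = unname(cw),
    probability = TRUE,
    importance = "impurity",
    seed = seed, num.threads = 1L,
    verbose = FALSE
  )
  imp <- fit$variable.importance
  imp_norm <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp),
                                                        length(imp))
  structure(list(forest = fit, classes = levels(y), importance = imp_norm,
                 hyper = hyper, weights = weights, seed = seed,
                 feature_names = feats),
            class = "rbp_model")
}

#' Predict class probabilities
#'
#' @param model An `rbp_model`.
#' @param features `data.frame`/matrix of feature columns matching training
#'   (extra columns such as `protein_id`/`label` are ignored).
#' @return Numeric matrix, one row per example, columns in `model$classes`
#'   order; rows are non-negative and sum to 1.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "rbp_model"))
  features <- as.data.frame(features)
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing)) {
    stop(sprintf("feature dimension mismatch; missing column(s): %s",
                 paste(utils::head(missing, 5L), collapse = ", ")),
         call. = FALSE)
  }
  x <- features[, model$feature_names, drop = FALSE]
  p <- stats::predict(model$forest, data = x, num.threads = 1L,
                      verbose = FALSE)$predictions
  p[, model$classes, drop = FALSE]
}

#' Rank feature components by Gini importance
#'
#' @param model An `rbp_model`.
#' @param l Number of components to return (1 <= l <= feature count).
#' @return Integer indices of the `l` most important components, descending
#'   importance, ties broken toward the lower index.
#' @export
top_gini_components <- function(model, l) {
  stopifnot(inherits(model, "rbp_model"))
  p <- length(model$importance)
  if (!is.numeric(l) || length(l) != 1L || l < 1 || l > p || l != floor(l)) {
    stop(sprintf("l must be an integer in [1, %d]", p), call. = FALSE)
  }
  order(-model$importance, seq_len(p))[seq_len(l)]
}

# Stratified fold assignment: round-robin within each class after a seeded
# shuffle, so every fold gets near-equal class composition.
stratified_folds <- function(labels, folds, seed) {
  counts <- table(labels)
  if (any(counts < folds)) {
    stop(sprintf("class(es) smaller than the fold count: %s",
                 paste(names(counts)[counts < folds], collapse = ", ")),
         call. = FALSE)
  }
  fold_of <- integer(length(labels))
  classes <- sort(names(counts))
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    idx <- with_seed(derive_seed(seed, 1000L + ci), sample(idx))
    fold_of[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold_of
}

#' Hyperparameter search by stratified cross-validation
#'
#' Scores every grid combination by k-fold stratified cross-validation on
#' the class-size-weighted F1 of plain arg-max predictions (confidence
#' threshold 0), and returns the best combination together with the full
#' score table. Deterministic given the seed; the result does not depend on
#' the order of the grid rows (ties go to the lexicographically first
#' combination in canonical grid order).
#'
#' @param examples Labeled example `data.frame` (training partition).
#' @param grid Hyperparameter `data.frame` (default [default_grid()]).
#' @param folds Number of CV folds (default 5).
#' @param seed Integer seed for folds and forests.
#' @return List with `best` (one-row `data.frame`), `cv` (grid with a
#'   `weighted_f1` column) and `folds`.
#' @export
tune_model <- function(examples, grid = default_grid(), folds = 5L, seed = 1) {
  stopifnot(nrow(grid) >= 1L)
  fold_of <- stratified_folds(examples$label, folds, seed)
  weights <- class_weights(table(examples$label))
  # canonical order makes tie-breaks independent of grid row order
  canon <- order(grid$n_trees, grid$split_features, grid$min_split,
                 grid$min_leaf)
  scores <- numeric(nrow(grid))
  for (gi in canon) {
    f1s <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- examples[fold_of != k, , drop = FALSE]
      te <- examples[fold_of == k, , drop = FALSE]
      fit <- train_model(tr, hyper = grid[gi, , drop = FALSE],
                         weights = weights, seed = derive_seed(seed, k))
      probs <- predict_proba(fit, te)
      finals <- thresholded_predict(probs, k = 0)$final_label
      counts <- count_outcomes(te$label, finals,
                               class_order = fit$classes)
      f1s[k] <- weighted_metrics(counts)$weighted_f1
    }
    scores[gi] <- mean(f1s)
  }
  best_gi <- canon[which.max(scores[canon])]
  cv <- grid
  cv$weighted_f1 <- scores
  list(best = grid[best_gi, , drop = FALSE], cv = cv, folds = folds)
}

#' Persist and restore a model manifest
#'
#' The manifest records hyperparameters, seed, class order and the weight
#' table as JSON next to the forest so runs are reproducible.
#'
#' @param model An `rbp_model`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_model_manifest <- function(model, path) {
  manifest <- list(
    hyperparameters = as.list(model$hyper),
    seed = model$seed,
    classes = model$classes,
    class_weights = as.list(model$weights$weights),
    feature_names = model$feature_names
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
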