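sep_examples <- function(n_classes = 3, per_class = 30, dim = 6,
                         separation = 8, seed = 1, skew = 1) {
  generate_separable_examples(
    corpus_spec(n_classes = n_classes, phages_per_class = per_class,
                rbps_per_phage = 1, separation = separation, skew = skew,
                seed = seed),
    dim = dim
  )
}

test_that("misclassification weights follow T/(t_c |C|) with conservation", {
  expect_equal(class_weights(c(a = 5, b = 5))$weights, c(a = 1, b = 1))
  expect_equal(class_weights(c(a = 8, b = 2))$weights, c(a = 0.625, b = 2.5))

  set.seed(99)
  for (i in 1:1000) {
    k <- sample(2:12, 1)
    t_c <- setNames(sample(1:500, k, replace = TRUE), paste0("c", seq_len(k)))
    cw <- class_weights(t_c)
    expect_equal(sum(t_c * cw$weights), sum(t_c), tolerance = 1e-9)
  }
  # scale invariance: doubling every count leaves weights unchanged
  t_c <- c(a = 3, b = 11, c = 40)
  expect_equal(class_weights(t_c)$weights, class_weights(2 * t_c)$weights)
  expect_error(class_weights(c(a = 0, b = 2)), "at least one")
})

test_that("the hyperparameter grid enumerates 96 combinations", {
  g <- default_grid()
  expect_equal(nrow(g), 96L)
  expect_equal(nrow(unique(g)), 96L)
  expect_setequal(unique(g$n_trees), c(50, 100, 150, 200))
  expect_setequal(unique(g$split_features), c("log2", "sqrt"))
  d <- default_hyperparameters()
  expect_equal(unname(unlist(d)), c("150", "sqrt", "2", "1"))
})

test_that("a weighted forest recovers well-separated synthetic classes", {
  ex <- sep_examples(separation = 8, skew = 0.7)
  fit <- train_model(ex, seed = 5)
  probs <- predict_proba(fit, ex)
  finals <- thresholded_predict(probs, k = 0)$final_label
  m <- weighted_metrics(count_outcomes(ex$label, finals, fit$classes))
  expect_gte(m$weighted_f1, 0.95)
})

test_that("training is seed-deterministic with normalized importances", {
  ex <- sep_examples(per_class = 15)
  f1 <- train_model(ex, seed = 11)
  f2 <- train_model(ex, seed = 11)
  expect_equal(predict_proba(f1, ex), predict_proba(f2, ex))
  expect_equal(sum(f1$importance), 1, tolerance = 1e-9)
  expect_error(train_model(ex[ex$label == ex$label[1], , drop = FALSE]),
               "two classes")
})

test_that("predicted probabilities are a distribution over the class order", {
  ex <- sep_examples(per_class = 12)
  fit <- train_model(ex, seed = 2)
  probs <- predict_proba(fit, ex)
  expect_equal(colnames(probs), fit$classes)
  expect_true(all(probs >= 0))
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)), tolerance = 1e-9)
  expect_error(predict_proba(fit, ex[, 1:4]), "mismatch")
})

test_that("a deep single tree concentrates mass on a training point's class", {
  ex <- sep_examples(per_class = 15, separation = 10)
  hyper <- data.frame(n_trees = 1L, split_features = "sqrt", min_split = 2L,
                      min_leaf = 1L, stringsAsFactors = FALSE)
  fit <- train_model(ex, hyper = hyper, seed = 3)
  p <- predict_proba(fit, ex[1, , drop = FALSE])
  expect_equal(colnames(p)[which.max(p)], ex$label[1])
  expect_gte(max(p), 0.99)
})

test_that("Gini component ranking sorts importances with index tie-breaks", {
  ex <- sep_examples(per_class = 12, dim = 5)
  fit <- train_model(ex, seed = 8)
  expect_equal(top_gini_components(fit, 5), order(-fit$importance, 1:5))
  expect_equal(top_gini_components(fit, 1), unname(which.max(fit$importance)))
  expect_error(top_gini_components(fit, 0), "in \\[1, 5\\]")
  expect_error(top_gini_components(fit, 6), "in \\[1, 5\\]")
  # synthetic tie-break check on a hand-built model object
  fake <- structure(list(importance = c(0.1, 0.4, 0.5)), class = "rbp_model")
  expect_equal(top_gini_components(fake, 2), c(3L, 2L))
  fake2 <- structure(list(importance = c(0.3, 0.4, 0.3)), class = "rbp_model")
  expect_equal(top_gini_components(fake2, 3), c(2L, 1L, 3L))
})

test_that("cross-validated tuning is deterministic and order-invariant", {
  ex <- sep_examples(n_classes = 2, per_class = 20, dim = 4, separation = 5)
  grid <- data.frame(n_trees = c(50L, 50L), split_features = "sqrt",
                     min_split = 2L, min_leaf = c(1L, 2L),
                     stringsAsFactors = FALSE)
  t1 <- tune_model(ex, grid, folds = 5, seed = 4)
  t2 <- tune_model(ex, grid[2:1, ], folds = 5, seed = 4)
  expect_equal(t1$best, t2$best, ignore_attr = TRUE)
  expect_equal(sort(t1$cv$weighted_f1), sort(t2$cv$weighted_f1))
  # singleton grid returns that combination
  single <- tune_model(ex, default_hyperparameters(), folds = 5, seed = 4)
  expect_equal(single$best, default_hyperparameters(), ignore_attr = TRUE)
  # the selected combination attains the maximum CV score
  expect_equal(max(t1$cv$weighted_f1),
               t1$cv$weighted_f1[which(t1$cv$min_leaf == t1$best$min_leaf &
                                         t1$cv$n_trees == t1$best$n_trees)])
  expect_error(tune_model(ex[c(1:4, 21:24), ], grid, folds = 5, seed = 1),
               "smaller")
})

test_that("model manifests round-trip hyperparameters and weights", {
  ex <- sep_examples(per_class = 10)
  fit <- train_model(ex, seed = 13)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_manifest(fit, path)
  manifest <- jsonlite::read_json(path)
  expect_equal(manifest$hyperparameters$n_trees, 150L)
  expect_equal(unlist(manifest$classes), fit$classes)
  expect_equal(manifest$seed, 13L)
})
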