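random_prob_matrix <- function(n, classes, seed) {
  set.seed(seed)
  p <- matrix(rexp(n * length(classes)), nrow = n,
              dimnames = list(NULL, classes))
  p / rowSums(p)
}

test_that("the confidence rule accepts iff the top-two gap reaches k", {
  p <- c(a = 0.6, b = 0.3, c = 0.1)
  expect_equal(thresholded_predict(p, 0.2)$final_label, "a")   # 0.3 >= 0.2
  expect_equal(thresholded_predict(p, 0.4)$final_label, others_label())
  expect_equal(thresholded_predict(p, 0.3)$final_label, "a")   # boundary

  # k = 0 always accepts the arg-max
  probs <- random_prob_matrix(50, c("a", "b", "c"), seed = 1)
  out <- thresholded_predict(probs, 0)
  expect_equal(out$final_label, out$argmax_label)
  expect_true(all(out$p1 >= out$p2))

  # exact tie: arg-max goes to class order, rejected whenever k > 0
  tie <- c(b = 0.4, a = 0.4, c = 0.2)
  expect_equal(thresholded_predict(tie, 0)$final_label, "b")
  expect_equal(thresholded_predict(tie, 1e-6)$final_label, others_label())

  expect_error(thresholded_predict(c(a = 1), 0), "two classes")
  expect_error(thresholded_predict(p, 1.5), "\\[0, 1\\]")
})

test_that("outcome counting reproduces the 6-sample worked case", {
  truths <- c("a", "a", "b", "b", others_label(), others_label())
  finals <- c("a", others_label(), "b", "b", others_label(), "a")
  counts <- count_outcomes(truths, finals, c("a", "b"))

  a <- counts[counts$class == "a", ]
  expect_equal(c(a$tp, a$fp, a$fn, a$tn), c(1, 1, 1, 3))
  o <- counts[counts$class == others_label(), ]
  expect_equal(c(o$tp, o$fp, o$fn, o$tn), c(1, 1, 1, 3))

  # per-class identities
  expect_true(all(counts$tp + counts$fn == counts$n))
  expect_true(all(counts$tp + counts$fp + counts$tn + counts$fn == 6))
  # correctly labeled samples partition into per-class TPs
  expect_equal(sum(counts$tp), sum(truths == finals))

  m <- weighted_metrics(counts)
  expect_equal(m$weighted_precision, 2 / 3, tolerance = 1e-12)
  expect_equal(m$weighted_recall, 2 / 3, tolerance = 1e-12)
  expect_equal(m$weighted_specificity, 5 / 6, tolerance = 1e-12)
  expect_equal(m$weighted_f1, 2 / 3, tolerance = 1e-12)

  expect_error(count_outcomes(c("a", "z"), c("a", "a"), c("a", "b")),
               "outside the class order")
})

test_that("perfect predictions score 1 on all weighted metrics", {
  truths <- c("a", "a", "b", others_label())
  m <- weighted_metrics(count_outcomes(truths, truths, c("a", "b")))
  expect_equal(m$weighted_precision, 1)
  expect_equal(m$weighted_recall, 1)
  expect_equal(m$weighted_specificity, 1)
  expect_equal(m$weighted_f1, 1)
})

test_that("weighted metrics equal an independent one-vs-rest oracle", {
  classes <- c("a", "b", "c", "d")
  all_labels <- c(classes, others_label())
  set.seed(23)
  for (i in 1:1000) {
    n <- sample(5:40, 1)
    truths <- sample(all_labels, n, replace = TRUE)
    finals <- sample(all_labels, n, replace = TRUE)
    m <- weighted_metrics(count_outcomes(truths, finals, classes))
    oracle <- oracle_weighted_metrics(truths, finals, all_labels)
    expect_equal(m$weighted_precision, oracle[["precision"]], tolerance = 1e-12)
    expect_equal(m$weighted_recall, oracle[["recall"]], tolerance = 1e-12)
    expect_equal(m$weighted_specificity, oracle[["specificity"]],
                 tolerance = 1e-12)
    expect_equal(m$weighted_f1, oracle[["f1"]], tolerance = 1e-12)
  }
})

test_that("rejections grow and per-class recall shrinks as k increases", {
  classes <- c("a", "b", "c", "d", "e")
  probs <- random_prob_matrix(1000, classes, seed = 31)
  set.seed(32)
  truths <- sample(c(classes, others_label()), 1000, replace = TRUE,
                   prob = c(rep(0.18, 5), 0.1))
  sweep <- metrics_over_thresholds(truths, probs)
  expect_equal(nrow(sweep), 11L)
  expect_equal(sweep$k, seq(0, 1, by = 0.1))
  # monotone rejection count
  expect_true(all(diff(sweep$n_others) >= 0))
  # per-class recall of every non-others class is non-increasing in k
  reports <- attr(sweep, "reports")
  for (cl in classes) {
    rec <- vapply(reports, function(r) {
      r$per_class$recall[r$per_class$class == cl]
    }, numeric(1))
    expect_true(all(diff(rec) <= 1e-12))
  }
  # at k = 0 nothing is rejected by the threshold
  pred0 <- thresholded_predict(probs, 0)
  expect_equal(sweep$n_others[1], sum(pred0$argmax_label == others_label()))
  expect_error(metrics_over_thresholds(truths, probs, numeric(0)), "non-empty")
})

test_that("evaluate_model ties the pipeline together on labeled examples", {
  spec <- corpus_spec(n_classes = 3, phages_per_class = 20, rbps_per_phage = 1,
                      separation = 8, seed = 2)
  ex <- generate_separable_examples(spec, dim = 6)
  sp <- stratified_split(ex, 0.7, seed = 3)
  fit <- train_model(sp$train, seed = 4)
  sweep <- evaluate_model(fit, sp$test, k_grid = c(0, 0.5, 1))
  expect_equal(nrow(sweep), 3L)
  expect_gte(sweep$weighted_f1[1], 0.9)
  expect_true(all(sweep$weighted_precision >= 0 & sweep$weighted_precision <= 1))
})
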