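test_that("confusion matrix counts, conserves supports, validates labels", {
  a <- c(rep("A", 10), rep("B", 5))
  p <- c(rep("A", 8), "B", "B", rep("B", 5))
  cm <- confusion(a, p, classes = c("A", "B"))
  expect_equal(cm$counts["A", "A"], 8L)
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 2L)
  expect_equal(unname(rowSums(cm$counts)), c(10L, 5L))       # per-class supports
  expect_equal(unname(cm$percent["A", ]), c(80, 20))         # row-percentage view
  # perfect predictions give a diagonal matrix
  cmp <- confusion(a, a, classes = c("A", "B"))
  expect_true(all(cmp$counts[upper.tri(cmp$counts) | lower.tri(cmp$counts)] == 0))
  expect_error(confusion(a, p, classes = "A"), class = "gleason_validation_error")
  expect_error(confusion(1:3, 1:4), class = "gleason_validation_error")
})

test_that("metrics: direct arithmetic and edge conventions", {
  # TP=8, FP=2, FN=2 -> precision = recall = F1 = 0.8
  cm <- confusion(c(rep(1, 10), rep(2, 10)),
                  c(rep(1, 8), 2, 2, 1, 1, rep(2, 8)), classes = 1:2)
  mt <- metrics(cm)
  expect_equal(mt$per_class$precision[1], 0.8)
  expect_equal(mt$per_class$recall[1], 0.8)
  expect_equal(mt$per_class$f1[1], 0.8)
  # perfect diagonal -> all ones
  mt1 <- metrics(confusion(rep(1:3, each = 5), rep(1:3, each = 5), classes = 1:3))
  expect_equal(mt1$accuracy, 1)
  expect_true(all(mt1$per_class$f1 == 1))
  # never-predicted class: precision 0 with warning
  cm0 <- confusion(c(1, 1, 2), c(1, 1, 1), classes = 1:2)
  expect_warning(m0 <- metrics(cm0), "precision")
  expect_equal(m0$per_class$precision[2], 0)
})

test_that("metrics equal a brute-force recount on many random matrices", {
  set.seed(123)
  for (rep in 1:100) {
    K <- sample(2:5, 1)
    n <- sample(20:60, 1)
    actual <- sample(seq_len(K), n, replace = TRUE)
    predicted <- sample(seq_len(K), n, replace = TRUE)
    mt <- suppressWarnings(metrics(confusion(actual, predicted, classes = seq_len(K))))
    # naive per-class recount from the raw label vectors
    for (k in seq_len(K)) {
      tp <- sum(actual == k & predicted == k)
      fp <- sum(actual != k & predicted == k)
      fn <- sum(actual == k & predicted != k)
      pr <- if (tp + fp == 0) 0 else tp / (tp + fp)
      re <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f1 <- if (pr + re == 0) 0 else 2 * pr * re / (pr + re)
      expect_equal(mt$per_class$precision[k], pr)
      expect_equal(mt$per_class$recall[k], re)
      expect_equal(mt$per_class$f1[k], f1)
    }
    expect_equal(mt$accuracy, mean(actual == predicted))
    expect_equal(unname(mt$macro_avg["f1"]), mean(mt$per_class$f1))
    w <- mt$per_class$support / n
    expect_equal(unname(mt$weighted_avg["precision"]),
                 sum(mt$per_class$precision * w))
  }
})

test_that("weighted average equals macro average under equal supports", {
  a <- rep(1:3, each = 10)
  p <- withr::with_seed(5, sample(1:3, 30, replace = TRUE))
  mt <- suppressWarnings(metrics(confusion(a, p, classes = 1:3)))
  expect_equal(mt$weighted_avg, mt$macro_avg)
})

test_that("ROC: hand-computed case, perfect separation, chance level", {
  # 4 scores, enumerated by hand: concordant pairs 3/4 -> AUC 0.75
  r <- roc_curve(c(0.9, 0.8, 0.4, 0.2), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(r$auc, 0.75)
  expect_true(all(r$points$tpr >= 0 & r$points$tpr <= 1))
  # perfectly separated scores
  expect_equal(roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  # scores independent of truth: AUC near 0.5 at large n
  set.seed(77)
  sc <- runif(4000); tr <- runif(4000) > 0.5
  expect_lt(abs(roc_curve(sc, tr)$auc - 0.5), 0.03)
  expect_error(roc_curve(c(0.1, 0.2), c(TRUE, TRUE)), class = "gleason_validation_error")
})
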