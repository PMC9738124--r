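test_that("node specifications form the label-resolving binary tree", {
  n1 <- cascade_node_spec(1)
  expect_equal(n1$negative_set, c(1L, 2L))
  expect_equal(n1$positive_set, c(3L, 4L, 5L))
  expect_equal(cascade_node_spec(2)$negative_set, 1L)
  expect_equal(cascade_node_spec(3)$positive_set, c(4L, 5L))
  expect_equal(cascade_node_spec(4)$positive_set, 5L)
  expect_error(cascade_node_spec(5), class = "gleason_validation_error")
})

test_that("balance_training_set equalizes counts at the rarest class", {
  labels <- rep(1:5, times = c(400, 300, 200, 150, 100))
  idx <- balance_training_set(labels, seed = 3)
  expect_equal(as.integer(table(labels[idx])), rep(100L, 5))
  # sampling without replacement
  expect_false(any(duplicated(idx)))
  # determinism
  expect_identical(idx, balance_training_set(labels, seed = 3))
  expect_false(identical(idx, balance_training_set(labels, seed = 4)))
  # already balanced input comes back complete
  bal <- rep(1:5, each = 20)
  expect_setequal(balance_training_set(bal, seed = 1), seq_along(bal))
  expect_error(balance_training_set(c(1, 2, 3, 4), seed = 1),
               class = "gleason_validation_error")
})

test_that("routing resolves every node-decision pattern to exactly one label", {
  # exhaustive check over the 2^4 hard decision patterns via synthetic oracle
  # nodes whose windows force each branch
  mk_batch <- function(label) {
    labs <- array(label, dim = c(4L, 4L, 1L))
    list(rgb = array(0, dim = c(4, 4, 3, 1)), labels = labs)
  }
  nodes <- lapply(1:4, function(i) {
    structure(list(spec = cascade_node_spec(i), backend = oracle_backend(),
                   fit = NULL), class = "cascade_node")
  })
  for (lab in 1:5) {
    out <- classify_patches(nodes, mk_batch(lab))
    expect_identical(out, lab)
    out2 <- classify_patches(nodes, mk_batch(lab), route = "path_product")
    expect_identical(out2, lab)
  }
})

test_that("oracle cascade reproduces Algorithm-1 labels on selected patches", {
  sl <- tiny_slide(5)
  lv <- level_config(20)
  sel <- select_training_patches(sl, lv)
  recs <- sel$records[sel$records$selected, ]
  nodes <- lapply(1:4, function(i) {
    structure(list(spec = cascade_node_spec(i), backend = oracle_backend(),
                   fit = NULL), class = "cascade_node")
  })
  n <- nrow(recs)
  labs <- array(0L, dim = c(20, 20, n))
  for (i in seq_len(n)) {
    labs[, , i] <- gleasonCascade:::window_matrix(sl$label_map, recs$row[i],
                                                  recs$col[i], 20L, 0L)
  }
  batch <- list(rgb = array(0, dim = c(20, 20, 3, n)), labels = labs)
  expect_identical(classify_patches(nodes, batch), recs$MV)
})

test_that("train_node with the oracle backend is exact; empty side errors", {
  x <- array(0, dim = c(8, 8, 3, 10))
  y <- rep(c(1L, 3L), 5)
  nd <- train_node(cascade_node_spec(1), x, y, oracle_backend())
  expect_equal(nd$val_accuracy, 1.0)
  expect_error(train_node(cascade_node_spec(4), x, y, oracle_backend()),
               class = "gleason_validation_error")
})

test_that("trained cascade records history and tuning; size mismatch errors", {
  mk <- function(n, seed) {
    withr::with_seed(seed, {
      y <- rep(1:5, length.out = n)
      x <- array(0, dim = c(10, 10, 3, n))
      cols <- rbind(c(230, 170, 200), c(220, 205, 170), c(175, 140, 205),
                    c(135, 100, 175), c(60, 75, 145))
      for (i in seq_len(n)) for (ch in 1:3) {
        x[, , ch, i] <- cols[y[i], ch] + rnorm(100, sd = 10)
      }
      list(x = x, y = y)
    })
  }
  d <- mk(80, 3)
  tune <- tuning_config(n_trials = 2L, seed = 11)
  nd <- train_node(cascade_node_spec(1), d$x, d$y,
                   tinycnn_backend(epochs = 12L, patience = 12L, batch = 8L),
                   tune, seed = 5)
  expect_s3_class(nd, "cascade_node")
  expect_equal(nrow(nd$tuning), 2L)
  expect_true(all(c("epoch", "train_loss", "val_loss", "val_accuracy") %in%
                    names(nd$history)))
  expect_gte(nd$val_accuracy, 0.9)  # trivially color-separable binary task
  # patch size mismatch is refused at classification time
  batch <- list(rgb = array(0, dim = c(8, 8, 3, 2)), labels = NULL)
  nodes <- lapply(1:4, function(i) nd)
  expect_error(classify_patches(nodes, batch), class = "gleason_validation_error")
})
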