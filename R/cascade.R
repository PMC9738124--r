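#' Node specifications of the binary cascade
#'
#' Four binary classifiers resolve the five GP labels per level:
#' node 1 separates \{1,2\} from \{3,4,5\}; node 2 separates 1 from 2;
#' node 3 separates 3 from \{4,5\}; node 4 separates 4 from 5.  The
#' "positive" side of each node is the higher-grade group.
#'
#' @param node_id 1..4.
#' @return object of class \code{cascade_node_spec} with \code{negative_set}
#'   and \code{positive_set}.
#' @export
cascade_node_spec <- function(node_id) {
  sets <- list(
    list(neg = c(1L, 2L), pos = c(3L, 4L, 5L)),
    list(neg = 1L, pos = 2L),
    list(neg = 3L, pos = c(4L, 5L)),
    list(neg = 4L, pos = 5L)
  )
  if (!node_id %in% 1:4) abort_validation("node_id must be in 1..4")
  s <- sets[[node_id]]
  structure(list(node_id = as.integer(node_id),
                 negative_set = s$neg, positive_set = s$pos),
            class = "cascade_node_spec")
}

#' Balance a training set by downsampling to the rarest class
#'
#' Every GP label is randomly downsampled (without replacement, seeded) to the
#' count of the rarest class — GP5 in realistic biopsy data, mirroring the
#' training regime that matches every class to the GP5 patch count.
#'
#' @param labels integer vector of GP labels (1..5), one per patch.
#' @param seed RNG seed.
#' @param classes the label set that must all be present (default 1..5).
#' @return integer vector of indices into \code{labels} forming the balanced
#'   set (sorted within class in sampled order).
#' @export
balance_training_set <- function(labels, seed = 1L, classes = 1:5) {
  counts <- table(factor(labels, levels = classes))
  if (any(counts == 0)) {
    abort_validation(paste("no training patches for class",
                           paste(names(counts)[counts == 0], collapse = ", ")))
  }
  target <- min(counts)
  with_seed(seed, {
    idx <- unlist(lapply(classes, function(cl) {
      pool <- which(labels == cl)
      if (length(pool) == target) pool else sample(pool, target)
    }), use.names = FALSE)
  })
  idx
}

# ---- classifier backends --------------------------------------------------

#' Oracle classifier backend
#'
#' A test double: "prediction" is the ground-truth modal tissue label of the
#' patch window, mapped to probability 1 on the matching side of the node.
#' Isolates tiling / fusion / grading plumbing from classifier quality.
#' @return backend object.
#' @export
oracle_backend <- function() structure(list(kind = "oracle"), class = c("oracle_backend", "classifier_backend"))

#' Tiny-CNN classifier backend
#'
#' @param filters,fc_units,dropout architecture knobs
#'   (\code{\link{tinycnn_architecture}}).
#' @param lr,batch,epochs,patience training knobs (\code{\link{tinycnn_train}});
#'   random search may override knobs listed in the tuning config's space.
#' @return backend object.
#' @export
tinycnn_backend <- function(filters = c(16L, 32L, 64L), fc_units = 64L,
                            dropout = 0.25, lr = 1e-3, batch = 32L,
                            epochs = 30L, patience = 6L) {
  structure(list(kind = "tiny_cnn", filters = filters, fc_units = fc_units,
                 dropout = dropout, lr = lr, batch = batch, epochs = epochs,
                 patience = patience),
            class = c("tinycnn_backend", "classifier_backend"))
}

#' Random-search tuning configuration
#'
#' Random search draws \code{n_trials} hyperparameter settings (learning rate
#' log-uniform, dropout uniform, filter sets and batch size categorical) and
#' keeps the trial with the best validation accuracy.
#'
#' @param n_trials number of random draws (>= 1); 1 = train once at defaults.
#' @param lr_range log10 bounds for the learning rate.
#' @param dropout_range uniform bounds for dropout.
#' @param filter_sets list of filter-count vectors to choose among.
#' @param batch_sizes candidate mini-batch sizes.
#' @param seed RNG seed for the trial sequence.
#' @return object of class \code{tuning_config}.
#' @export
tuning_config <- function(n_trials = 3L, lr_range = c(-3.3, -2.2),
                          dropout_range = c(0.1, 0.4),
                          filter_sets = list(c(8L, 16L), c(8L, 16L, 32L), c(16L, 32L)),
                          batch_sizes = c(16L, 32L), seed = 1L) {
  if (n_trials < 1L) abort_validation("n_trials must be >= 1")
  structure(list(n_trials = as.integer(n_trials), lr_range = lr_range,
                 dropout_range = dropout_range, filter_sets = filter_sets,
                 batch_sizes = batch_sizes, seed = as.integer(seed)),
            class = "tuning_config")
}

# ground-truth modal label of each window in an (S, S, N) label array;
# windows with no tissue default to label 1 (their votes only ever land on
# background pixels, which grading ignores)
batch_modal_labels <- function(labels) {
  N <- dim(labels)[3]
  out <- integer(N)
  for (i in seq_len(N)) {
    m <- modal_label(labels[, , i], ties_na = FALSE)
    out[i] <- if (is.na(m)) 1L else m
  }
  out
}

#' Train one cascade node
#'
#' Filters the (already balanced) patch pool to the node's labels, maps them
#' to the binary task, splits off a stratified validation set, and trains the
#' backend — with random search over the tuning space when the backend learns.
#'
#' @param node a \code{\link{cascade_node_spec}}.
#' @param x (S, S, 3, N) patch array.
#' @param y integer GP labels (1..5) aligned with \code{x}.
#' @param backend an \code{\link{oracle_backend}} or
#'   \code{\link{tinycnn_backend}}.
#' @param tuning a \code{\link{tuning_config}}.
#' @param seed RNG seed (validation split, training).
#' @param val_fraction stratified validation share.
#' @return object of class \code{cascade_node}: the node spec, fitted backend
#'   payload, validation accuracy, and training history.
#' @export
train_node <- function(node, x, y, backend, tuning = tuning_config(), seed = 1L,
                       val_fraction = 0.25) {
  stopifnot(inherits(node, "cascade_node_spec"))
  keep <- y %in% c(node$negative_set, node$positive_set)
  y2 <- ifelse(y[keep] %in% node$positive_set, 2L, 1L)
  if (length(unique(y2)) < 2L) {
    abort_validation(sprintf("node %d: one side of the binary task is empty", node$node_id))
  }
  if (inherits(backend, "oracle_backend")) {
    return(structure(list(spec = node, backend = backend, fit = NULL,
                          val_accuracy = 1.0, history = NULL, tuning = NULL),
                     class = "cascade_node"))
  }
  xk <- x[, , , keep, drop = FALSE]
  # stratified train/validation split
  split <- with_seed(derive_seed(seed, "split", node$node_id), {
    val <- unlist(lapply(1:2, function(cl) {
      pool <- which(y2 == cl)
      sample(pool, max(1L, round(val_fraction * length(pool))))
    }), use.names = FALSE)
    val
  })
  tr <- setdiff(seq_along(y2), split)
  S <- dim(xk)[1]
  trials <- with_seed(derive_seed(tuning$seed, "rs", node$node_id), {
    lapply(seq_len(tuning$n_trials), function(i) {
      list(lr = 10^runif(1, tuning$lr_range[1], tuning$lr_range[2]),
           dropout = runif(1, tuning$dropout_range[1], tuning$dropout_range[2]),
           filters = tuning$filter_sets[[sample.int(length(tuning$filter_sets), 1L)]],
           batch = sample(tuning$batch_sizes, 1L))
    })
  })
  if (tuning$n_trials == 1L) {
    trials[[1]] <- list(lr = backend$lr, dropout = backend$dropout,
                        filters = backend$filters, batch = backend$batch)
  }
  best <- NULL
  trial_log <- data.frame()
  for (ti in seq_along(trials)) {
    tp <- trials[[ti]]
    arch <- tinycnn_architecture(S, filters = tp$filters,
                                 fc_units = backend$fc_units, dropout = tp$dropout)
    fit <- tinycnn_train(xk[, , , tr, drop = FALSE], y2[tr], arch,
                         xk[, , , split, drop = FALSE], y2[split],
                         lr = tp$lr, batch = tp$batch, epochs = backend$epochs,
                         patience = backend$patience,
                         seed = derive_seed(seed, "trial", node$node_id, ti))
    trial_log <- rbind(trial_log,
                       data.frame(trial = ti, lr = tp$lr, dropout = tp$dropout,
                                  filters = paste(tp$filters, collapse = "-"),
                                  batch = tp$batch, val_accuracy = fit$val_accuracy))
    if (is.null(best) || fit$val_accuracy > best$val_accuracy) {
      best <- fit
      best$trial <- ti
    }
  }
  structure(list(spec = node, backend = backend, fit = best$model,
                 val_accuracy = best$val_accuracy, history = best$history,
                 tuning = trial_log),
            class = "cascade_node")
}

# node-level probabilities for a patch batch: N x 2 (neg side, pos side)
node_predict <- function(node, batch) {
  if (inherits(node$backend, "oracle_backend")) {
    if (is.null(batch$labels)) {
      abort_validation("oracle backend needs ground-truth label windows")
    }
    truth <- batch_modal_labels(batch$labels)
    pos <- truth %in% node$spec$positive_set
    cbind(ifelse(pos, 0, 1), ifelse(pos, 1, 0))
  } else {
    tinycnn_predict(node$fit, batch$rgb)
  }
}

#' Classify patches through the four-node cascade of one level
#'
#' Routing: node 1 picks \{1,2\} vs \{3,4,5\}; node 2 resolves 1 vs 2;
#' node 3 resolves 3 vs \{4,5\}; node 4 resolves 4 vs 5.  With
#' \code{route = "argmax"} (default) each node decides by hard argmax
#' (probability ties resolve to the lower-grade side); with
#' \code{route = "path_product"} the five path probabilities are multiplied
#' out and the argmax label (ties to the lower label) is returned.
#'
#' @param level_nodes list of four fitted \code{cascade_node}s (ids 1..4).
#' @param batch list with \code{rgb} = (S, S, 3, N) array and, for the oracle
#'   backend, \code{labels} = (S, S, N) ground-truth windows.
#' @param route routing rule.
#' @return integer vector of GP labels in 1..5.
#' @export
classify_patches <- function(level_nodes, batch, route = c("argmax", "path_product")) {
  route <- match.arg(route)
  N <- dim(batch$rgb)[4]
  S <- dim(batch$rgb)[1]
  for (nd in level_nodes) {
    if (!inherits(nd$backend, "oracle_backend") && !is.null(nd$fit) &&
        nd$fit$arch$input_size != S) {
      abort_validation(sprintf("patch size %d does not match node input size %d",
                               S, nd$fit$arch$input_size))
    }
  }
  sub_batch <- function(b, ids) {
    list(rgb = b$rgb[, , , ids, drop = FALSE],
         labels = if (is.null(b$labels)) NULL else b$labels[, , ids, drop = FALSE])
  }
  if (route == "path_product") {
    p1 <- node_predict(level_nodes[[1]], batch)
    p2 <- node_predict(level_nodes[[2]], batch)
    p3 <- node_predict(level_nodes[[3]], batch)
    p4 <- node_predict(level_nodes[[4]], batch)
    P <- cbind(p1[, 1] * p2[, 1],            # 1
               p1[, 1] * p2[, 2],            # 2
               p1[, 2] * p3[, 1],            # 3
               p1[, 2] * p3[, 2] * p4[, 1],  # 4
               p1[, 2] * p3[, 2] * p4[, 2])  # 5
    return(max.col(P, ties.method = "first"))
  }
  out <- integer(N)
  p1 <- node_predict(level_nodes[[1]], batch)
  lo <- which(p1[, 2] <= 0.5)   # ties -> lower-grade side
  hi <- which(p1[, 2] > 0.5)
  if (length(lo)) {
    p2 <- node_predict(level_nodes[[2]], sub_batch(batch, lo))
    out[lo] <- ifelse(p2[, 2] > 0.5, 2L, 1L)
  }
  if (length(hi)) {
    bh <- sub_batch(batch, hi)
    p3 <- node_predict(level_nodes[[3]], bh)
    is45 <- p3[, 2] > 0.5
    out[hi[!is45]] <- 3L
    if (any(is45)) {
      p4 <- node_predict(level_nodes[[4]], sub_batch(bh, which(is45)))
      out[hi[is45]] <- ifelse(p4[, 2] > 0.5, 5L, 4L)
    }
  }
  out
}
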