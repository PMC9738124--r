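#' Train the full cascade (four nodes per level) on labeled slides
#'
#' For each level: slides are equalized (and optionally edge-enhanced),
#' training patches are selected on the unshifted grid (modal label == center
#' label, background ratio <= 0.5), the pooled patches are balanced once at
#' the 5-class level by downsampling to the rarest class, and the four binary
#' nodes are trained on their respective regroupings.
#'
#' @param slides list of labeled \code{\link{slide_image}}s.
#' @param levels list of \code{\link{level_config}}s (default 100/75/50).
#' @param backend classifier backend (\code{\link{tinycnn_backend}} or
#'   \code{\link{oracle_backend}}).
#' @param tuning a \code{\link{tuning_config}}.
#' @param preprocess a \code{\link{preprocess_config}}.
#' @param seed master seed; all sub-seeds derive from it.
#' @return object of class \code{cascade_model}: per-level lists of four
#'   fitted \code{cascade_node}s plus the configuration and a seed manifest.
#' @export
train_cascade <- function(slides, levels = default_levels(),
                          backend = tinycnn_backend(), tuning = tuning_config(),
                          preprocess = preprocess_config(), seed = 1L) {
  for (s in slides) {
    if (is.null(s$label_map)) abort_validation("all training slides need label maps")
  }
  prepped <- lapply(slides, preprocess_slide, cfg = preprocess)
  level_models <- vector("list", length(levels))
  level_info <- list()
  oracle <- inherits(backend, "oracle_backend")
  for (li in seq_along(levels)) {
    lv <- levels[[li]]
    if (oracle) {  # nothing to fit: each node echoes ground truth
      level_models[[li]] <- lapply(1:4, function(nid) {
        structure(list(spec = cascade_node_spec(nid), backend = backend,
                       fit = NULL, val_accuracy = 1.0, history = NULL,
                       tuning = NULL), class = "cascade_node")
      })
      level_info[[li]] <- list(S = lv$S, n_selected = 0L, n_balanced = 0L,
                               val_accuracy = rep(1.0, 4))
      next
    }
    pool_x <- list(); pool_y <- integer(0)
    for (s in prepped) {
      sel <- select_training_patches(s, lv, cfg = preprocess)
      for (p in sel$patches) {
        pool_x[[length(pool_x) + 1L]] <- p$rgb
        pool_y <- c(pool_y, p$label)
      }
    }
    if (!length(pool_y)) abort_validation(sprintf("level S=%d selected no patches", lv$S))
    bal <- balance_training_set(pool_y, seed = derive_seed(seed, "balance", lv$S))
    x <- array(0, dim = c(lv$S, lv$S, 3L, length(bal)))
    for (i in seq_along(bal)) x[, , , i] <- pool_x[[bal[i]]]
    y <- pool_y[bal]
    nodes <- lapply(1:4, function(nid) {
      train_node(cascade_node_spec(nid), x, y, backend, tuning,
                 seed = derive_seed(seed, "node", lv$S, nid))
    })
    level_models[[li]] <- nodes
    level_info[[li]] <- list(S = lv$S, n_selected = length(pool_y),
                             n_balanced = length(bal),
                             val_accuracy = vapply(nodes, `[[`, 0, "val_accuracy"))
  }
  structure(list(levels = levels, nodes = level_models, backend = backend,
                 preprocess = preprocess, info = level_info, seed = seed),
            class = "cascade_model")
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("<cascade_model> %d level(s), backend %s\n",
              length(x$levels), x$backend$kind))
  for (info in x$info) {
    cat(sprintf("  S=%3d: %d patches selected, %d balanced; node val acc %s\n",
                info$S, info$n_selected, info$n_balanced,
                paste(sprintf("%.2f", info$val_accuracy), collapse = " ")))
  }
  invisible(x)
}

# label image of one group: every pixel gets the label of the single patch
# covering it in that group
paint_group <- function(dims, grp, labels) {
  H <- dims[1]; W <- dims[2]
  img <- matrix(1L, H, W)
  S <- grp$S
  for (i in seq_len(nrow(grp$refs))) {
    r0 <- grp$refs$row[i]; c0 <- grp$refs$col[i]
    rr <- max(r0, 0L):min(r0 + S - 1L, H - 1L)
    cc <- max(c0, 0L):min(c0 + S - 1L, W - 1L)
    if (rr[1] <= rr[length(rr)] && cc[1] <= cc[length(cc)]) {
      img[rr + 1L, cc + 1L] <- labels[i]
    }
  }
  img
}

#' Grade one slide end-to-end
#'
#' Preprocesses the slide, runs every patch of every group of every level
#' through the cascade, paints per-group label images, fuses the 39 votes
#' per pixel by majority, and derives GS/GG from the fused GP map.
#'
#' @param model a \code{\link{cascade_model}}.
#' @param slide a \code{\link{slide_image}} (ground truth only needed for the
#'   oracle backend).
#' @param benign_threshold,tie see \code{\link{grade_from_gp_map}} and
#'   \code{\link{majority_vote}}.
#' @param route routing rule, see \code{\link{classify_patches}}.
#' @return list with \code{gp_map} (fused H x W GP labels), \code{grade}
#'   (a \code{grade_result}), \code{stack} (the \code{vote_stack}),
#'   \code{tissue} (logical mask used for grading) and \code{n_groups}.
#' @export
grade_slide <- function(model, slide, benign_threshold = 0.005,
                        tie = "lower", route = "argmax") {
  stopifnot(inherits(model, "cascade_model"))
  oracle <- inherits(model$backend, "oracle_backend")
  prepped <- preprocess_slide(slide, model$preprocess)
  dims <- dim(prepped$rgb)[1:2]
  label_images <- list()
  for (li in seq_along(model$levels)) {
    groups <- generate_patch_groups(prepped, model$levels[[li]])
    for (grp in groups) {
      batch <- extract_group_batch(prepped, grp, with_labels = oracle)
      labels <- classify_patches(model$nodes[[li]], batch, route = route)
      label_images[[length(label_images) + 1L]] <- paint_group(dims, grp, labels)
    }
  }
  stack <- accumulate_votes(label_images)
  gp_map <- majority_vote(stack, tie = tie)
  tissue <- tissue_mask(prepped, model$preprocess)
  grade <- grade_from_gp_map(gp_map, tissue, benign_threshold = benign_threshold)
  list(gp_map = gp_map, grade = grade, stack = stack, tissue = tissue,
       n_groups = length(label_images))
}

#' Grade directly from a ground-truth label map
#'
#' The reference against which the pipeline's slide-level output is checked:
#' applies \code{\link{grade_from_gp_map}} straight to the ground truth.
#'
#' @param label_map H x W integer matrix, 0 = background.
#' @param benign_threshold as in \code{\link{grade_from_gp_map}}.
#' @return a \code{grade_result}.
#' @export
grade_from_truth <- function(label_map, benign_threshold = 0.005) {
  grade_from_gp_map(label_map, label_map != 0L, benign_threshold = benign_threshold)
}

#' Boundary-quantization bound for pixel-wise GP accuracy
#'
#' Patch-level classification cannot resolve labels finer than a patch, so
#' fused maps may err near class boundaries.  This computes the fraction of
#' tissue pixels lying within Chebyshev distance \code{radius} (typically the
#' largest patch size) of any pixel with a different label (background
#' included); 1 minus this fraction lower-bounds the pixel accuracy an ideal
#' patch classifier can be held to.
#'
#' @param label_map ground-truth H x W label matrix.
#' @param radius Chebyshev radius in pixels.
#' @return fraction of tissue pixels near a boundary, in [0, 1].
#' @export
boundary_fraction <- function(label_map, radius) {
  H <- nrow(label_map); W <- ncol(label_map)
  b <- matrix(FALSE, H, W)
  b[-H, ] <- b[-H, ] | (label_map[-H, ] != label_map[-1, ])
  b[-1, ] <- b[-1, ] | (label_map[-1, ] != label_map[-H, ])
  b[, -W] <- b[, -W] | (label_map[, -W] != label_map[, -1])
  b[, -1] <- b[, -1] | (label_map[, -1] != label_map[, -W])
  near <- dilate_chebyshev(b, radius)
  tissue <- label_map != 0L
  if (!any(tissue)) abort_validation("no tissue in label map")
  mean(near[tissue])
}

#' Pixel-wise GP accuracy of a fused map against ground truth
#'
#' @param gp_map fused GP label map.
#' @param label_map ground truth.
#' @return accuracy over tissue pixels.
#' @export
pixel_accuracy <- function(gp_map, label_map) {
  tissue <- label_map != 0L
  mean(gp_map[tissue] == label_map[tissue])
}
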