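#' Level configuration for pyramidal tiling
#'
#' One analysis level = one square patch size S.  Overlapping coverage is
#' obtained from 1 + 3*(1/shift_fraction - 1) complete non-overlapping tilings
#' ("patch groups"): the unshifted grid plus, for each direction (X = columns,
#' Y = rows, diagonal = both), every shift step k*shift_fraction*S short of a
#' full period.  At the default 20\% shift that is 13 groups per level: five
#' shift steps return the grid to its origin, so four shifted groups exist per
#' direction.
#'
#' @param S patch side length in pixels (paper levels: 100, 75, 50).
#' @param shift_fraction fraction of S per shift step; \code{S*shift_fraction}
#'   must be a whole number of pixels and \code{1/shift_fraction} an integer.
#' @return object of class \code{level_config}.
#' @export
level_config <- function(S, shift_fraction = 0.2) {
  S <- as.integer(S)
  if (S <= 0) abort_validation("S must be positive")
  if (shift_fraction <= 0 || shift_fraction >= 1) {
    abort_validation("shift_fraction must be in (0, 1)")
  }
  inv <- 1 / shift_fraction
  if (abs(inv - round(inv)) > 1e-9) {
    abort_validation("1/shift_fraction must be an integer")
  }
  step <- S * shift_fraction
  if (abs(step - round(step)) > 1e-9) {
    abort_validation("S * shift_fraction must be a whole number of pixels")
  }
  structure(list(S = S, shift_fraction = shift_fraction,
                 step_px = as.integer(round(step)),
                 n_steps = as.integer(round(inv))),
            class = "level_config")
}

#' Default pyramid: patch sizes 100, 75 and 50 with 20\% shifts
#' @return list of three \code{\link{level_config}}s.
#' @export
default_levels <- function() lapply(c(100L, 75L, 50L), level_config)

#' Generate all patch groups of one level
#'
#' Each group is a complete tiling: its grid is anchored at \code{offset - S}
#' (so shifted grids start one patch before the canvas) and extends until every
#' canvas pixel is covered by exactly one patch of the group; pixels of patches
#' that hang over the border are padding (background).  Patch origins are
#' 0-based row/col of the top-left pixel, windows are half-open
#' \code{[r, r+S) x [c, c+S)}.
#'
#' @param slide a \code{\link{slide_image}} (or anything with \code{$rgb}).
#' @param level a \code{\link{level_config}}.
#' @return list of 13 groups (at 20\% shift); each has \code{group_id} (0 =
#'   unshifted), \code{direction} ("none", "x", "y", "diag"), \code{step},
#'   \code{anchor}, and \code{refs}, a data.frame of patch origins
#'   (\code{row}, \code{col}).
#' @export
generate_patch_groups <- function(slide, level) {
  stopifnot(inherits(level, "level_config"))
  d <- dim(slide$rgb)
  H <- d[1]; W <- d[2]
  S <- level$S
  if (H < S || W < S) {
    abort_validation(sprintf("slide (%dx%d) smaller than patch size %d", H, W, S))
  }
  mk_group <- function(gid, dir, k, ar, ac) {
    rows <- seq.int(ar, H - 1L, by = S)
    cols <- seq.int(ac, W - 1L, by = S)
    list(group_id = gid, direction = dir, step = k,
         anchor = c(row = ar, col = ac), S = S,
         refs = data.frame(row = rep(rows, times = length(cols)),
                           col = rep(cols, each = length(rows))))
  }
  groups <- list(mk_group(0L, "none", 0L, 0L, 0L))
  gid <- 0L
  for (dir in c("x", "y", "diag")) {
    for (k in seq_len(level$n_steps - 1L)) {
      gid <- gid + 1L
      off <- k * level$step_px
      ar <- if (dir %in% c("y", "diag")) off - S else 0L
      ac <- if (dir %in% c("x", "diag")) off - S else 0L
      groups[[gid + 1L]] <- mk_group(gid, dir, as.integer(k), as.integer(ar), as.integer(ac))
    }
  }
  groups
}

# extract the window [r0, r0+S) x [c0, c0+S) (0-based) from a matrix,
# filling out-of-canvas pixels with `fill`
window_matrix <- function(m, r0, c0, S, fill = 0L) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, S, S)
  rr <- max(r0, 0L):min(r0 + S - 1L, H - 1L)
  cc <- max(c0, 0L):min(c0 + S - 1L, W - 1L)
  if (length(rr) > 0 && length(cc) > 0 && rr[1] <= rr[length(rr)] && cc[1] <= cc[length(cc)]) {
    out[rr - r0 + 1L, cc - c0 + 1L] <- m[rr + 1L, cc + 1L]
  }
  out
}

# extract an RGB window with white padding
window_rgb <- function(rgb, r0, c0, S, fill = 255) {
  out <- array(fill, dim = c(S, S, 3L))
  for (ch in 1:3) out[, , ch] <- window_matrix(rgb[, , ch], r0, c0, S, fill = fill)
  out
}

#' Background ratio of a patch window
#'
#' Fraction of the S x S window that is background: label 0 when a label-map
#' window is given, or FALSE pixels of a tissue-mask window.  Out-of-canvas
#' padding counts as background.
#'
#' @param window S x S integer label window (0 = background) or logical
#'   tissue-mask window (TRUE = tissue).
#' @return fraction in [0, 1].
#' @export
background_ratio <- function(window) {
  if (is.logical(window)) mean(!window) else mean(window == 0L)
}

# modal tissue label (1..5) of a label window; NA when no tissue or when the
# top two counts tie (ambiguous patch)
modal_label <- function(window, ties_na = TRUE) {
  counts <- tabulate(window[window > 0L], nbins = 5L)
  if (all(counts == 0L)) return(NA_integer_)
  mx <- max(counts)
  winners <- which(counts == mx)
  if (ties_na && length(winners) > 1L) return(NA_integer_)
  winners[1]
}

#' Select training patches (modal label == center label, BR <= 0.5)
#'
#' Implements the training-patch filter: over the unshifted grid of the level,
#' a patch is kept iff its modal ground-truth tissue label (MV) equals the
#' label at its center pixel (PC) and its background ratio (BR, fraction of
#' label-0 pixels) is at most 0.5 — i.e. the patch is more than half tissue.
#' Patches with a modal-count tie or a background center are ambiguous and
#' removed.  The center pixel of an S x S window is at offset
#' \code{floor(S/2)} in both axes (0-based).
#'
#' @param slide a labeled \code{\link{slide_image}}.
#' @param level a \code{\link{level_config}}.
#' @param cfg optional \code{\link{preprocess_config}} used when
#'   \code{ee_stage = "patch"} to enhance each selected patch.
#' @param keep_rasters if FALSE, only the selection records are returned
#'   (no pixel data) — used by tests and audits.
#' @return list with \code{records} (data.frame: row, col, MV, PC, BR,
#'   selected) and \code{patches} (list of \code{list(rgb, label)} for the
#'   selected patches, when \code{keep_rasters}).
#' @export
select_training_patches <- function(slide, level, cfg = NULL, keep_rasters = TRUE) {
  stopifnot(inherits(slide, "slide_image"))
  if (is.null(slide$label_map)) abort_validation("slide has no ground-truth label map")
  S <- level$S
  grp <- generate_patch_groups(slide, level)[[1]]  # unshifted grid only
  ctr <- S %/% 2L
  n <- nrow(grp$refs)
  MV <- integer(n); PC <- integer(n); BR <- numeric(n)
  for (i in seq_len(n)) {
    r0 <- grp$refs$row[i]; c0 <- grp$refs$col[i]
    w <- window_matrix(slide$label_map, r0, c0, S, fill = 0L)
    MV[i] <- modal_label(w)
    PC[i] <- w[ctr + 1L, ctr + 1L]
    BR[i] <- background_ratio(w)
  }
  selected <- !is.na(MV) & MV == PC & BR <= 0.5
  records <- data.frame(row = grp$refs$row, col = grp$refs$col,
                        MV = MV, PC = PC, BR = BR, selected = selected)
  patches <- NULL
  if (keep_rasters) {
    idx <- which(selected)
    patches <- vector("list", length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      p <- window_rgb(slide$rgb, records$row[i], records$col[i], S)
      if (!is.null(cfg) && cfg$ee_stage == "patch" && cfg$ee_amount > 0) {
        p <- enhance_edges(p, cfg)
      }
      patches[[j]] <- list(rgb = p, label = MV[i],
                           row = records$row[i], col = records$col[i])
    }
  }
  list(records = records, patches = patches)
}

# stack the patches of one group into an (S, S, 3, N) array (white padding),
# plus the matching label windows when the slide has ground truth
extract_group_batch <- function(slide, grp, with_labels = FALSE) {
  S <- grp$S
  n <- nrow(grp$refs)
  x <- array(255, dim = c(S, S, 3L, n))
  labs <- if (with_labels && !is.null(slide$label_map)) array(0L, dim = c(S, S, n)) else NULL
  for (i in seq_len(n)) {
    x[, , , i] <- window_rgb(slide$rgb, grp$refs$row[i], grp$refs$col[i], S)
    if (!is.null(labs)) {
      labs[, , i] <- window_matrix(slide$label_map, grp$refs$row[i], grp$refs$col[i], S, 0L)
    }
  }
  list(rgb = x, labels = labs, refs = grp$refs, S = S)
}
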