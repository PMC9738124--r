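#' Accumulate per-group label images into a vote stack
#'
#' Each patch group contributes one complete label image (every pixel carries
#' the label of the single patch covering it in that group).  With three
#' levels of 13 groups each, every canvas pixel collects exactly 39 votes.
#' The stack is stored as per-label count planes.
#'
#' @param label_images list of H x W integer matrices (labels 1..5), one per
#'   patch group.
#' @param n_expected optional expected group count (e.g. 39); mismatch errors.
#' @return object of class \code{vote_stack}: \code{counts} (H x W x 5 array)
#'   and \code{n_votes}.
#' @export
accumulate_votes <- function(label_images, n_expected = NULL) {
  if (!length(label_images)) abort_validation("no label images supplied")
  if (!is.null(n_expected) && length(label_images) != n_expected) {
    abort_validation(sprintf("expected %d label images, got %d",
                             n_expected, length(label_images)))
  }
  d <- dim(label_images[[1]])
  counts <- array(0L, dim = c(d[1], d[2], 5L))
  for (img in label_images) {
    if (!all(dim(img) == d)) abort_validation("label image dimensions differ")
    if (!all(img %in% 1:5)) abort_validation("votes must be GP labels 1..5")
    for (lab in 1:5) counts[, , lab] <- counts[, , lab] + (img == lab)
  }
  structure(list(counts = counts, n_votes = length(label_images)),
            class = "vote_stack")
}

#' Pixel-wise majority vote over a stack
#'
#' Each pixel receives the modal label of its votes; count ties break toward
#' the lower (less aggressive) GP label by default.
#'
#' @param stack a \code{\link{vote_stack}}.
#' @param tie \code{"lower"} (default) or \code{"higher"} GP label on ties.
#' @return H x W integer matrix of fused GP labels.
#' @export
majority_vote <- function(stack, tie = c("lower", "higher")) {
  tie <- match.arg(tie)
  stopifnot(inherits(stack, "vote_stack"))
  if (stack$n_votes < 1L) abort_validation("vote stack is empty")
  counts <- stack$counts
  labs <- if (tie == "lower") 1:5 else 5:1
  best <- matrix(labs[1], nrow = dim(counts)[1], ncol = dim(counts)[2])
  bestc <- counts[, , labs[1]]
  for (lab in labs[-1]) {
    better <- counts[, , lab] > bestc   # strict: earlier (preferred) label keeps ties
    best[better] <- lab
    bestc[better] <- counts[, , lab][better]
  }
  best
}

# GP -> (GS, GG) relation for ordered malignant pattern pairs
gg_from_patterns <- function(primary, secondary) {
  gs <- primary + secondary
  gg <- if (gs <= 6L) 1L
  else if (primary == 3L && secondary == 4L) 2L
  else if (primary == 4L && secondary == 3L) 3L
  else if (gs == 8L) 4L
  else 5L  # GS 9 or 10
  list(GS = gs, GG = gg)
}

#' Gleason score and grade group from a fused GP map
#'
#' Tissue-area histogram of the GP labels determines the primary (largest
#' malignant area among GP 3/4/5) and secondary (second largest; equal to the
#' primary when only one malignant pattern is present) patterns.  GS is their
#' sum; GG follows the standard ISUP relation: GS6 -> GG1; 3+4 -> GG2;
#' 4+3 -> GG3; GS8 (4+4, 3+5, 5+3) -> GG4; GS9/10 -> GG5.  A slide whose
#' malignant fraction of tissue is below \code{benign_threshold} — or whose
#' tissue is all GP1/GP2 — is Benign (no GS/GG).
#'
#' @param gp_map H x W integer matrix of GP labels (0 allowed, ignored as
#'   background).
#' @param tissue_mask logical matrix, TRUE = tissue; defaults to
#'   \code{gp_map != 0}.
#' @param benign_threshold minimum malignant fraction of tissue for a slide to
#'   be graded (default 0.005).
#' @return object of class \code{grade_result}: \code{gp_histogram} (pixel
#'   counts for labels 1..5 over tissue), \code{primary_pattern},
#'   \code{secondary_pattern}, \code{GS}, \code{GG} (integer 1..5 or NA),
#'   \code{GG_label} ("Benign" or "GG1".."GG5"), \code{malignant_fraction}.
#' @export
grade_from_gp_map <- function(gp_map, tissue_mask = NULL, benign_threshold = 0.005) {
  if (is.null(tissue_mask)) tissue_mask <- gp_map != 0L
  vals <- gp_map[tissue_mask]
  vals <- vals[vals %in% 1:5]
  if (!length(vals)) abort_validation("no tissue pixels to grade")
  hist <- tabulate(vals, nbins = 5L)
  names(hist) <- as.character(1:5)
  mal <- hist[3:5]
  mal_frac <- sum(mal) / sum(hist)
  if (mal_frac < benign_threshold || all(mal == 0)) {
    return(structure(list(gp_histogram = hist, primary_pattern = NA_integer_,
                          secondary_pattern = NA_integer_, GS = NA_integer_,
                          GG = NA_integer_, GG_label = "Benign",
                          malignant_fraction = mal_frac),
                     class = "grade_result"))
  }
  labs <- c(3L, 4L, 5L)
  ord <- order(mal, decreasing = TRUE)  # stable: area ties resolve to lower GP
  primary <- labs[ord[1]]
  secondary <- if (mal[ord[2]] > 0) labs[ord[2]] else primary
  gsgg <- gg_from_patterns(primary, secondary)
  structure(list(gp_histogram = hist, primary_pattern = primary,
                 secondary_pattern = secondary, GS = gsgg$GS, GG = gsgg$GG,
                 GG_label = paste0("GG", gsgg$GG),
                 malignant_fraction = mal_frac),
            class = "grade_result")
}

#' @export
print.grade_result <- function(x, ...) {
  if (x$GG_label == "Benign") {
    cat(sprintf("<grade_result> Benign (malignant fraction %.4f)\n", x$malignant_fraction))
  } else {
    cat(sprintf("<grade_result> GS %d (%d+%d), %s\n",
                x$GS, x$primary_pattern, x$secondary_pattern, x$GG_label))
  }
  cat("GP histogram:", paste(sprintf("%s=%d", names(x$gp_histogram), x$gp_histogram),
                             collapse = " "), "\n")
  invisible(x)
}
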