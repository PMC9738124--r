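#' Default per-class texture parameters for synthetic slides
#'
#' Each Gleason pattern (GP) class gets a base RGB color loosely following H&E
#' appearance (stroma pink through dark basophilic carcinoma), a band-limited
#' noise amplitude, a noise granularity (box-blur width in pixels), and an
#' optional periodic motif (stripes or dots) so classes differ in texture as
#' well as color.  Base colors keep at least one channel well below the
#' background threshold so intensity-based tissue masking works.
#'
#' @return named list (labels "1".."5") of texture descriptor lists with
#'   fields \code{base_rgb}, \code{noise_amp}, \code{granularity},
#'   \code{motif}, \code{motif_period}, \code{motif_amp}.
#' @export
default_textures <- function() {
  tex <- function(rgb, amp = 10, gran = 5L, motif = "none", period = 8, mamp = 0.10) {
    list(base_rgb = rgb, noise_amp = amp, granularity = as.integer(gran),
         motif = motif, motif_period = period, motif_amp = mamp)
  }
  list(
    `1` = tex(c(235, 170, 200), motif = "stripes", period = 12, mamp = 0.08), # stroma: pink, coarse fibres
    `2` = tex(c(225, 205, 170), motif = "none"),                              # benign: pale eosinophilic
    `3` = tex(c(175, 140, 205), motif = "dots", period = 10, mamp = 0.15),    # GP3: discrete glands
    `4` = tex(c(135, 100, 175), motif = "dots", period = 6, mamp = 0.15),     # GP4: fused glands
    `5` = tex(c(60, 75, 145), motif = "stripes", period = 5, mamp = 0.10)     # GP5: solid basophilic sheets
  )
}

#' Specification of a synthetic biopsy slide
#'
#' Describes the stated world the generator emulates: a connected tissue
#' silhouette on a near-white background, partitioned into contiguous
#' Voronoi-cell blobs whose areas follow the configured class prevalence.
#' The default prevalence reflects the imbalance of real biopsy data
#' (stroma dominates at ~40% of tissue, GP5 is rare at ~5%).
#'
#' @param width,height canvas size in pixels.
#' @param class_prevalence named numeric vector over labels "1".."5";
#'   non-negative, summing to 1.
#' @param tissue_fraction fraction of the canvas covered by tissue (0,0.75].
#' @param texture_params per-class texture descriptors, see
#'   \code{\link{default_textures}}.
#' @param n_cells number of Voronoi cells used to partition the tissue;
#'   defaults to roughly one cell per 800 tissue pixels (at least 60) so each
#'   class's area can be met to within a fraction of a percent while regions
#'   stay contiguous.
#' @param seed integer; fully determines the slide.
#' @param max_patch largest patch side the slide must support; the canvas must
#'   be at least 3x this size in each dimension.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(width = 600L, height = 600L,
                           class_prevalence = c(`1` = 0.40, `2` = 0.20, `3` = 0.20,
                                                `4` = 0.15, `5` = 0.05),
                           tissue_fraction = 0.6,
                           texture_params = default_textures(),
                           n_cells = NULL,
                           seed = 1L,
                           max_patch = 100L) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.null(names(class_prevalence)) ||
      !all(names(class_prevalence) %in% as.character(1:5))) {
    abort_validation("class_prevalence must be named with labels in 1..5")
  }
  prev <- numeric(5); names(prev) <- as.character(1:5)
  prev[names(class_prevalence)] <- class_prevalence
  if (any(prev < 0)) abort_validation("class prevalences must be >= 0")
  if (abs(sum(prev) - 1) > 1e-8) {
    abort_validation(sprintf("class prevalences must sum to 1 (got %.6f)", sum(prev)))
  }
  if (width < 3L * max_patch || height < 3L * max_patch) {
    abort_validation(sprintf("canvas must be at least 3x the largest patch (%d px)", max_patch))
  }
  if (tissue_fraction <= 0 || tissue_fraction > 0.75) {
    abort_validation("tissue_fraction must be in (0, 0.75]")
  }
  if (is.null(n_cells)) {
    n_cells <- max(60L, as.integer(round(width * height * tissue_fraction / 800)))
  }
  structure(list(width = width, height = height, class_prevalence = prev,
                 tissue_fraction = tissue_fraction, texture_params = texture_params,
                 n_cells = as.integer(n_cells), seed = as.integer(seed),
                 max_patch = as.integer(max_patch)),
            class = "synthetic_spec")
}

# wobbly-ellipse tissue silhouette covering ~tissue_fraction of the canvas
tissue_silhouette <- function(spec) {
  H <- spec$height; W <- spec$width
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  s <- sqrt(spec$tissue_fraction / pi)
  a <- W * s; b <- H * s
  x <- matrix(rep(seq_len(W), each = H), H, W)
  y <- matrix(rep(seq_len(H), W), H, W)
  u <- (x - cx) / a; v <- (y - cy) / b
  theta <- atan2(v, u)
  ph <- runif(2, 0, 2 * pi)
  wobble <- 1 + 0.07 * sin(3 * theta + ph[1]) + 0.05 * sin(5 * theta + ph[2])
  u * u + v * v <= wobble * wobble
}

#' Generate a ground-truth Gleason-pattern label map
#'
#' Lays a connected tissue silhouette on the canvas and partitions it into
#' many small Voronoi cells (for fine area control).  Each class except the
#' most prevalent then claims a compact, contiguous region: starting from a
#' seed cell placed as far as possible from regions already claimed, cells
#' are absorbed in order of distance to the seed until the class's target
#' area is met to within half a cell.  The most prevalent class (stroma in
#' the default prevalence) takes every remaining cell — mirroring how stroma
#' surrounds carcinoma foci in real biopsies, and keeping focal regions large
#' relative to the analysis patches.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return integer matrix height x width; 0 = background, 1..5 = GP label.
#' @export
make_label_map <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(derive_seed(spec$seed, "label_map"), {
    tissue <- tissue_silhouette(spec)
    H <- spec$height; W <- spec$width
    tpix <- which(tissue)
    n <- length(tpix)
    ncell <- min(spec$n_cells, n)
    centers <- sample(tpix, ncell)
    ci <- (centers - 1L) %% H + 1L
    cj <- (centers - 1L) %/% H + 1L
    pi_ <- (tpix - 1L) %% H + 1L
    pj <- (tpix - 1L) %/% H + 1L
    best <- rep.int(1L, n)
    bestd <- rep.int(Inf, n)
    for (k in seq_len(ncell)) {
      d <- (pi_ - ci[k])^2 + (pj - cj[k])^2
      imp <- d < bestd
      best[imp] <- k
      bestd[imp] <- d[imp]
    }
    sizes <- tabulate(best, nbins = ncell)
    target <- spec$class_prevalence * n
    cls_of_cell <- integer(ncell)             # 0 = unassigned
    present <- which(target > 0)
    remainder_cls <- present[which.max(target[present])]  # ties -> lower label
    disc_classes <- present[order(target[present], decreasing = TRUE)]
    disc_classes <- setdiff(disc_classes, remainder_cls)
    for (cls in disc_classes) {
      un <- which(cls_of_cell == 0L)
      if (!length(un)) break
      asg <- which(cls_of_cell > 0L)
      if (length(asg)) {
        # seed: unassigned cell farthest from all claimed regions (maximin)
        mind <- vapply(un, function(k) {
          min((ci[k] - ci[asg])^2 + (cj[k] - cj[asg])^2)
        }, 0)
        seedk <- un[which.max(mind)]
      } else {
        seedk <- un[sample.int(length(un), 1L)]
      }
      d2 <- (ci[un] - ci[seedk])^2 + (cj[un] - cj[seedk])^2
      ordk <- un[order(d2)]
      acc <- 0
      for (k in ordk) {
        if (acc >= target[cls]) break
        if (abs(acc + sizes[k] - target[cls]) > abs(acc - target[cls])) break
        cls_of_cell[k] <- cls
        acc <- acc + sizes[k]
      }
    }
    cls_of_cell[cls_of_cell == 0L] <- remainder_cls
    lab <- matrix(0L, H, W)
    lab[tpix] <- cls_of_cell[best]
    lab
  })
}

# band-limited unit-variance noise field
noise_field <- function(H, W, granularity) {
  z <- matrix(rnorm(H * W), H, W)
  if (granularity > 1L) {
    w <- granularity + (granularity + 1L) %% 2L  # force odd
    z <- box_blur(z, w)
  }
  s <- sd(as.vector(z))
  if (s > 0) z <- z / s
  z
}

#' Render a synthetic slide from a label map
#'
#' Paints each class with its base color modulated by an optional periodic
#' motif, then adds per-class band-limited noise.  Background is flat
#' near-white (250 on all channels).  With all noise amplitudes and motif
#' amplitudes zero, class regions are exactly their base colors.
#'
#' @param label_map integer matrix from \code{\link{make_label_map}} (values
#'   0..5).
#' @param spec the \code{\link{synthetic_spec}} (texture parameters + seed).
#' @return object of class \code{slide_image}: list with \code{rgb}
#'   (H x W x 3 array, 0..255) and \code{label_map}.
#' @export
render_slide <- function(label_map, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  bad <- setdiff(unique(as.vector(label_map)), 0:5)
  if (length(bad)) abort_validation(paste("unknown label value(s):", paste(bad, collapse = ", ")))
  H <- nrow(label_map); W <- ncol(label_map)
  rgb <- array(250, dim = c(H, W, 3L))
  x <- matrix(rep(seq_len(W), each = H), H, W)
  y <- matrix(rep(seq_len(H), W), H, W)
  with_seed(derive_seed(spec$seed, "render"), {
    for (lab in as.character(1:5)) {
      mask <- label_map == as.integer(lab)
      if (!any(mask)) next
      tp <- spec$texture_params[[lab]]
      if (is.null(tp)) abort_validation(paste("no texture parameters for label", lab))
      mod <- matrix(1, H, W)
      if (tp$motif == "stripes") {
        ang <- (as.integer(lab) * 37) %% 180 * pi / 180
        phase <- 2 * pi * (x * cos(ang) + y * sin(ang)) / tp$motif_period
        mod <- 1 + tp$motif_amp * sin(phase)
      } else if (tp$motif == "dots") {
        mod <- 1 + tp$motif_amp *
          sin(2 * pi * x / tp$motif_period) * sin(2 * pi * y / tp$motif_period)
      }
      nz <- if (tp$noise_amp > 0) noise_field(H, W, tp$granularity) else matrix(0, H, W)
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[mask] <- clip255(tp$base_rgb[ch] * mod[mask] + tp$noise_amp * nz[mask])
        rgb[, , ch] <- plane
      }
    }
  })
  slide_image(rgb, label_map)
}

#' Construct a slide-image object
#'
#' @param rgb H x W x 3 numeric array with values in 0..255.
#' @param label_map optional H x W integer matrix with values in 0..5
#'   (0 = background).
#' @return object of class \code{slide_image}.
#' @export
slide_image <- function(rgb, label_map = NULL) {
  if (!is_rgb_array(rgb)) abort_validation("rgb must be an H x W x 3 array")
  if (!is.null(label_map)) {
    if (!all(dim(label_map) == dim(rgb)[1:2])) {
      abort_validation("rgb and label_map dimensions differ")
    }
    if (!all(label_map %in% 0:5)) abort_validation("label values must be in 0..5")
    storage.mode(label_map) <- "integer"
  }
  structure(list(rgb = rgb, label_map = label_map), class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<slide_image> %d x %d px, %s ground truth\n", d[1], d[2],
              if (is.null(x$label_map)) "without" else "with"))
  invisible(x)
}

#' Generate a complete synthetic slide (label map + rendering)
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a \code{\link{slide_image}} with ground truth attached.
#' @export
synth_slide <- function(spec) {
  render_slide(make_label_map(spec), spec)
}
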