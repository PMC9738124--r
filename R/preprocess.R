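#' Preprocessing configuration
#'
#' @param heq_mode \code{"luminance"} (default) equalizes the luminance channel
#'   and rescales RGB proportionally, preserving hue of the H&E stains;
#'   \code{"per_channel"} equalizes R, G and B independently.
#' @param ee_amount unsharp-mask gain (>= 0); 0 disables edge enhancement.
#' @param ee_radius Gaussian blur radius (sigma, pixels) of the unsharp mask.
#' @param tissue_threshold intensity at or above which (on all three channels)
#'   a pixel counts as background; 0..256, where 256 means no pixel is ever
#'   background.
#' @param ee_stage where edge enhancement is applied: \code{"slide"} (once, to
#'   the whole equalized slide before patches are cut — the default, cheap and
#'   identical to per-patch enhancement away from patch borders),
#'   \code{"patch"} (to each patch individually), or \code{"none"}.
#' @return object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(heq_mode = c("luminance", "per_channel"),
                              ee_amount = 1.0, ee_radius = 1.5,
                              tissue_threshold = 240,
                              ee_stage = c("slide", "patch", "none")) {
  heq_mode <- match.arg(heq_mode)
  ee_stage <- match.arg(ee_stage)
  if (ee_radius <= 0) abort_validation("ee_radius must be > 0")
  if (ee_amount < 0) abort_validation("ee_amount must be >= 0")
  if (tissue_threshold < 0 || tissue_threshold > 256) {
    abort_validation("tissue_threshold must be in [0, 256]")
  }
  structure(list(heq_mode = heq_mode, ee_amount = ee_amount, ee_radius = ee_radius,
                 tissue_threshold = tissue_threshold, ee_stage = ee_stage),
            class = "preprocess_config")
}

# classic 8-bit equalization map: v -> round(255*(cdf(v)-cdf_min)/(1-cdf_min));
# monotone non-decreasing, and the exactly-uniform histogram is a fixed point
equalize_map <- function(values) {
  v <- pmin(pmax(as.integer(round(values)), 0L), 255L)
  h <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(h) / sum(h)
  cdf_min <- cdf[which(h > 0)[1]]
  if (cdf_min >= 1) return(seq(0L, 255L))  # constant image: identity map
  as.integer(round(255 * (cdf - cdf_min) / (1 - cdf_min)))
}

luminance <- function(rgb) 0.299 * rgb[, , 1] + 0.587 * rgb[, , 2] + 0.114 * rgb[, , 3]

#' Histogram equalization of a slide
#'
#' Spreads intensity values over the full 0..255 range.  In luminance mode the
#' equalizing map T acts on luminance Y and each RGB channel is scaled by
#' (T(Y)+1)/(Y+1), which keeps chrominance ratios; in per-channel mode each
#' channel is equalized independently.  Either way the map applied to the
#' equalized channel(s) is monotone non-decreasing, dimensions are unchanged
#' and any ground-truth label map passes through untouched.
#'
#' @param slide a \code{\link{slide_image}}.
#' @param cfg a \code{\link{preprocess_config}}.
#' @return equalized \code{\link{slide_image}}.
#' @export
histogram_equalize <- function(slide, cfg = preprocess_config()) {
  stopifnot(inherits(slide, "slide_image"))
  rgb <- slide$rgb
  if (length(rgb) == 0) abort_validation("empty image")
  if (cfg$heq_mode == "per_channel") {
    for (ch in 1:3) {
      m <- equalize_map(rgb[, , ch])
      rgb[, , ch] <- m[pmin(pmax(as.integer(round(rgb[, , ch])), 0L), 255L) + 1L]
    }
  } else {
    y <- luminance(rgb)
    yq <- pmin(pmax(as.integer(round(y)), 0L), 255L)
    m <- equalize_map(yq)
    ratio <- (m[yq + 1L] + 1) / (yq + 1)
    for (ch in 1:3) rgb[, , ch] <- clip255(rgb[, , ch] * ratio)
  }
  slide_image(rgb, slide$label_map)
}

#' Unsharp-mask edge enhancement
#'
#' \code{out = clip(x + amount * (x - gaussian_blur(x, radius)))}, applied per
#' channel.  With \code{ee_amount = 0} the input is returned bit-identically.
#'
#' @param patch H x W x 3 array (0..255) — a patch or a whole slide raster.
#' @param cfg a \code{\link{preprocess_config}}.
#' @return enhanced array, clipped to [0, 255].
#' @export
enhance_edges <- function(patch, cfg = preprocess_config()) {
  if (!is_rgb_array(patch)) abort_validation("patch must be an H x W x 3 array")
  if (cfg$ee_radius <= 0) abort_validation("ee_radius must be > 0")
  if (cfg$ee_amount == 0) return(patch)
  out <- patch
  for (ch in 1:3) {
    blur <- gaussian_blur(patch[, , ch], cfg$ee_radius)
    out[, , ch] <- clip255(patch[, , ch] + cfg$ee_amount * (patch[, , ch] - blur))
  }
  out
}

#' Intensity-based tissue mask
#'
#' A pixel is background iff all three channels are at or above
#' \code{tissue_threshold}; when the slide carries a ground-truth label map,
#' background is label 0 instead.  Returns TRUE for tissue.
#'
#' @param slide a \code{\link{slide_image}}.
#' @param cfg a \code{\link{preprocess_config}}.
#' @param use_labels use the ground-truth label map when present (default TRUE).
#' @return logical matrix, TRUE = tissue.
#' @export
tissue_mask <- function(slide, cfg = preprocess_config(), use_labels = TRUE) {
  stopifnot(inherits(slide, "slide_image"))
  if (use_labels && !is.null(slide$label_map)) return(slide$label_map != 0L)
  bg <- slide$rgb[, , 1] >= cfg$tissue_threshold &
    slide$rgb[, , 2] >= cfg$tissue_threshold &
    slide$rgb[, , 3] >= cfg$tissue_threshold
  !bg
}

# slide-level preprocessing as used by the pipeline: HEQ, then (optionally)
# slide-wide edge enhancement
preprocess_slide <- function(slide, cfg = preprocess_config()) {
  out <- histogram_equalize(slide, cfg)
  if (cfg$ee_stage == "slide" && cfg$ee_amount > 0) {
    out <- slide_image(enhance_edges(out$rgb, cfg), out$label_map)
  }
  out
}
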