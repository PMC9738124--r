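# PNG raster I/O.  Slides are 8-bit RGB PNGs; label maps are 8-bit grayscale
# PNGs whose pixel value IS the label (0 = background, 1..5 = GP), i.e. they
# look black to the eye but round-trip exactly.

#' Write a slide image (and its label map) to PNG
#'
#' @param slide a \code{\link{slide_image}}.
#' @param path output path for the RGB PNG.
#' @param label_path optional path for the label-map PNG (written only when the
#'   slide has ground truth).
#' @param spec optional \code{\link{synthetic_spec}}; when given, a sidecar
#'   JSON (\code{<path>.json}) records it, seed included.
#' @return \code{path}, invisibly.
#' @export
write_slide_png <- function(slide, path, label_path = NULL, spec = NULL) {
  stopifnot(inherits(slide, "slide_image"))
  png::writePNG(slide$rgb / 255, target = path)
  if (!is.null(slide$label_map) && !is.null(label_path)) {
    png::writePNG(slide$label_map / 255, target = label_path)
  }
  if (!is.null(spec)) {
    sc <- unclass(spec)
    jsonlite::write_json(sc, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a slide image from PNG
#'
#' @param path RGB (or grayscale) PNG of the slide.
#' @param label_path optional grayscale PNG whose pixel values are labels 0..5.
#' @return a \code{\link{slide_image}}.
#' @export
read_slide_png <- function(path, label_path = NULL) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  rgb <- round(img * 255)
  lab <- NULL
  if (!is.null(label_path)) {
    lm <- png::readPNG(label_path)
    if (length(dim(lm)) == 3L) lm <- lm[, , 1]
    lab <- matrix(as.integer(round(lm * 255)), nrow(lm), ncol(lm))
  }
  slide_image(rgb, lab)
}

#' Write a Gleason-pattern map as a grayscale PNG (pixel value = label)
#' @param gp_map integer matrix with values 0..5.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gp_map_png <- function(gp_map, path) {
  stopifnot(all(gp_map %in% 0:5))
  png::writePNG(gp_map / 255, target = path)
  invisible(path)
}
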