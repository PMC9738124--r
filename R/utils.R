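# internal helpers shared across modules

# validation errors carry a dedicated class so the CLI can map them to exit 2
abort_validation <- function(msg, call. = FALSE) {
  cond <- structure(
    class = c("gleason_validation_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed and a tag
#'
#' All stochastic operations in the package take explicit seeds; pipeline code
#' derives per-stage seeds from one master seed so a single integer reproduces
#' a whole run.  The derivation is a small deterministic string hash kept below
#' .Machine$integer.max.
#'
#' @param seed master seed (single integer).
#' @param ... tag components (coerced to character) identifying the consumer.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  tag <- paste(vapply(list(...), as.character, ""), collapse = "/")
  h <- as.double(seed) %% 2147483629
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h)
}

# run expr with a temporary RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

is_rgb_array <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

# separable box blur via integral images; width must be odd
box_blur <- function(m, width) {
  if (width <= 1L) return(m)
  r <- (width - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  # pad by replication, cumulative sums along each axis
  mp <- m[c(rep(1L, r), seq_len(H), rep(H, r)), c(rep(1L, r), seq_len(W), rep(W, r)), drop = FALSE]
  cs <- apply(mp, 2L, cumsum)
  row_sums <- cs[seq_len(H) + 2L * r, , drop = FALSE] -
    rbind(0, cs)[seq_len(H), , drop = FALSE]
  cs2 <- t(apply(row_sums, 1L, cumsum))
  out <- cs2[, seq_len(W) + 2L * r, drop = FALSE] -
    cbind(0, cs2)[, seq_len(W), drop = FALSE]
  out / (width * width)
}

# 1-D Gaussian kernel for unsharp masking; sigma in pixels
gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur of a matrix with edge replication
gaussian_blur <- function(m, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  H <- nrow(m); W <- ncol(m)
  mp <- m[c(rep(1L, r), seq_len(H), rep(H, r)), , drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * mp[(i - 1L) + seq_len(H), , drop = FALSE]
  mp <- out[, c(rep(1L, r), seq_len(W), rep(W, r)), drop = FALSE]
  out <- matrix(0, H, W)
  for (i in seq_along(k)) out <- out + k[i] * mp[, (i - 1L) + seq_len(W), drop = FALSE]
  out
}

# binary dilation of a logical matrix by a Chebyshev ball of given radius
dilate_chebyshev <- function(mask, radius) {
  if (radius <= 0L) return(mask)
  m <- mask
  H <- nrow(m); W <- ncol(m)
  # separable: running OR along rows then columns
  out <- m
  for (d in seq_len(radius)) {
    out[seq_len(H - d), ] <- out[seq_len(H - d), ] | m[d + seq_len(H - d), ]
    out[d + seq_len(H - d), ] <- out[d + seq_len(H - d), ] | m[seq_len(H - d), ]
  }
  m <- out
  for (d in seq_len(radius)) {
    out[, seq_len(W - d)] <- out[, seq_len(W - d)] | m[, d + seq_len(W - d)]
    out[, d + seq_len(W - d)] <- out[, d + seq_len(W - d)] | m[, seq_len(W - d)]
  }
  out
}
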