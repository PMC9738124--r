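# shared fixtures: small slides and levels, memoized per test session

.fixture_cache <- new.env(parent = emptyenv())

tiny_levels <- function() lapply(c(20L, 15L, 10L), level_config)

tiny_spec <- function(seed = 1L, ...) {
  synthetic_spec(width = 120L, height = 120L, seed = seed, max_patch = 20L, ...)
}

tiny_slide <- function(seed = 1L) {
  key <- paste0("slide", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- synth_slide(tiny_spec(seed))
  }
  .fixture_cache[[key]]
}

# brute-force modal label of a label window: histogram over tissue labels,
# NA on ties — independent of modal_label()'s implementation details
brute_modal <- function(w) {
  counts <- sapply(1:5, function(l) sum(w == l))
  if (all(counts == 0)) return(NA_integer_)
  mx <- max(counts)
  if (sum(counts == mx) > 1) return(NA_integer_)
  which.max(counts)
}

# random RGB array helper
rand_rgb <- function(h, w, seed = 1) {
  withr::with_seed(seed, array(runif(h * w * 3, 0, 255), dim = c(h, w, 3)))
}
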