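test_that("vote accumulation checks counts and sizes", {
  imgs13 <- replicate(13, matrix(3L, 6, 6), simplify = FALSE)
  st <- accumulate_votes(imgs13)
  expect_equal(st$n_votes, 13L)                 # one level: 13 votes per pixel
  expect_true(all(apply(st$counts, c(1, 2), sum) == 13L))
  imgs39 <- replicate(39, matrix(2L, 6, 6), simplify = FALSE)
  st39 <- accumulate_votes(imgs39, n_expected = 39L)
  expect_equal(st39$n_votes, 39L)               # three levels: 39 votes per pixel
  expect_error(accumulate_votes(imgs13, n_expected = 39L),
               class = "gleason_validation_error")
  expect_error(accumulate_votes(list(matrix(1L, 2, 2), matrix(1L, 3, 3))),
               class = "gleason_validation_error")
  expect_error(accumulate_votes(list(matrix(7L, 2, 2))),
               class = "gleason_validation_error")
})

test_that("majority vote: unanimity, strict majority, tie direction, idempotence", {
  # 20 votes label 3 vs 19 label 4 -> 3
  imgs <- c(replicate(20, matrix(3L, 2, 2), simplify = FALSE),
            replicate(19, matrix(4L, 2, 2), simplify = FALSE))
  expect_true(all(majority_vote(accumulate_votes(imgs)) == 3L))
  # unanimous 39 x label 5 -> 5
  expect_true(all(majority_vote(accumulate_votes(
    replicate(39, matrix(5L, 2, 2), simplify = FALSE))) == 5L))
  # fusing identical maps returns that map
  m <- matrix(sample(1:5, 36, replace = TRUE), 6, 6)
  expect_identical(majority_vote(accumulate_votes(replicate(13, m, simplify = FALSE))),
                   m)
  # ties break toward the lower label by default, higher when configured
  tied <- c(replicate(3, matrix(2L, 2, 2), simplify = FALSE),
            replicate(3, matrix(4L, 2, 2), simplify = FALSE))
  expect_true(all(majority_vote(accumulate_votes(tied)) == 2L))
  expect_true(all(majority_vote(accumulate_votes(tied), tie = "higher") == 4L))
})

test_that("fused maps equal a brute-force per-pixel histogram oracle", {
  set.seed(99)
  for (rep in 1:5) {
    n_imgs <- sample(c(5L, 13L, 39L), 1)
    imgs <- replicate(n_imgs, matrix(sample(1:5, 64, replace = TRUE), 8, 8),
                      simplify = FALSE)
    fused <- majority_vote(accumulate_votes(imgs))
    votes <- simplify2array(imgs)  # 8 x 8 x n
    oracle <- apply(votes, c(1, 2), function(v) {
      h <- tabulate(v, nbins = 5)
      which.max(h)  # which.max takes the first (lowest) maximum
    })
    expect_identical(fused, matrix(as.integer(oracle), 8, 8))
  }
})

test_that("grading follows the GP/GS/GG relation exhaustively", {
  # all ordered malignant pairs: construct maps with 50%/30% areas
  expected <- list(
    `33` = c(6, 1), `34` = c(7, 2), `35` = c(8, 4),
    `43` = c(7, 3), `44` = c(8, 4), `45` = c(9, 5),
    `53` = c(8, 4), `54` = c(9, 5), `55` = c(10, 5)
  )
  for (p in 3:5) for (s in 3:5) {
    gp <- matrix(1L, 10, 10)
    gp[1:5, ] <- p                      # 50% primary
    if (s != p) gp[6:8, ] <- s          # 30% secondary
    g <- grade_from_gp_map(gp)
    key <- paste0(p, s)
    expect_equal(g$primary_pattern, p)
    expect_equal(g$secondary_pattern, s)
    expect_equal(g$GS, expected[[key]][1])
    expect_equal(g$GG, expected[[key]][2])
    expect_equal(g$GG_label, paste0("GG", expected[[key]][2]))
  }
})

test_that("grading handles benign slides, thresholds and errors", {
  # only labels 1/2 -> Benign with no GS/GG
  benign <- matrix(rep(c(1L, 2L), 50), 10, 10)
  g <- grade_from_gp_map(benign)
  expect_equal(g$GG_label, "Benign")
  expect_true(is.na(g$GS))
  # malignant fraction below threshold -> Benign; above -> graded
  m <- matrix(1L, 20, 20); m[1, 1] <- 3L   # 0.25% malignant
  expect_equal(grade_from_gp_map(m)$GG_label, "Benign")
  expect_equal(grade_from_gp_map(m, benign_threshold = 0.001)$GG_label, "GG1")
  # single malignant pattern doubles as secondary (e.g. 3+3)
  single <- matrix(1L, 10, 10); single[1:4, ] <- 3L
  g3 <- grade_from_gp_map(single)
  expect_equal(c(g3$primary_pattern, g3$secondary_pattern, g3$GS, g3$GG),
               c(3, 3, 6, 1))
  expect_error(grade_from_gp_map(matrix(0L, 5, 5)), class = "gleason_validation_error")
})

test_that("area-based pattern ordering drives GS/GG as specified", {
  mk_map <- function(fracs) {
    # fracs: named fractions over labels; fill a 100x100 map row-wise
    gp <- integer(10000)
    at <- 1L
    for (lab in names(fracs)) {
      n <- round(fracs[[lab]] * 10000)
      gp[at:(at + n - 1L)] <- as.integer(lab)
      at <- at + n
    }
    gp[gp == 0L] <- 1L
    matrix(gp, 100, 100)
  }
  g <- grade_from_gp_map(mk_map(list(`3` = 0.6, `4` = 0.3)))
  expect_equal(c(g$GS, g$GG), c(7, 2))     # 3+4 favorable
  g <- grade_from_gp_map(mk_map(list(`4` = 0.5, `3` = 0.4)))
  expect_equal(c(g$GS, g$GG), c(7, 3))     # 4+3 unfavorable
  g <- grade_from_gp_map(mk_map(list(`3` = 0.3, `5` = 0.2, `1` = 0.5)))
  expect_equal(c(g$GS, g$GG), c(8, 4))     # 3+5
})
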