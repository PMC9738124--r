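test_that("level_config enforces integral shift arithmetic", {
  expect_error(level_config(100, shift_fraction = 0.3), class = "gleason_validation_error")
  expect_error(level_config(33, shift_fraction = 0.2), class = "gleason_validation_error")
  lv <- level_config(100)
  expect_equal(lv$step_px, 20)   # 20% shift of a 100 px patch
  expect_equal(lv$n_steps, 5)    # five shift steps recover the original grid
})

test_that("patch-group structure: 13 groups, 4 per direction, exact coverage", {
  sl <- slide_image(array(200, c(400, 400, 3)))
  for (S in c(100L, 75L, 50L)) {
    groups <- generate_patch_groups(sl, level_config(S))
    expect_length(groups, 13L)
    expect_equal(sum(vapply(groups, function(g) g$direction == "x", NA)), 4L)
    expect_equal(sum(vapply(groups, function(g) g$direction == "y", NA)), 4L)
    expect_equal(sum(vapply(groups, function(g) g$direction == "diag", NA)), 4L)
    # every canvas pixel covered by exactly one patch per group
    for (g in groups[c(1, 2, 7, 13)]) {
      cover <- matrix(0L, 400, 400)
      for (i in seq_len(nrow(g$refs))) {
        r0 <- g$refs$row[i]; c0 <- g$refs$col[i]
        rr <- max(r0, 0L):min(r0 + S - 1L, 399L)
        cc <- max(c0, 0L):min(c0 + S - 1L, 399L)
        cover[rr + 1L, cc + 1L] <- cover[rr + 1L, cc + 1L] + 1L
      }
      expect_true(all(cover == 1L))
    }
  }
  expect_error(generate_patch_groups(slide_image(array(0, c(40, 40, 3))), level_config(50)),
               class = "gleason_validation_error")
})

test_that("background_ratio counts background inclusively at the 0.5 boundary", {
  expect_equal(background_ratio(matrix(0L, 10, 10)), 1.0)
  expect_equal(background_ratio(matrix(3L, 10, 10)), 0.0)
  half <- matrix(0L, 10, 10); half[, 6:10] <- 2L   # tissue half holds the center
  expect_equal(background_ratio(half), 0.5)
  # BR == 0.5 passes the selection filter (predicate is BR <= 0.5)
  sl <- slide_image(array(100, c(10, 10, 3)), half)
  sel <- select_training_patches(sl, level_config(10, shift_fraction = 0.5))
  expect_true(sel$records$selected[1])
})

test_that("modal labels equal a brute-force histogram on random windows", {
  lm <- tiny_slide(5)$label_map
  set.seed(404)
  for (i in 1:60) {
    r0 <- sample(0:100, 1); c0 <- sample(0:100, 1); S <- sample(c(7, 10, 15), 1)
    w <- gleasonCascade:::window_matrix(lm, r0, c0, S, 0L)
    expect_identical(gleasonCascade:::modal_label(w), brute_modal(w))
  }
})

test_that("Algorithm-1 selection matches the predicate, brute-forced", {
  sl <- tiny_slide(5)
  lv <- level_config(20)
  sel <- select_training_patches(sl, lv)
  expect_gt(sum(sel$records$selected), 0)
  ctr <- 20L %/% 2L
  for (i in seq_len(nrow(sel$records))) {
    rec <- sel$records[i, ]
    w <- gleasonCascade:::window_matrix(sl$label_map, rec$row, rec$col, 20L, 0L)
    mv <- brute_modal(w)
    pc <- w[ctr + 1L, ctr + 1L]
    br <- mean(w == 0L)
    expect_identical(rec$selected, !is.na(mv) && mv == pc && br <= 0.5)
    if (rec$selected) expect_identical(rec$MV, mv)
  }
  # returned patches carry the modal label
  labs <- vapply(sel$patches, `[[`, 0L, "label")
  expect_identical(labs, sel$records$MV[sel$records$selected])
})

test_that("selection removes majority-background and center-mismatch patches", {
  # patch 60% background -> removed
  lm <- matrix(0L, 10, 10); lm[, 1:4] <- 3L
  sl <- slide_image(array(100, c(10, 10, 3)), lm)
  sel <- select_training_patches(sl, level_config(10, shift_fraction = 0.5))
  expect_false(sel$records$selected[1])
  expect_equal(sel$records$BR[1], 0.6)
  # modal label 4 but center pixel 3 -> removed
  lm2 <- matrix(4L, 11, 11); lm2[6, 6] <- 3L
  sl2 <- slide_image(array(100, c(11, 11, 3)), lm2)
  sel2 <- select_training_patches(sl2, level_config(11, shift_fraction = 1 / 11))
  expect_false(sel2$records$selected[1])
  expect_equal(sel2$records$MV[1], 4L)
  expect_equal(sel2$records$PC[1], 3L)
  # homogeneous patch selected with its label
  lm3 <- matrix(3L, 10, 10)
  sel3 <- select_training_patches(slide_image(array(90, c(10, 10, 3)), lm3),
                                  level_config(10, shift_fraction = 0.5))
  expect_true(sel3$records$selected[1])
  expect_equal(sel3$records$MV[1], 3L)
  expect_error(select_training_patches(slide_image(array(1, c(10, 10, 3))),
                                       level_config(10, shift_fraction = 0.5)),
               class = "gleason_validation_error")
})
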