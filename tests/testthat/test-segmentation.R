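test_that("relief map is the morphological gradient", {
  expect_identical(relief_map(matrix(1, 8, 8)), matrix(0, 8, 8))
  step <- matrix(0, 8, 8); step[, 5:8] <- 1
  rel <- relief_map(step)
  expect_true(all(rel[, c(4, 5)] == 1))     # the two columns astride the edge
  expect_true(all(rel[, c(1:3, 6:8)] == 0))
  expect_true(all(relief_map(rand_img(16, 16, 1)) >= 0))
})

test_that("background markers avoid nuclei and cover the background", {
  ren <- render_scene(generate_scene(n_nuclei = 20, seed = 3))
  seg <- segment_nuclei(ren$image, keep_stages = TRUE)
  bg <- background_markers(seg$stages$prepared, nucleus_radius = 8)
  truth_bg <- ren$labels == 0L
  expect_equal(sum(bg & !truth_bg), 0)                 # never on a nucleus
  expect_gte(sum(bg & truth_bg) / sum(truth_bg), 0.5)  # covers most background
  # invariant to adding a constant
  expect_identical(background_markers(seg$stages$prepared + 0.25, 8), bg)
  expect_warning(empty <- background_markers(matrix(1, 16, 16), 2), "constant")
  expect_false(any(empty))
})

test_that("marker watershed floods basins to the ridge deterministically", {
  relief <- matrix(0, 16, 16)
  relief[, 8] <- 1                       # single ridge column
  fg <- matrix(0L, 16, 16)
  fg[8, 4] <- 1L; fg[8, 12] <- 2L
  bg <- matrix(FALSE, 16, 16)
  lab <- marker_watershed(relief, fg, bg)
  # left basin (and the ridge it reaches first) -> 1, right basin -> 2
  expect_true(all(lab[, 1:8] == 1L))
  expect_true(all(lab[, 9:16] == 2L))
  expect_equal(sum(table(lab)), 256)
  # no foreground markers -> everything background
  expect_identical(marker_watershed(relief, matrix(0L, 16, 16), bg),
                   matrix(0L, 16, 16))
  # overlap between fg and bg is rejected
  bad <- bg; bad[8, 4] <- TRUE
  expect_error(marker_watershed(relief, fg, bad), "overlap")
})

test_that("watershed output partitions the image into connected marked regions", {
  ren <- render_scene(generate_scene(n_nuclei = 15, size = 192, seed = 5))
  seg <- segment_nuclei(ren$image)
  lab <- seg$labels
  n <- nrow(seg$centers)
  expect_equal(sort(unique(as.vector(lab[lab > 0]))), seq_len(n))
  expect_equal(length(lab), prod(dim(lab)))
  for (k in seq_len(n)) {
    mask <- lab == k
    expect_true(mask[seg$centers$row[k], seg$centers$col[k]])  # contains marker
    comp <- oracle_flood(centers_to_markers(seg$centers[k, ], dim(lab), 0) > 0,
                         mask)
    expect_identical(comp, mask)                               # 4-connected
  }
})

test_that("the pipeline is deterministic and handles blank images", {
  ren <- render_scene(generate_scene(n_nuclei = 10, size = 160, seed = 2))
  s1 <- segment_nuclei(ren$image)
  s2 <- segment_nuclei(ren$image)
  expect_identical(s1$labels, s2$labels)
  expect_identical(s1$centers, s2$centers)
  # pure background (with and without noise): no nuclei
  for (ns in c(3, 0)) {
    blank <- render_scene(generate_scene(n_nuclei = 0, size = 96,
                                         noise_sigma = ns, seed = 1))
    s0 <- suppressWarnings(segment_nuclei(blank$image))
    expect_equal(nrow(s0$centers), 0L)
    expect_true(all(s0$labels == 0L))
  }
})

test_that("stage errors carry the stage name", {
  expect_error(segment_nuclei(array(-1, c(8, 8, 3))), "stain_separation")
})

test_that("segmentation recovers detection and overlap on synthetic scenes", {
  res <- vapply(1:3, function(seed) {
    ren <- render_scene(generate_scene(n_nuclei = 30, seed = seed))
    seg <- segment_nuclei(ren$image)
    ev <- evaluate_segmentation(seg$labels, seg$centers, ren$labels,
                                ren$centers, max_dist = 8)
    c(ev$f1, ev$mean_dice, abs(ev$n_pred - 30) / 30)
  }, numeric(3))
  expect_true(all(res[1, ] >= 0.9))
  expect_true(all(res[2, ] >= 0.80))
  expect_lte(mean(res[3, ]), 0.1)
})
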