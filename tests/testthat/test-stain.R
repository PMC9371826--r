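test_that("optical density follows the log-ratio law", {
  img <- array(255, c(2, 2, 3))
  expect_equal(rgb_to_od(img), array(0, c(2, 2, 3)))
  expect_equal(rgb_to_od(array(25.5, c(1, 1, 3)))[1, 1, ], rep(1, 3))
  expect_equal(rgb_to_od(array(2.55, c(1, 1, 3)))[1, 1, ], rep(2, 3))
  # zero intensity is clamped to 1, keeping OD finite
  od0 <- rgb_to_od(array(0, c(1, 1, 3)))
  expect_true(all(is.finite(od0)))
  expect_equal(od0[1, 1, 1], log10(255))
  expect_error(rgb_to_od(img, i0 = 0), "positive")
  expect_error(rgb_to_od(img - 300), "negative")
})

test_that("optical density decreases monotonically with intensity", {
  i <- seq(1, 255, length.out = 50)
  img <- array(rep(i, 3), c(50, 1, 3))
  od <- rgb_to_od(img)[, 1, 1]
  expect_true(all(diff(od) < 0))
})

test_that("stain vectors normalize to unit rows", {
  m <- normalize_stain_vectors(rbind(c(3, 4, 0), c(0, 1, 0), c(0, 0, 2)))
  expect_equal(m[1, ], c(0.6, 0.8, 0), ignore_attr = TRUE)
  expect_equal(m[2, ], c(0, 1, 0), ignore_attr = TRUE)   # already unit
  expect_equal(unname(sqrt(rowSums(normalize_stain_vectors(
    he_dab_stain_matrix())^2))), rep(1, 3), tolerance = 1e-9)
  expect_error(normalize_stain_vectors(rbind(c(0, 0, 0), c(0, 1, 0), c(1, 0, 0))),
               "degenerate")
  expect_warning(normalize_stain_vectors(rbind(c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))),
                 "collinear")
})

test_that("deconvolution inverts the stain matrix", {
  expect_equal(deconvolution_matrix(diag(3)), diag(3), ignore_attr = TRUE)
  m <- normalize_stain_vectors(he_dab_stain_matrix())
  d <- deconvolution_matrix(m)
  expect_equal(unname(d %*% m), diag(3), tolerance = 1e-9)
  # printed reference diagonal for the standard H&E-DAB matrix
  expect_equal(unname(round(diag(d), 2)), c(1.88, 1.13, 1.57))
})

test_that("deconvolution agrees with cofactor inversion on random matrices", {
  # independent 3x3 inversion via the cofactor formula
  inv3 <- function(m) {
    minor <- function(i, j) {
      s <- m[-i, -j, drop = FALSE]
      s[1, 1] * s[2, 2] - s[1, 2] * s[2, 1]
    }
    co <- outer(1:3, 1:3, Vectorize(function(i, j) (-1)^(i + j) * minor(i, j)))
    det <- m[1, 1] * minor(1, 1) - m[1, 2] * minor(1, 2) + m[1, 3] * minor(1, 3)
    t(co) / det
  }
  set.seed(42)
  for (k in 1:100) {
    m <- normalize_stain_vectors(matrix(runif(9, 0.1, 1), 3))
    if (abs(det(m)) < 0.05) next  # skip near-singular draws
    d <- deconvolution_matrix(m)
    expect_equal(unname(d), inv3(unname(m)), tolerance = 1e-9)
    expect_equal(unname(d %*% m), diag(3), tolerance = 1e-9)
  }
})

test_that("stain separation is linear and inverts the forward model", {
  m <- normalize_stain_vectors(he_dab_stain_matrix())
  d <- deconvolution_matrix(m)
  zero <- array(0, c(4, 4, 3))
  expect_equal(separate_stains(zero, d), zero)
  set.seed(11)
  conc_true <- array(runif(4 * 5 * 3, 0, 1), c(4, 5, 3))
  od <- array(NA_real_, c(4, 5, 3))
  for (c in 1:3)
    od[, , c] <- conc_true[, , 1] * m[1, c] + conc_true[, , 2] * m[2, c] +
                 conc_true[, , 3] * m[3, c]
  expect_equal(separate_stains(od, d), conc_true, tolerance = 1e-9)
  expect_equal(separate_stains(2 * od, d), 2 * separate_stains(od, d))
})

test_that("hematoxylin channel extraction rescales to [0, 1]", {
  expect_equal(hematoxylin_channel(array(0.7, c(3, 3, 3))), matrix(0, 3, 3))
  # pure-eosin uniform render: hematoxylin concentration ~ 0, constant -> 0
  m <- normalize_stain_vectors(he_dab_stain_matrix())
  d <- deconvolution_matrix(m)
  img <- array(0, c(4, 4, 3))
  for (c in 1:3) img[, , c] <- 255 * 10^-(0.4 * m[2, c])
  h <- hematoxylin_channel(separate_stains(rgb_to_od(img), d))
  expect_true(max(abs(h)) < 0.05)
  # one hematoxylin-dominant block is the channel maximum region
  img2 <- img
  for (c in 1:3) img2[2:3, 2:3, c] <- 255 * 10^-(0.8 * m[1, c] + 0.1 * m[2, c])
  h2 <- hematoxylin_channel(separate_stains(rgb_to_od(img2), d))
  expect_true(all(h2[2:3, 2:3] == 1))
  expect_true(all(h2[h2 < 1] < 0.5))
})
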