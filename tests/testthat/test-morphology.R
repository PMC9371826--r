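test_that("disk dilation/erosion match the brute-force oracle", {
  for (seed in 1:5) {
    img <- rand_img(16, 16, seed)
    for (r in 1:3) {
      expect_identical(gray_dilate(img, r), oracle_dilate(img, r))
      expect_identical(gray_erode(img, r), oracle_erode(img, r))
    }
  }
})

test_that("geodesic dilation is clipped by the mask and grows by the disk radius", {
  g <- matrix(1, 15, 15)
  f <- matrix(0, 15, 15); f[8, 8] <- 1
  cur <- f
  for (k in 1:4) {
    cur <- geodesic_dilate(cur, g, radius = 1)
    # support after k steps is the radius-k disk neighbourhood (city-disk union)
    expected <- matrix(0, 15, 15)
    for (i in 1:15) for (j in 1:15) {
      # union of k unit-disk dilations = all pixels reachable in k unit steps
      d <- abs(i - 8) + abs(j - 8)  # unit disk is the 4-neighbourhood cross
      if (d <= k) expected[i, j] <- 1
    }
    expect_identical(cur, expected)
  }
  expect_identical(geodesic_dilate(g, g, 1), g)   # f = g -> g
  f2 <- matrix(0.5, 4, 4)
  expect_identical(geodesic_dilate(f2, f2, 2), f2)
  expect_error(geodesic_dilate(g, g * 0, 1), "row 1, col 1")
})

test_that("geodesic erosion is the grayscale dual of geodesic dilation", {
  for (seed in 1:10) {
    p <- rand_pair(16, 16, seed)
    K <- 1
    lhs <- geodesic_erode(p$mask, p$marker, radius = 1)   # f >= g side
    rhs <- K - geodesic_dilate(K - p$mask, K - p$marker, radius = 1)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
  f <- matrix(0.8, 6, 6)
  expect_identical(geodesic_erode(f, f, 1), f)
})

test_that("reconstruction recovers exactly the marker-touched components", {
  mask <- matrix(0, 12, 12)
  mask[2:5, 2:5] <- 1      # component A
  mask[8:11, 7:11] <- 1    # component B
  marker <- matrix(0, 12, 12); marker[3, 3] <- 1   # touches A only
  rec <- reconstruct_by_dilation(marker, mask, radius = 1)
  expected <- oracle_flood(marker > 0, mask > 0) * 1
  expect_identical(rec, expected)
  expect_true(all(rec[8:11, 7:11] == 0))
  # dual: dark component touched by a marker pit is fully restored
  rec2 <- reconstruct_by_erosion(1 - marker, 1 - mask, radius = 1)
  expect_identical(rec2, 1 - expected)
})

test_that("reconstruction equals the naive iterate-to-stability oracle bit-exactly", {
  for (seed in 1:10) {
    p <- rand_pair(16, 16, seed)
    expect_identical(reconstruct_by_dilation(p$marker, p$mask, 1),
                     oracle_reconstruct_dilation(p$marker, p$mask, 1))
    expect_identical(reconstruct_by_erosion(p$mask, p$marker, 1),
                     oracle_reconstruct_erosion(p$mask, p$marker, 1))
  }
})

test_that("reconstruction is idempotent, monotone and a geodesic fixed point", {
  p <- rand_pair(16, 16, 77)
  rec <- reconstruct_by_dilation(p$marker, p$mask, 1)
  expect_identical(reconstruct_by_dilation(rec, p$mask, 1), rec)
  expect_identical(geodesic_dilate(rec, p$mask, 1), rec)
  # monotone: smaller marker gives pointwise smaller reconstruction
  rec_small <- reconstruct_by_dilation(p$marker * 0.5, p$mask, 1)
  expect_true(all(rec_small <= rec + 1e-12))
  # f = g is already stable
  expect_identical(reconstruct_by_dilation(p$mask, p$mask, 1), p$mask)
})

test_that("opening by reconstruction removes small bright objects, keeps large ones exactly", {
  img <- matrix(0, 24, 24); img[3:5, 3:5] <- 1
  expect_identical(open_by_reconstruction(img, 3), matrix(0, 24, 24))
  big <- matrix(0, 24, 24); big[5:19, 5:19] <- 1
  expect_identical(open_by_reconstruction(big, 3), big)  # corners intact
  cst <- matrix(0.3, 8, 8)
  expect_identical(open_by_reconstruction(cst, 2), cst)
})

test_that("closing by reconstruction fills small dark pits", {
  img <- matrix(1, 24, 24); img[10:12, 10:12] <- 0
  expect_identical(close_by_reconstruction(img, 3), matrix(1, 24, 24))
  cst <- matrix(0.3, 8, 8)
  expect_identical(close_by_reconstruction(cst, 2), cst)
})

test_that("opening/closing by reconstruction are anti-extensive/extensive and idempotent", {
  for (seed in c(2, 4)) {
    img <- rand_img(20, 20, seed)
    op <- open_by_reconstruction(img, 2)
    cl <- close_by_reconstruction(img, 2)
    expect_true(all(op <= img) && all(cl >= img))
    expect_identical(open_by_reconstruction(op, 2), op)
    expect_identical(close_by_reconstruction(cl, 2), cl)
    # stability of the alternating open/close pair
    oc <- close_by_reconstruction(open_by_reconstruction(img, 2), 2)
    oc2 <- close_by_reconstruction(open_by_reconstruction(oc, 2), 2)
    expect_identical(oc2, oc)
  }
})

test_that("shape smoothing uses the half-radius closing and removes notches", {
  cst <- matrix(0.6, 10, 10)
  expect_identical(smooth_shape(cst, 4), cst)
  # half of radius 4 is 2: equal to a plain closing at radius 2
  img <- rand_img(12, 12, 8)
  closing_r2 <- oracle_erode(oracle_dilate(img, 2), 2)
  expect_identical(smooth_shape(img, 4), closing_r2)
  # single-pixel dark pit inside a bright region is filled at radius 1
  edge <- matrix(0, 10, 10); edge[, 6:10] <- 1; edge[5, 8] <- 0
  sm <- smooth_shape(edge, 2)   # uses radius 1
  expect_equal(sm[5, 8], 1)
})

test_that("convolution backend agrees with an independent image filter (interior)", {
  img <- rand_img(32, 32, 21)
  k <- gaussian_kernel(1.2, 3)
  mine <- gaussian_smooth(img, 1.2, 3)
  ref <- EBImage::filter2(EBImage::Image(img), k)
  expect_equal(mine[5:28, 5:28], EBImage::imageData(ref)[5:28, 5:28],
               tolerance = 1e-10)
})
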