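# Independent brute-force oracles, written in plain R and kept deliberately
# naive: double loops, iterate-to-stability, direct summation. The compiled
# implementations must agree with these on small images.

disk_mask <- function(radius) {
  d <- expand.grid(di = -radius:radius, dj = -radius:radius)
  d[d$di^2 + d$dj^2 <= radius^2, ]
}

oracle_morph <- function(img, radius, fun) {
  H <- nrow(img); W <- ncol(img)
  off <- disk_mask(radius)
  out <- matrix(NA_real_, H, W)
  for (i in 1:H) for (j in 1:W) {
    ii <- i + off$di; jj <- j + off$dj
    ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
    out[i, j] <- fun(img[cbind(ii[ok], jj[ok])])
  }
  out
}

oracle_dilate <- function(img, radius) oracle_morph(img, radius, max)
oracle_erode  <- function(img, radius) oracle_morph(img, radius, min)

oracle_reconstruct_dilation <- function(marker, mask, radius) {
  f <- marker
  repeat {
    nf <- pmin(oracle_dilate(f, radius), mask)
    if (identical(nf, f)) return(f)
    f <- nf
  }
}

oracle_reconstruct_erosion <- function(marker, mask, radius) {
  f <- marker
  repeat {
    nf <- pmax(oracle_erode(f, radius), mask)
    if (identical(nf, f)) return(f)
    f <- nf
  }
}

# half-sample symmetric reflection of a 1-based index into [1, n]
reflect1 <- function(i, n) {
  while (any(i < 1 | i > n)) {
    i <- ifelse(i < 1, 1 - i, i)
    i <- ifelse(i > n, 2 * n + 1 - i, i)
  }
  i
}

oracle_bilateral <- function(img, sigma_s, sigma_r, radius) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(NA_real_, H, W)
  for (i in 1:H) for (j in 1:W) {
    wsum <- 0; vsum <- 0
    for (di in -radius:radius) for (dj in -radius:radius) {
      ii <- reflect1(i + di, H); jj <- reflect1(j + dj, W)
      w <- exp(-(di^2 + dj^2) / (2 * sigma_s^2)) *
           exp(-(img[i, j] - img[ii, jj])^2 / (2 * sigma_r^2))
      wsum <- wsum + w
      vsum <- vsum + w * img[ii, jj]
    }
    out[i, j] <- vsum / wsum
  }
  out
}

# 4-connected flood fill from all TRUE seed pixels restricted to mask
oracle_flood <- function(seed, mask) {
  H <- nrow(mask); W <- ncol(mask)
  reach <- seed & mask
  repeat {
    grown <- reach
    grown[-1, ] <- grown[-1, ] | reach[-H, ]
    grown[-H, ] <- grown[-H, ] | reach[-1, ]
    grown[, -1] <- grown[, -1] | reach[, -W]
    grown[, -W] <- grown[, -W] | reach[, -1]
    grown <- grown & mask
    if (identical(grown, reach)) return(reach)
    reach <- grown
  }
}

# deterministic random grayscale image in [0, 1]
rand_img <- function(H, W, seed) {
  set.seed(seed)
  matrix(runif(H * W), H, W)
}

# random marker/mask pair with marker <= mask
rand_pair <- function(H, W, seed) {
  set.seed(seed)
  a <- matrix(runif(H * W), H, W)
  b <- matrix(runif(H * W), H, W)
  list(marker = pmin(a, b), mask = pmax(a, b))
}

# render a dark-disk intensity image (background 1, disks 0) for FRST tests
disk_image <- function(H, W, centers, radius) {
  img <- matrix(1, H, W)
  for (k in seq_len(nrow(centers))) {
    for (i in 1:H) for (j in 1:W)
      if ((i - centers[k, 1])^2 + (j - centers[k, 2])^2 <= radius^2)
        img[i, j] <- 0
  }
  img
}
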