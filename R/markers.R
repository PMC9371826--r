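#' Fast radial symmetry transform
#'
#' Gradient-voting transform whose response peaks at the centres of radially
#' symmetric blobs. For each radius `n`, every pixel with sufficient gradient
#' magnitude votes at the point `n` pixels along (bright polarity) or against
#' (dark polarity) its gradient direction; an orientation image counts votes
#' and a magnitude image sums gradient magnitudes. The per-radius response
#' `(min(O, k_n)/k_n)^alpha * (M/k_n)` is smoothed with a Gaussian of scale
#' `0.25 * n` and responses are averaged over radii. `k_n` caps the
#' orientation count at 8 for radius 1 and 9.9 otherwise.
#'
#' Nuclei are dark in stained intensity images, so the default polarity is
#' `"dark"`; the segmentation pipeline passes the *inverted* hematoxylin
#' concentration map (nuclei are bright in concentration), keeping that
#' convention.
#'
#' @param image numeric matrix (non-constant, else the response is zero).
#' @param radii integer radii (pixels) of the blobs to respond to.
#' @param alpha radial strictness exponent; larger values penalize
#'   non-radial structure more strongly.
#' @param gradient_threshold fraction of the maximum gradient magnitude below
#'   which pixels do not vote, in `[0, 1)`.
#' @param polarity `"dark"`, `"bright"` or `"both"`.
#' @return Response matrix, same size as `image`.
#' @export
frst <- function(image, radii, alpha = 2, gradient_threshold = 0.05,
                 polarity = c("dark", "bright", "both")) {
  image <- as_gray(image)
  polarity <- match.arg(polarity)
  radii <- as.integer(radii)
  if (length(radii) == 0L || any(is.na(radii)) || any(radii < 1L))
    stop("`radii` must be a non-empty set of integers >= 1")
  if (any(radii > min(dim(image)) / 2))
    stop("radius larger than half the smallest image dimension")
  if (!is.finite(alpha) || alpha <= 0) stop("`alpha` must be positive")
  if (gradient_threshold < 0 || gradient_threshold >= 1)
    stop("`gradient_threshold` must be in [0, 1)")

  H <- nrow(image); W <- ncol(image)
  sobel_x <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)       # d/dcol
  gx <- cpp_conv2_reflect(image, sobel_x)
  gy <- cpp_conv2_reflect(image, t(sobel_x))                     # d/drow
  mag <- sqrt(gx^2 + gy^2)
  gmax <- max(mag)
  if (gmax == 0) return(matrix(0, H, W))

  sel <- which(mag > gradient_threshold * gmax)
  ui <- gy[sel] / mag[sel]
  uj <- gx[sel] / mag[sel]
  pi0 <- ((sel - 1L) %% H) + 1L
  pj0 <- ((sel - 1L) %/% H) + 1L
  msel <- mag[sel]

  vote <- function(ti, tj) {
    ok <- ti >= 1L & ti <= H & tj >= 1L & tj <= W
    idx <- (tj[ok] - 1L) * H + ti[ok]
    o <- tabulate(idx, H * W)
    m <- numeric(H * W)
    s <- rowsum(msel[ok], group = idx)
    m[as.integer(rownames(s))] <- s
    list(o = matrix(o, H, W), m = matrix(m, H, W))
  }

  resp <- matrix(0, H, W)
  for (n in radii) {
    o <- matrix(0, H, W); m <- matrix(0, H, W)
    if (polarity %in% c("bright", "both")) {
      v <- vote(pi0 + as.integer(round(n * ui)), pj0 + as.integer(round(n * uj)))
      o <- o + v$o; m <- m + v$m
    }
    if (polarity %in% c("dark", "both")) {
      v <- vote(pi0 - as.integer(round(n * ui)), pj0 - as.integer(round(n * uj)))
      o <- o + v$o; m <- m + v$m
    }
    kn <- if (n == 1L) 8 else 9.9
    fn <- (pmin(o, kn) / kn)^alpha * (m / kn)
    sigma <- 0.25 * n
    resp <- resp + gaussian_smooth(fn, sigma, radius = max(1L, ceiling(3 * sigma)))
  }
  resp / length(radii)
}

#' Extract centres from a symmetry response map
#'
#' Finds local maxima (8-neighbourhood) at least `rel_threshold` times the
#' global maximum, then accepts them greedily in descending score order,
#' rejecting any candidate within `min_distance` pixels (Euclidean) of an
#' already accepted centre. Score ties break by (row, col) order, so the
#' result is deterministic; the returned list is sorted by (row, col).
#'
#' @param response numeric matrix, e.g. from [frst()].
#' @param rel_threshold fraction of the global maximum in `(0, 1]`.
#' @param min_distance exclusion radius in pixels (>= 1).
#' @return `data.frame` with integer columns `row`, `col` (1-based) and
#'   numeric `score`; zero rows when the response has no positive peak.
#' @export
detect_centers <- function(response, rel_threshold = 0.3, min_distance = 8) {
  response <- as_gray(response)
  if (rel_threshold <= 0 || rel_threshold > 1)
    stop("`rel_threshold` must be in (0, 1]")
  if (min_distance < 1) stop("`min_distance` must be >= 1")
  H <- nrow(response); W <- ncol(response)
  top <- max(response)
  empty <- data.frame(row = integer(), col = integer(), score = numeric())
  if (top <= 0) return(empty)

  # local maxima: >= all 8 neighbours (borders padded with -Inf)
  pad <- matrix(-Inf, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- response
  is_max <- matrix(TRUE, H, W)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    is_max <- is_max & response >= pad[(2:(H + 1L)) + di, (2:(W + 1L)) + dj]
  }
  cand <- which(is_max & response >= rel_threshold * top)
  if (length(cand) == 0L) return(empty)
  ci <- ((cand - 1L) %% H) + 1L
  cj <- ((cand - 1L) %/% H) + 1L
  sc <- response[cand]
  ord <- order(-sc, ci, cj)
  ci <- ci[ord]; cj <- cj[ord]; sc <- sc[ord]

  keep_i <- integer(); keep_j <- integer(); keep_s <- numeric()
  for (k in seq_along(ci)) {
    if (length(keep_i) == 0L ||
        all((keep_i - ci[k])^2 + (keep_j - cj[k])^2 >= min_distance^2)) {
      keep_i <- c(keep_i, ci[k]); keep_j <- c(keep_j, cj[k])
      keep_s <- c(keep_s, sc[k])
    }
  }
  out <- data.frame(row = keep_i, col = keep_j, score = keep_s)
  out[order(out$row, out$col), , drop = FALSE]
}

#' Stamp centres into a foreground marker image
#'
#' Creates a label image with a small disk stamped at each centre, labelled
#' 1..N in list order. Stamps are clipped to the image and an overlapping
#' later stamp yields to the earlier one (no pixel is relabelled).
#'
#' @param centers `data.frame` with `row`, `col` columns (1-based), as from
#'   [detect_centers()].
#' @param dim image dimensions `c(H, W)`.
#' @param stamp_radius disk radius of each stamp in pixels.
#' @return Integer `H x W` matrix; 0 = background, 1..N = marker stamps.
#' @export
centers_to_markers <- function(centers, dim, stamp_radius = 2L) {
  H <- as.integer(dim[1]); W <- as.integer(dim[2])
  lab <- matrix(0L, H, W)
  if (nrow(centers) == 0L) return(lab)
  if (any(centers$row < 1L | centers$row > H | centers$col < 1L | centers$col > W))
    stop("centre coordinates outside the image")
  r <- max(0L, as.integer(stamp_radius))
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= r^2, ]
  for (k in seq_len(nrow(centers))) {
    ii <- centers$row[k] + off$di
    jj <- centers$col[k] + off$dj
    ok <- ii >= 1L & ii <= H & jj >= 1L & jj <= W
    idx <- (jj[ok] - 1L) * H + ii[ok]
    idx <- idx[lab[idx] == 0L]
    lab[idx] <- k
  }
  lab
}
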