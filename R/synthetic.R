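#' Generate a synthetic nucleus scene
#'
#' Samples a hard-core point pattern of elliptical "nuclei" on a rectangular
#' image: centres are rejection-sampled until all pairwise distances are at
#' least `min_separation`, semi-major axes are uniform in `radius_range`,
#' axis ratios uniform in `axis_ratio_range` (near-circular, as hematoxylin
#' nuclei mostly are), and orientations uniform. Every nucleus lies fully
#' inside the image. All randomness flows from `seed`; the caller's RNG
#' state is left untouched.
#'
#' @param n_nuclei number of nuclei.
#' @param size image size `c(H, W)` (a scalar means square).
#' @param radius_range range of the semi-major axis in pixels.
#' @param min_separation minimum centre-to-centre distance in pixels;
#'   defaults to `2 * max(radius_range) + 2` so nuclei never touch.
#' @param axis_ratio_range range of the minor/major axis ratio.
#' @param concentrations stain concentrations: named list with
#'   `nucleus = c(H, E)` and `background = c(H, E)` amounts.
#' @param noise_sigma additive Gaussian noise standard deviation on the
#'   8-bit intensity scale.
#' @param seed integer seed.
#' @return A `nucseg_scene` object describing the ground truth.
#' @export
generate_scene <- function(n_nuclei = 30L, size = c(256L, 256L),
                           radius_range = c(6, 10),
                           min_separation = 2 * max(radius_range) + 2,
                           axis_ratio_range = c(0.7, 1.0),
                           concentrations = list(nucleus = c(0.8, 0.1),
                                                 background = c(0.05, 0.35)),
                           noise_sigma = 3, seed = 1L) {
  size <- rep_len(as.integer(size), 2L)
  H <- size[1]; W <- size[2]
  r_max <- max(radius_range)
  if (n_nuclei * pi * r_max^2 >= 0.5 * H * W)
    stop("infeasible packing: too many/large nuclei for the image")
  margin <- r_max + 2
  if (H - 2 * margin <= 0 || W - 2 * margin <= 0)
    stop("image too small for the requested nucleus radius")

  centers <- with_scene_seed(seed, {
    ci <- numeric(0); cj <- numeric(0)
    attempts <- 0L
    while (length(ci) < n_nuclei) {
      attempts <- attempts + 1L
      if (attempts > 20000L)
        stop("failed to place nuclei after 20000 attempts; ",
             "reduce n_nuclei or min_separation")
      i <- stats::runif(1, margin, H - margin)
      j <- stats::runif(1, margin, W - margin)
      if (length(ci) == 0L ||
          all((ci - i)^2 + (cj - j)^2 >= min_separation^2)) {
        ci <- c(ci, i); cj <- c(cj, j)
      }
    }
    a <- stats::runif(n_nuclei, radius_range[1], radius_range[2])
    b <- a * stats::runif(n_nuclei, axis_ratio_range[1], axis_ratio_range[2])
    theta <- stats::runif(n_nuclei, 0, pi)
    data.frame(row = ci, col = cj, a = a, b = b, theta = theta)
  })
  if (n_nuclei == 0L)
    centers <- data.frame(row = numeric(), col = numeric(), a = numeric(),
                          b = numeric(), theta = numeric())

  structure(list(size = size, nuclei = centers,
                 concentrations = concentrations,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "nucseg_scene")
}

# evaluate expr under a scene-derived RNG stream, restoring global state
with_scene_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.nucseg_scene <- function(x, ...) {
  cat(sprintf("nucseg scene: %d x %d, %d nuclei, noise sigma %.3g, seed %d\n",
              x$size[1], x$size[2], nrow(x$nuclei), x$noise_sigma, x$seed))
  invisible(x)
}

#' Render a scene to an H&E-like RGB image
#'
#' Forward Beer-Lambert model: each pixel's per-channel intensity is
#' `I_c = I0 * 10^(-sum_s c_s * M[s, c])` with M the normalized stain
#' matrix, nucleus interiors carrying high hematoxylin and the background
#' high eosin. Seeded Gaussian noise is added per channel and clipped to
#' `[0, I0]`. Intensities are kept continuous (not quantized to integers);
#' quantization happens only if the image is written to an 8-bit file.
#'
#' @param scene a [generate_scene()] result.
#' @param stains raw stain matrix (rows = stains), normalized internally.
#' @param i0 incident intensity (default 255).
#' @return List with `image` (`H x W x 3`, in `[0, i0]`), `labels` (integer
#'   ground-truth mask, 0 = background, 1..N = nuclei) and `centers`
#'   (`data.frame` of the true centres, 1-based `row`, `col`).
#' @export
render_scene <- function(scene, stains = he_dab_stain_matrix(), i0 = 255) {
  stopifnot(inherits(scene, "nucseg_scene"))
  m <- normalize_stain_vectors(stains)
  H <- scene$size[1]; W <- scene$size[2]
  labels <- matrix(0L, H, W)
  nuc <- scene$nuclei
  for (k in seq_len(nrow(nuc))) {
    # bounding box scan, exact point-in-ellipse test
    r <- ceiling(max(nuc$a[k], nuc$b[k])) + 1L
    ii <- max(1L, floor(nuc$row[k] - r)):min(H, ceiling(nuc$row[k] + r))
    jj <- max(1L, floor(nuc$col[k] - r)):min(W, ceiling(nuc$col[k] + r))
    di <- outer(ii - nuc$row[k], rep(1, length(jj)))
    dj <- outer(rep(1, length(ii)), jj - nuc$col[k])
    u <- (di * cos(nuc$theta[k]) + dj * sin(nuc$theta[k])) / nuc$a[k]
    v <- (-di * sin(nuc$theta[k]) + dj * cos(nuc$theta[k])) / nuc$b[k]
    inside <- u^2 + v^2 <= 1
    block <- labels[ii, jj]
    block[inside] <- k
    labels[ii, jj] <- block
  }
  cH <- ifelse(labels > 0L, scene$concentrations$nucleus[1],
               scene$concentrations$background[1])
  cE <- ifelse(labels > 0L, scene$concentrations$nucleus[2],
               scene$concentrations$background[2])
  img <- array(0, c(H, W, 3))
  for (c in 1:3)
    img[, , c] <- i0 * 10^-(cH * m[1, c] + cE * m[2, c])
  if (scene$noise_sigma > 0) {
    noise <- with_scene_seed(scene$seed + 1L,
                             array(stats::rnorm(H * W * 3, 0, scene$noise_sigma),
                                   c(H, W, 3)))
    img <- img + noise
  }
  img <- pmin(pmax(img, 0), i0)
  list(image = img,
       labels = labels,
       centers = data.frame(row = nuc$row, col = nuc$col))
}
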