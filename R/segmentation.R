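#' Morphological gradient relief
#'
#' The watershed flooding surface: dilation minus erosion with a unit disk.
#' The relief is zero on flat regions and large on edges, so basins form
#' inside nuclei and in the background, separated by ridges on nucleus
#' boundaries.
#'
#' @param image prepared grayscale map.
#' @return Non-negative matrix of the same size.
#' @export
relief_map <- function(image) {
  image <- as_gray(image)
  cpp_disk_dilate(image, 1L) - cpp_disk_erode(image, 1L)
}

#' Background markers from Otsu thresholding
#'
#' Thresholds the hematoxylin map with Otsu's method (over the data range,
#' so the mask is invariant to adding a constant), takes the complement as
#' candidate background, and erodes it by a disk of the expected nucleus
#' radius so the marker keeps a safe distance from every nucleus.
#'
#' @param image prepared hematoxylin map (nuclei bright).
#' @param nucleus_radius expected nucleus radius in pixels.
#' @return Logical matrix, `TRUE` on confident background. Constant images
#'   yield an empty mask with a warning.
#' @export
background_markers <- function(image, nucleus_radius = 8L) {
  image <- as_gray(image)
  rng <- range(image)
  if (rng[2] - rng[1] <= 0) {
    warning("constant image: no background markers")
    return(matrix(FALSE, nrow(image), ncol(image)))
  }
  thr <- EBImage::otsu(EBImage::Image(image), range = rng, levels = 256L)
  bg <- (image <= thr) * 1
  er <- cpp_disk_erode(bg, check_radius(nucleus_radius))
  mask <- er >= 1
  if (!any(mask)) warning("no background markers survive erosion")
  mask
}

#' Marker-controlled watershed
#'
#' Floods the relief from all markers simultaneously in ascending relief
#' order: the background mask seeds label 0 and each foreground marker seeds
#' its own label. Every reachable pixel joins the basin that reaches it
#' first; ties break by (relief, row, col), so the result is deterministic.
#' Each foreground region is connected and contains its marker stamp; with
#' no foreground markers every pixel gets label 0.
#'
#' @param relief numeric flooding surface, e.g. [relief_map()].
#' @param fg integer foreground marker image (0 = none, 1..N = markers), as
#'   from [centers_to_markers()].
#' @param bg logical background marker mask, disjoint from `fg`.
#' @param connectivity 4 (default) or 8 neighbourhood for flooding.
#' @return Integer label matrix: 0 = background, 1..N = nuclei.
#' @export
marker_watershed <- function(relief, fg, bg, connectivity = 4L) {
  relief <- as_gray(relief)
  if (!all(dim(fg) == dim(relief)) || !all(dim(bg) == dim(relief)))
    stop("relief, fg and bg must share dimensions")
  fg <- matrix(as.integer(fg), nrow(relief))
  if (any(bg & fg > 0L))
    stop("foreground and background markers overlap")
  seeds <- matrix(-1L, nrow(relief), ncol(relief))
  seeds[bg] <- 0L
  seeds[fg > 0L] <- fg[fg > 0L]
  cpp_marker_watershed(relief, seeds, as.integer(connectivity))
}

#' Segment nuclei in an H&E image
#'
#' Runs the full foreground-marker watershed pipeline:
#' \enumerate{
#'   \item colour deconvolution of the optical-density image and extraction
#'     of the hematoxylin channel;
#'   \item Gaussian then bilateral denoising;
#'   \item opening and closing by reconstruction, then a half-size smoothing
#'     closing;
#'   \item fast radial symmetry transform on the inverted map, peak
#'     extraction, and marker stamping (skipped, yielding zero nuclei, when
#'     the absolute hematoxylin contrast falls below
#'     `markers.min_contrast` — blank fields contain no nuclei);
#'   \item Otsu-based background markers and marker-controlled watershed on
#'     the morphological gradient.
#' }
#' Deterministic: identical image and configuration give bit-identical
#' output.
#'
#' @param image `H x W x 3` RGB array, values in `[0, 255]`.
#' @param config a [nucseg_config()] object.
#' @param keep_stages keep intermediate images in the result (for
#'   inspection/debugging).
#' @return A `nucseg_segmentation` object: list with `labels` (integer
#'   matrix, 0 = background), `centers` (`data.frame` of 1-based `row`,
#'   `col`, `score`), `config`, and optionally `stages`.
#' @export
segment_nuclei <- function(image, config = nucseg_config(), keep_stages = FALSE) {
  stopifnot(inherits(config, "nucseg_config"))
  cfg <- resolve_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage \"%s\": %s", name, conditionMessage(e)), call. = FALSE))
  }

  h_contrast <- NA_real_
  h <- stage("stain_separation", {
    od <- rgb_to_od(image)
    m <- normalize_stain_vectors(matrix(cfg$stains$matrix, 3, byrow = TRUE))
    conc <- separate_stains(od, deconvolution_matrix(m))
    h_contrast <- diff(range(conc[, , 1]))   # absolute concentration contrast
    hematoxylin_channel(conc)
  })
  den <- stage("denoising", {
    g <- gaussian_smooth(h, cfg$gaussian$sigma, cfg$gaussian$radius)
    bilateral_filter(g, cfg$bilateral$sigma_spatial, cfg$bilateral$sigma_range,
                     cfg$bilateral$radius)
  })
  prep <- stage("morphology", {
    r <- cfg$morphology$se_radius
    smooth_shape(close_by_reconstruction(open_by_reconstruction(den, r), r), r)
  })
  centers <- stage("markers", {
    # gate on absolute hematoxylin contrast: FRST and peak extraction are
    # scale-free, so a blank field would otherwise amplify noise into
    # spurious centres.  Contrast is measured in concentration units
    # (nucleus-background contrast is ~0.75 at typical staining; noise-only
    # fields sit well below 0.1).
    contrast <- diff(range(prep)) * h_contrast
    if (!is.finite(contrast) || contrast < cfg$markers$min_contrast) {
      data.frame(row = integer(), col = integer(), score = numeric())
    } else {
      src <- if (cfg$frst$source == "prepared") prep else den
      resp <- frst(max(src) - src, cfg$frst$radii, cfg$frst$alpha,
                   cfg$frst$gradient_threshold, cfg$frst$polarity)
      detect_centers(resp, cfg$markers$rel_threshold, cfg$markers$min_distance)
    }
  })
  labels <- stage("watershed", {
    fg <- centers_to_markers(centers, dim(prep), cfg$markers$stamp_radius)
    bg <- background_markers(prep, round(cfg$morphology$nucleus_radius))
    bg[fg > 0L] <- FALSE
    relief <- if (cfg$watershed$surface == "gradient") relief_map(prep)
              else max(prep) - prep
    marker_watershed(relief, fg, bg, cfg$watershed$connectivity)
  })

  out <- list(labels = labels, centers = centers, config = config)
  if (keep_stages) out$stages <- list(hematoxylin = h, denoised = den,
                                      prepared = prep)
  structure(out, class = "nucseg_segmentation")
}

#' @export
print.nucseg_segmentation <- function(x, ...) {
  cat(sprintf("nucseg segmentation: %d x %d image, %d nuclei\n",
              nrow(x$labels), ncol(x$labels), nrow(x$centers)))
  invisible(x)
}

#' Plot a segmentation as a label overlay
#'
#' @param x a `nucseg_segmentation`.
#' @param ... passed to [graphics::image()].
#' @export
plot.nucseg_segmentation <- function(x, ...) {
  n <- max(x$labels)
  cols <- c("grey95", grDevices::hcl.colors(max(n, 1L), "Dark 3"))
  graphics::image(t(x$labels)[, nrow(x$labels):1], col = cols, axes = FALSE,
                  asp = nrow(x$labels) / ncol(x$labels), ...)
  invisible(x)
}
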