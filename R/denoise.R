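#' Discretized 2D Gaussian kernel
#'
#' Samples `exp(-(x^2 + y^2) / (2 sigma^2)) / (2 pi sigma^2)` on the integer
#' grid `[-radius, radius]^2` and normalizes the result to sum to one.
#'
#' @param sigma spatial standard deviation in pixels (> 0).
#' @param radius kernel half-width in pixels; defaults to `ceiling(3 * sigma)`.
#' @return `(2 radius + 1)` square matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, radius = ceiling(3 * sigma)) {
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be positive")
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be at least 1")
  x <- -radius:radius
  k <- outer(x, x, function(i, j) exp(-(i^2 + j^2) / (2 * sigma^2)))
  k <- k / (2 * pi * sigma^2)
  k / sum(k)
}

#' Gaussian smoothing
#'
#' Convolves a grayscale image with the normalized Gaussian kernel,
#' reflecting the image at its borders (so constant images are exact fixed
#' points and no dark halo appears at the edge).
#'
#' @param image numeric matrix.
#' @inheritParams gaussian_kernel
#' @return Smoothed matrix of the same size.
#' @export
gaussian_smooth <- function(image, sigma = 1, radius = ceiling(3 * sigma)) {
  image <- as_gray(image)
  cpp_conv2_reflect(image, gaussian_kernel(sigma, radius))
}

#' Edge-preserving bilateral filter
#'
#' Each output pixel is the normalized weighted mean of the intensities in a
#' square window, weighted by a spatial Gaussian of scale `sigma_spatial` and
#' a range (intensity-difference) Gaussian of scale `sigma_range`. Pixels on
#' the far side of an edge get small range weights, so edges stay sharp while
#' flat regions are smoothed. Borders are handled by reflection, matching
#' [gaussian_smooth()]; with an effectively infinite `sigma_range` the filter
#' reduces to Gaussian smoothing at `sigma_spatial`.
#'
#' @param image numeric matrix.
#' @param sigma_spatial spatial scale in pixels.
#' @param sigma_range range scale in intensity units (the working maps are on
#'   `[0, 1]`, so the default 0.1 is a tenth of full scale).
#' @param radius window half-width; defaults to `ceiling(3 * sigma_spatial)`.
#' @return Filtered matrix; every output value lies within the range of the
#'   input (convex combination of window intensities).
#' @export
bilateral_filter <- function(image, sigma_spatial = 2, sigma_range = 0.1,
                             radius = ceiling(3 * sigma_spatial)) {
  image <- as_gray(image)
  if (!is.finite(sigma_spatial) || sigma_spatial <= 0)
    stop("`sigma_spatial` must be positive")
  if (!is.finite(sigma_range) || sigma_range <= 0)
    stop("`sigma_range` must be positive (degenerate range kernel)")
  radius <- as.integer(radius)
  if (radius < 1L) stop("`radius` must be at least 1")
  cpp_bilateral(image, sigma_spatial, sigma_range, radius)
}

# coerce to a plain numeric matrix, rejecting empty/ill-shaped input
as_gray <- function(image) {
  if (is.null(dim(image)) || length(dim(image)) != 2L)
    stop("expected a 2D grayscale image")
  if (any(dim(image) == 0L)) stop("empty image")
  storage.mode(image) <- "double"
  if (any(!is.finite(image))) stop("image has non-finite values")
  image
}
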