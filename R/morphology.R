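#' Flat-disk grayscale dilation and erosion
#'
#' Dilation (erosion) replaces each pixel by the maximum (minimum) over a
#' flat disk of the given radius. At the border only in-image neighbours are
#' considered, the usual minus/plus-infinity padding convention.
#'
#' @param image numeric matrix.
#' @param radius disk radius in pixels (>= 1); a pixel at offset `(dy, dx)`
#'   belongs to the disk when `dy^2 + dx^2 <= radius^2`.
#' @return Matrix of the same size.
#' @export
gray_dilate <- function(image, radius = 1L) {
  cpp_disk_dilate(as_gray(image), check_radius(radius))
}

#' @rdname gray_dilate
#' @export
gray_erode <- function(image, radius = 1L) {
  cpp_disk_erode(as_gray(image), check_radius(radius))
}

check_radius <- function(radius) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) stop("`radius` must be an integer >= 1")
  radius
}

check_pair <- function(marker, mask, dilation) {
  marker <- as_gray(marker)
  mask <- as_gray(mask)
  if (!all(dim(marker) == dim(mask)))
    stop("marker and mask must have the same dimensions")
  bad <- if (dilation) marker > mask else marker < mask
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "marker must be %s mask everywhere; first violation at (row %d, col %d)",
      if (dilation) "<=" else ">=", idx[1], idx[2]))
  }
  list(marker = marker, mask = mask)
}

#' Geodesic dilation and erosion
#'
#' One geodesic step of a marker image `f` against a mask image `g`:
#' geodesic dilation is the pointwise minimum of the dilated marker and the
#' mask (requires `f <= g`); geodesic erosion is the pointwise maximum of
#' the eroded marker and the mask (requires `f >= g`). Iterating either step
#' to stability gives morphological reconstruction.
#'
#' @param marker grayscale marker image `f`.
#' @param mask grayscale mask image `g`, same size.
#' @param radius structuring-element (flat disk) radius.
#' @return Matrix of the same size, bounded between marker and mask.
#' @export
geodesic_dilate <- function(marker, mask, radius = 1L) {
  p <- check_pair(marker, mask, dilation = TRUE)
  pmin(cpp_disk_dilate(p$marker, check_radius(radius)), p$mask)
}

#' @rdname geodesic_dilate
#' @export
geodesic_erode <- function(marker, mask, radius = 1L) {
  p <- check_pair(marker, mask, dilation = FALSE)
  pmax(cpp_disk_erode(p$marker, check_radius(radius)), p$mask)
}

#' Morphological reconstruction
#'
#' Iterates the geodesic step until two successive iterates are identical and
#' returns the fixed point. Reconstruction by dilation grows the marker
#' inside the mask, exactly restoring the mask components the marker touches
#' and erasing the rest; reconstruction by erosion is its dual. Convergence
#' is guaranteed (monotone, bounded by the mask); the iteration count is
#' capped at `H * W`.
#'
#' @inheritParams geodesic_dilate
#' @return Matrix of the same size; a fixed point of the geodesic step.
#' @export
reconstruct_by_dilation <- function(marker, mask, radius = 1L) {
  p <- check_pair(marker, mask, dilation = TRUE)
  cpp_reconstruct(p$marker, p$mask, check_radius(radius), TRUE)$image
}

#' @rdname reconstruct_by_dilation
#' @export
reconstruct_by_erosion <- function(marker, mask, radius = 1L) {
  p <- check_pair(marker, mask, dilation = FALSE)
  cpp_reconstruct(p$marker, p$mask, check_radius(radius), FALSE)$image
}

#' Opening and closing by reconstruction
#'
#' Opening by reconstruction erodes the image and then reconstructs it by
#' dilation under the original: bright structures smaller than the disk are
#' removed while surviving structures keep their exact shape (unlike a plain
#' opening, which rounds corners). Closing by reconstruction is the dual and
#' removes small dark structures. Both are idempotent; opening is
#' anti-extensive (output <= input) and closing extensive (output >= input).
#'
#' @param image numeric matrix.
#' @param radius structuring-element radius; structures smaller than this
#'   disk are flattened.
#' @return Matrix of the same size.
#' @export
open_by_reconstruction <- function(image, radius = 1L) {
  image <- as_gray(image)
  radius <- check_radius(radius)
  reconstruct_by_dilation(cpp_disk_erode(image, radius), image, radius)
}

#' @rdname open_by_reconstruction
#' @export
close_by_reconstruction <- function(image, radius = 1L) {
  image <- as_gray(image)
  radius <- check_radius(radius)
  reconstruct_by_erosion(cpp_disk_dilate(image, radius), image, radius)
}

#' Contour-smoothing closing
#'
#' A plain morphological closing (dilation then erosion) with a disk half the
#' radius of the main reconstruction structuring element (at least 1). Run
#' after opening/closing by reconstruction, it removes the burrs and small
#' adhesions left on nucleus outlines without disturbing nucleus-scale
#' structure.
#'
#' @param image numeric matrix.
#' @param full_radius radius of the reconstruction structuring element; the
#'   smoothing disk uses `max(1, floor(full_radius / 2))`.
#' @return Matrix of the same size.
#' @export
smooth_shape <- function(image, full_radius = 4L) {
  image <- as_gray(image)
  r <- max(1L, as.integer(floor(check_radius(full_radius) / 2)))
  cpp_disk_erode(cpp_disk_dilate(image, r), r)
}
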