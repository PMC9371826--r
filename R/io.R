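img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") "png"
  else if (ext %in% c("tif", "tiff")) "tiff"
  else stop("unsupported image format \".", ext, "\"; use PNG or TIFF")
}

#' Read an RGB image
#'
#' Reads an 8-bit RGB PNG or TIFF as an `H x W x 3` array on the `[0, 255]`
#' scale. Grayscale images are rejected (the pipeline needs three colour
#' channels for stain separation); an alpha channel is dropped with a
#' warning; 16-bit input is rescaled to the 8-bit range with a warning.
#'
#' @param path file path (.png, .tif, .tiff).
#' @return Numeric `H x W x 3` array in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  fmt <- img_format(path)
  img <- if (fmt == "png") png::readPNG(path, info = TRUE)
         else tiff::readTIFF(path, info = TRUE)
  info <- attr(img, "info")
  depth <- if (fmt == "png") info$bit.depth else attr(img, "bits.per.sample")
  if (is.null(depth)) depth <- 8L
  if (length(dim(img)) == 2L || dim(img)[3] == 1L)
    stop("grayscale image: the pipeline requires a 3-channel RGB image")
  if (dim(img)[3] == 4L) {
    warning("alpha channel dropped")
    img <- img[, , 1:3, drop = FALSE]
  }
  if (dim(img)[3] != 3L)
    stop("unsupported channel count (", dim(img)[3], "); expected RGB")
  if (depth > 8L) warning(depth, "-bit image rescaled to the 8-bit range")
  arr <- array(as.numeric(img), dim(img)) * 255
  attr(arr, "info") <- NULL
  arr
}

#' Write an 8-bit RGB image
#'
#' Rounds to integers, clips to `[0, 255]` and writes PNG or TIFF.
#'
#' @param image `H x W x 3` array on the `[0, 255]` scale.
#' @param path output path (.png, .tif, .tiff).
#' @export
write_image <- function(image, path) {
  fmt <- img_format(path)
  x <- pmin(pmax(round(image), 0), 255) / 255
  if (fmt == "png") png::writePNG(x, path) else tiff::writeTIFF(x, path)
  invisible(path)
}

#' Write and read a stain concentration map
#'
#' Per-stain grayscale maps are written either as 32-bit float TIFF or as
#' 8-bit PNG after min-max rescaling to `[0, 1]`. Float TIFF samples are
#' stored as `value / 4` (the writer's float range is `[0, 1]`; optical
#' densities and hence concentrations stay below 4, and division by a power
#' of two costs no precision); `read_stain_map()` undoes the scaling.
#' Values are clipped to `[0, 4]` on write — negative unmixing residuals
#' truncate to 0.
#'
#' @param map numeric matrix.
#' @param path output path.
#' @param format `"float_tiff"` (default for .tif/.tiff) or `"png8"`.
#' @return `read_stain_map()` returns the concentration matrix.
#' @export
write_stain_map <- function(map, path,
                            format = c("float_tiff", "png8")) {
  format <- match.arg(format)
  map <- as_gray(map)
  if (format == "float_tiff") {
    if (img_format(path) != "tiff") stop("float maps must be written as TIFF")
    tiff::writeTIFF(pmin(pmax(map, 0), 4) / 4, path,
                    bits.per.sample = 32L, reduce = FALSE)
  } else {
    rng <- range(map)
    x <- if (rng[2] > rng[1]) (map - rng[1]) / (rng[2] - rng[1]) else map * 0
    png::writePNG(x, path)
  }
  invisible(path)
}

#' @rdname write_stain_map
#' @export
read_stain_map <- function(path) {
  if (!file.exists(path)) stop("stain map file not found: ", path)
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x * 4
}

#' Write and read label images
#'
#' Label images are stored as single-channel 16-bit TIFF, which round-trips
#' integer labels exactly. (The PNG writer available here is 8-bit only, so
#' label output is TIFF.)
#'
#' @param labels integer matrix, values in `[0, 65535]`.
#' @param path output path (.tif/.tiff).
#' @return `read_labels()` returns the integer label matrix.
#' @export
write_labels <- function(labels, path) {
  if (img_format(path) != "tiff")
    stop("labels are written as 16-bit TIFF; use a .tif/.tiff path")
  if (max(labels) > 65535L)
    stop("more than 65535 labels cannot be stored in 16 bits")
  if (min(labels) < 0L) stop("labels must be non-negative")
  tiff::writeTIFF(matrix(as.numeric(labels) / 65535, nrow(labels)),
                  path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  x <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  matrix(as.integer(x), nrow(x))
}

#' Write and read centre lists
#'
#' Centres are exchanged as CSV with header `row,col,score` using 0-based
#' (row, col) coordinates, origin at the top-left pixel. In memory the
#' package uses 1-based coordinates (the R convention); the offset is
#' applied here, at the file boundary only.
#'
#' @param centers `data.frame` with `row`, `col` and optionally `score`.
#' @param path CSV path.
#' @return `read_centers()` returns a 1-based `data.frame` with `row`,
#'   `col`, `score`.
#' @export
write_centers <- function(centers, path) {
  out <- data.frame(row = centers$row - 1, col = centers$col - 1,
                    score = if ("score" %in% names(centers)) centers$score
                            else NA_real_)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_centers
#' @export
read_centers <- function(path) {
  if (!file.exists(path)) stop("centre file not found: ", path)
  x <- utils::read.csv(path)
  if (!all(c("row", "col") %in% names(x)))
    stop("centre CSV must have columns row,col[,score]")
  data.frame(row = x$row + 1, col = x$col + 1,
             score = if ("score" %in% names(x)) x$score else NA_real_)
}
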