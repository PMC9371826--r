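#' Standard H&E-DAB stain optical-density vectors
#'
#' Raw (unnormalized) optical-density vectors for hematoxylin, eosin and DAB
#' over the (R, G, B) channels, rows = stains. These are the widely used
#' reference vectors for brightfield colour deconvolution; pass them through
#' [normalize_stain_vectors()] before inverting.
#'
#' @return A 3x3 numeric matrix with rownames `c("hematoxylin", "eosin",
#'   "dab")` and colnames `c("R", "G", "B")`.
#' @export
#' @examples
#' m <- normalize_stain_vectors(he_dab_stain_matrix())
#' round(diag(deconvolution_matrix(m)), 2)
he_dab_stain_matrix <- function() {
  m <- rbind(
    hematoxylin = c(0.650, 0.704, 0.286),
    eosin       = c(0.072, 0.990, 0.105),
    dab         = c(0.268, 0.570, 0.776)
  )
  colnames(m) <- c("R", "G", "B")
  m
}

#' Convert an RGB image to optical density
#'
#' Per channel, `OD_c = -log10(I_c / I0_c)`: the Beer-Lambert optical density
#' of the transmitted light, which is additive across stains and linear in
#' stain concentration. Intensities are clamped to at least 1 before the log
#' so a zero pixel yields a finite density (about 2.41 for 8-bit input).
#'
#' @param image numeric `H x W x 3` array, values in `[0, i0]`.
#' @param i0 incident light intensity, a positive scalar or length-3 vector
#'   (default 255 for 8-bit images).
#' @return `H x W x 3` array of non-negative optical densities.
#' @export
rgb_to_od <- function(image, i0 = 255) {
  if (any(!is.finite(i0)) || any(i0 <= 0))
    stop("`i0` must be positive and finite")
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("`image` must be an H x W x 3 array")
  if (any(image < 0)) stop("`image` has negative intensities")
  i0 <- rep_len(i0, 3L)
  if (any(sweep(image, 3, i0, ">"))) stop("`image` has intensities above `i0`")
  od <- image
  for (c in 1:3) od[, , c] <- -log10(pmax(image[, , c], 1) / i0[c])
  pmax(od, 0)
}

#' Normalize stain vectors to unit length
#'
#' Divides each stain's OD vector (a row) by its Euclidean norm, giving the
#' normalized stain matrix M whose inverse is the colour-deconvolution
#' matrix.
#'
#' @param raw 3x3 numeric matrix, rows = stains, columns = (R, G, B).
#' @return The row-normalized 3x3 matrix (rownames preserved).
#' @export
normalize_stain_vectors <- function(raw) {
  raw <- as.matrix(raw)
  if (!all(dim(raw) == c(3L, 3L))) stop("stain matrix must be 3x3")
  if (any(!is.finite(raw))) stop("stain matrix has non-finite entries")
  len <- sqrt(rowSums(raw^2))
  if (any(len == 0)) {
    bad <- stain_names(raw)[len == 0]
    stop("degenerate stain vector (all zero): ", paste(bad, collapse = ", "))
  }
  m <- raw / len
  if (qr(m)$rank < 3L)
    warning("stain vectors are collinear; the stain matrix is singular")
  m
}

stain_names <- function(m) {
  if (!is.null(rownames(m))) rownames(m) else paste0("stain", 1:3)
}

#' Colour-deconvolution matrix
#'
#' Inverts the normalized stain matrix M, giving the matrix D with
#' `C = D %*% y`: per-pixel stain contributions from the OD vector y. For the
#' standard H&E-DAB vectors the diagonal of D is (1.88, 1.13, 1.57) to two
#' decimals.
#'
#' @param m normalized 3x3 stain matrix (rows = stains).
#' @return 3x3 matrix D with `D %*% m` equal to the identity.
#' @export
deconvolution_matrix <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(3L, 3L))) stop("stain matrix must be 3x3")
  if (any(abs(sqrt(rowSums(m^2)) - 1) > 1e-9))
    stop("stain matrix rows must be unit length; see normalize_stain_vectors()")
  d <- tryCatch(solve(m), error = function(e) {
    stop("stain matrix is singular and cannot be inverted (stains: ",
         paste(stain_names(m), collapse = ", "), ")", call. = FALSE)
  })
  dimnames(d) <- rev(dimnames(m))
  d
}

#' Separate stain contributions
#'
#' Applies the colour-deconvolution matrix per pixel, `C = D %*% y`, unmixing
#' the OD image into per-stain concentration maps.
#'
#' @param od `H x W x 3` optical-density array (see [rgb_to_od()]).
#' @param d 3x3 deconvolution matrix (see [deconvolution_matrix()]).
#' @return `H x W x 3` array of stain concentrations, third axis ordered as
#'   the rows of the stain matrix (hematoxylin, eosin, DAB by default).
#' @export
separate_stains <- function(od, d) {
  if (length(dim(od)) != 3L || dim(od)[3] != 3L)
    stop("`od` must be an H x W x 3 array")
  d <- as.matrix(d)
  if (!all(dim(d) == c(3L, 3L))) stop("`d` must be 3x3")
  dm <- dim(od)
  # forward model: y = c M (row vectors), so c = y M^-1 = y D
  y <- matrix(od, ncol = 3L)        # pixels x channels
  conc <- y %*% d                   # pixels x stains
  array(conc, dm)
}

#' Extract the hematoxylin channel
#'
#' Returns the hematoxylin concentration map rescaled to `[0, 1]` by min-max
#' over the image; a constant map rescales to all zeros. This grayscale map
#' is the working surface for all downstream stages (nuclei appear bright).
#'
#' @param conc `H x W x 3` concentration array from [separate_stains()].
#' @param channel index of the hematoxylin channel (default 1).
#' @return `H x W` matrix in `[0, 1]`.
#' @export
hematoxylin_channel <- function(conc, channel = 1L) {
  if (length(dim(conc)) != 3L) stop("`conc` must be an H x W x 3 array")
  h <- conc[, , channel]
  rng <- range(h)
  if (rng[2] - rng[1] <= 0) return(array(0, dim(h)))
  (h - rng[1]) / (rng[2] - rng[1])
}
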