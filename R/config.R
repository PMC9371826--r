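config_defaults <- function() {
  list(
    stains = list(matrix = as.vector(t(he_dab_stain_matrix()))),
    gaussian = list(sigma = 1.0, radius = NULL),
    bilateral = list(sigma_spatial = 2.0, sigma_range = 0.1, radius = NULL),
    morphology = list(nucleus_radius = 8L, se_radius = NULL),
    frst = list(radii = NULL, alpha = 2, gradient_threshold = 0.05,
                polarity = "dark", source = "prepared"),
    markers = list(rel_threshold = 0.3, min_distance = NULL, stamp_radius = 2L,
                   min_contrast = 0.1),
    watershed = list(surface = "gradient", connectivity = 4L),
    seed = 1L
  )
}

known_keys <- function() {
  d <- config_defaults()
  unlist(lapply(names(d), function(g) {
    if (is.list(d[[g]])) paste(g, names(d[[g]]), sep = ".") else g
  }))
}

#' Pipeline configuration
#'
#' Builds the full parameter set of the segmentation pipeline, with defaults
#' for everything not supplied. Parameters are grouped (`gaussian`,
#' `bilateral`, `morphology`, `frst`, `markers`, `watershed`, `stains`) and
#' set by dotted names, e.g. `nucseg_config("morphology.nucleus_radius" = 10)`.
#' Unknown keys are rejected with a suggestion for the nearest known key.
#'
#' Derived defaults (filled in when left `NULL`): filter radii are
#' `ceiling(3 * sigma)`; the reconstruction structuring-element radius is
#' `round(nucleus_radius / 2)`; FRST radii are `nucleus_radius + c(-2, 0, 2)`;
#' the marker exclusion distance is `nucleus_radius`.
#'
#' @param ... dotted `key = value` overrides.
#' @return A `nucseg_config` object (a named list of parameter groups).
#' @export
#' @examples
#' cfg <- nucseg_config("gaussian.sigma" = 1.5)
#' cfg$gaussian$sigma
nucseg_config <- function(...) {
  over <- list(...)
  cfg <- config_defaults()
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all configuration overrides must be named")
    for (key in names(over)) cfg <- set_config_key(cfg, key, over[[key]])
  }
  validate_config(cfg)
}

set_config_key <- function(cfg, key, value) {
  known <- known_keys()
  if (!key %in% known) {
    # match leniently: ignore separator style and group/name order, so
    # e.g. "sigma_gauss" still points at "gaussian.sigma"
    norm <- gsub("[._]", ".", key)
    dist_to <- function(cand) {
      parts <- strsplit(cand, ".", fixed = TRUE)[[1]]
      forms <- c(cand, paste(rev(parts), collapse = "."))
      min(utils::adist(norm, forms, partial = TRUE))
    }
    near <- known[which.min(vapply(known, dist_to, numeric(1)))]
    stop(sprintf("unknown configuration key \"%s\"; did you mean \"%s\"?",
                 key, near))
  }
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1L) cfg[[parts]] <- value
  else cfg[[parts[1]]][[parts[2]]] <- value
  cfg
}

validate_config <- function(cfg) {
  num1 <- function(x, key, lo = -Inf) {
    if (is.null(x)) return(invisible(NULL))
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= lo)
      stop(sprintf("configuration key \"%s\" must be a single number > %s", key, lo))
  }
  sm <- cfg$stains$matrix
  if (!is.numeric(sm) || length(sm) != 9L)
    stop("stains.matrix must hold nine numbers, row-major, rows = stains (H, E, DAB)")
  num1(cfg$gaussian$sigma, "gaussian.sigma", 0)
  num1(cfg$gaussian$radius, "gaussian.radius", 0)
  num1(cfg$bilateral$sigma_spatial, "bilateral.sigma_spatial", 0)
  num1(cfg$bilateral$sigma_range, "bilateral.sigma_range", 0)
  num1(cfg$bilateral$radius, "bilateral.radius", 0)
  num1(cfg$morphology$nucleus_radius, "morphology.nucleus_radius", 0)
  num1(cfg$morphology$se_radius, "morphology.se_radius", 0)
  if (!is.null(cfg$frst$radii) &&
      (!is.numeric(cfg$frst$radii) || any(cfg$frst$radii < 1)))
    stop("frst.radii must be integers >= 1")
  num1(cfg$frst$alpha, "frst.alpha", 0)
  if (!is.numeric(cfg$frst$gradient_threshold) ||
      cfg$frst$gradient_threshold < 0 || cfg$frst$gradient_threshold >= 1)
    stop("frst.gradient_threshold must be in [0, 1)")
  if (!cfg$frst$polarity %in% c("dark", "bright", "both"))
    stop("frst.polarity must be one of dark, bright, both")
  if (!cfg$frst$source %in% c("prepared", "denoised"))
    stop("frst.source must be \"prepared\" or \"denoised\"")
  if (!is.numeric(cfg$markers$rel_threshold) ||
      cfg$markers$rel_threshold <= 0 || cfg$markers$rel_threshold > 1)
    stop("markers.rel_threshold must be in (0, 1]")
  num1(cfg$markers$min_distance, "markers.min_distance", 0)
  num1(cfg$markers$min_contrast, "markers.min_contrast", -1)
  num1(cfg$markers$stamp_radius, "markers.stamp_radius", -1)
  if (!cfg$watershed$surface %in% c("gradient", "inverted_intensity"))
    stop("watershed.surface must be \"gradient\" or \"inverted_intensity\"")
  if (!cfg$watershed$connectivity %in% c(4L, 8L))
    stop("watershed.connectivity must be 4 or 8")
  num1(cfg$seed, "seed", -Inf)
  structure(cfg, class = "nucseg_config")
}

# fill the NULL-able derived defaults in one place
resolve_config <- function(cfg) {
  nr <- as.integer(round(cfg$morphology$nucleus_radius))
  if (is.null(cfg$gaussian$radius))
    cfg$gaussian$radius <- ceiling(3 * cfg$gaussian$sigma)
  if (is.null(cfg$bilateral$radius))
    cfg$bilateral$radius <- ceiling(3 * cfg$bilateral$sigma_spatial)
  if (is.null(cfg$morphology$se_radius))
    cfg$morphology$se_radius <- max(1L, as.integer(round(nr / 2)))
  if (is.null(cfg$frst$radii))
    cfg$frst$radii <- pmax(1L, nr + c(-2L, 0L, 2L))
  if (is.null(cfg$markers$min_distance))
    cfg$markers$min_distance <- nr
  cfg
}

#' @export
print.nucseg_config <- function(x, ...) {
  cat("nucseg pipeline configuration\n")
  r <- resolve_config(x)
  for (g in setdiff(names(r), "stains")) {
    if (is.list(r[[g]])) {
      vals <- vapply(r[[g]], function(v) paste(format(v), collapse = " "), "")
      cat(sprintf("  %s: %s\n", g,
                  paste(sprintf("%s = %s", names(vals), vals), collapse = ", ")))
    } else cat(sprintf("  %s = %s\n", g, format(r[[g]])))
  }
  m <- matrix(x$stains$matrix, 3, byrow = TRUE)
  cat("  stains (rows H, E, DAB):\n")
  for (i in 1:3) cat("   ", paste(format(m[i, ], digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Read and write pipeline configuration files
#'
#' Configuration files are YAML with the same grouped keys as
#' [nucseg_config()] (e.g. a `gaussian:` block with a `sigma:` entry). An
#' empty file yields the all-defaults configuration; unknown keys are an
#' error naming the nearest known key, so typos fail closed.
#'
#' @param path file path.
#' @return `load_config()` returns a `nucseg_config`; `save_config()`
#'   (invisibly) returns `path`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  cfg <- config_defaults()
  for (g in names(raw)) {
    if (!is.list(raw[[g]]) || !g %in% names(cfg)) {
      key <- g
      cfg <- set_config_key(cfg, key, raw[[g]])
    } else {
      for (k in names(raw[[g]]))
        cfg <- set_config_key(cfg, paste(g, k, sep = "."), raw[[g]][[k]])
    }
  }
  validate_config(cfg)
}

#' @rdname load_config
#' @param config a `nucseg_config` object.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "nucseg_config"))
  out <- unclass(config)
  # drop unresolved NULLs so the file round-trips through the defaults
  out <- lapply(out, function(g) if (is.list(g)) Filter(Negate(is.null), g) else g)
  yaml::write_yaml(out, path)
  invisible(path)
}
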