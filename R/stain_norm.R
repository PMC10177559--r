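#' RGB image container
#'
#' A thin wrapper around an `H x W x 3` numeric array of 8-bit intensities
#' (0--255) that records the pixel size in micrometres.  Most functions in
#' the package accept either a plain array or an `rgb_image`.
#'
#' @param pixels `H x W x 3` array with values in `[0, 255]`.
#' @param um_per_px micrometres per pixel (default 0.25, i.e. roughly x40
#'   magnification).
#' @return An object of class `rgb_image`.
#' @export
rgb_image <- function(pixels, um_per_px = 0.25) {
  pixels <- as_pixel_array(pixels)
  structure(list(pixels = pixels, um_per_px = um_per_px),
            class = "rgb_image")
}

as_pixel_array <- function(x) {
  if (inherits(x, "rgb_image")) return(x$pixels)
  x <- unclass(x)
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  stopifnot(is.array(x), length(dim(x)) == 3L, dim(x)[3] == 3L)
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("pixel values must be finite and in [0, 255]")
  x
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d px, %.3g um/px\n", d[1], d[2], x$um_per_px))
  invisible(x)
}

#' Stain basis matrix
#'
#' Constructs and validates a 3 x 2 optical-density stain basis.  Column 1
#' is the hematoxylin-like stain, column 2 the eosin-like stain.  Columns
#' are normalised to unit length; entries must be nonnegative and the
#' columns must span an angle of more than 1 degree.
#'
#' @param columns 3 x 2 numeric matrix (or 6 values, column-major).
#' @return A validated unit-column 3 x 2 matrix of class `stain_matrix`.
#' @export
stain_matrix <- function(columns) {
  m <- matrix(as.numeric(columns), nrow = 3, ncol = 2)
  if (anyNA(m) || any(!is.finite(m)) || any(m < 0))
    stop("stain matrix entries must be finite and nonnegative")
  norms <- sqrt(colSums(m^2))
  if (any(norms == 0)) stop("stain matrix has a zero column")
  m <- sweep(m, 2, norms, "/")
  ang <- vector_angle_deg(m[, 1], m[, 2])
  if (ang <= 1)
    stop(sprintf("stain columns are collinear (angle %.3f deg <= 1 deg)", ang))
  structure(m, class = c("stain_matrix", "matrix", "array"))
}

vector_angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Default target stain basis and concentration reference
#'
#' The reference H&E basis shipped with the package (the widely used
#' Macenko-style defaults), together with the 99th-percentile concentration
#' scale that [normalise_stains()] maps source concentrations onto.  Both
#' can be overridden per call.
#'
#' @return `default_target_stain()`: a `stain_matrix`;
#'   `default_concentration_reference()`: length-2 numeric.
#' @export
default_target_stain <- function() {
  stain_matrix(c(0.5626, 0.7201, 0.4062,
                 0.2159, 0.8012, 0.5581))
}

#' @rdname default_target_stain
#' @details The concentration reference is the widely used (1.9705,
#'   1.0308) natural-log scale re-expressed in this package's log10
#'   optical-density units (divided by `ln 10`).
#' @export
default_concentration_reference <- function() c(1.9705, 1.0308) / log(10)

#' Convert intensities to optical density
#'
#' `OD = -log10(I / background)`, channel-wise.  Intensities below 1 are
#' clamped to 1 before the logarithm so zero pixels stay finite.
#'
#' @param image `rgb_image` or `H x W x 3` array.
#' @param background background (white) intensity, > 0.
#' @return `H x W x 3` array of nonnegative optical densities.
#' @export
to_optical_density <- function(image, background = 255) {
  stopifnot(background > 0)
  px <- as_pixel_array(image)
  px <- pmax(px, 1)
  -log10(px / background)
}

#' Invert [to_optical_density()]
#'
#' @param od array of optical densities.
#' @inheritParams to_optical_density
#' @return 8-bit intensity array (rounded, clamped to `[0, 255]`).
#' @export
od_to_intensity <- function(od, background = 255) {
  pmin(pmax(round(background * 10^(-od)), 0), 255)
}

#' Estimate the stain basis of an image (Macenko procedure)
#'
#' Projects the optical-density cloud of tissue pixels onto its top two
#' singular directions and takes the extreme-angle percentiles of the
#' projected directions as the two stain vectors.  The construction
#' leaves the column order ambiguous; by package convention the
#' hematoxylin-like column -- the one with the larger red-channel optical
#' density (hematoxylin looks blue because it absorbs red) -- is returned
#' first.
#'
#' @inheritParams to_optical_density
#' @param od_threshold tissue pixels are those whose OD vector has
#'   Euclidean norm above this (default 0.15).
#' @param angle_percentile alpha for the extreme angles: the
#'   `alpha`-th and `(100 - alpha)`-th percentiles of the projected angle
#'   distribution (default 1).
#' @return A `stain_matrix`.
#' @export
estimate_stain_matrix <- function(image, od_threshold = 0.15,
                                  angle_percentile = 1, background = 255) {
  od <- to_optical_density(image, background)
  odm <- matrix(od, ncol = 3)
  keep <- sqrt(rowSums(odm^2)) > od_threshold
  n_tissue <- sum(keep)
  if (n_tissue < 100)
    stop(sprintf("stain estimation needs >= 100 tissue pixels, found %d",
                 n_tissue))
  odt <- odm[keep, , drop = FALSE]
  sv <- svd(odt, nu = 0, nv = 2)
  v <- sv$v
  # orient the plane so projections fall in a half-plane with positive x
  proj <- odt %*% v
  if (sum(proj[, 1]) < 0) { v[, 1] <- -v[, 1]; proj[, 1] <- -proj[, 1] }
  phi <- atan2(proj[, 2], proj[, 1])
  a <- angle_percentile / 100
  lo <- stats::quantile(phi, a, names = FALSE)
  hi <- stats::quantile(phi, 1 - a, names = FALSE)
  c1 <- as.vector(v %*% c(cos(lo), sin(lo)))
  c2 <- as.vector(v %*% c(cos(hi), sin(hi)))
  fix <- function(u) {
    if (sum(u) < 0) u <- -u
    u <- pmax(u, 0)
    if (all(u == 0)) stop("degenerate stain direction (all-nonpositive)")
    u / sqrt(sum(u^2))
  }
  c1 <- fix(c1); c2 <- fix(c2)
  if (vector_angle_deg(c1, c2) <= 1)
    stop(sprintf(
      "degenerate stain basis: recovered columns are collinear (%.3f deg); the image may contain a single stain",
      vector_angle_deg(c1, c2)))
  # hematoxylin-like column first: hematoxylin transmits blue and absorbs
  # red, so it is the column with the larger red-channel OD
  cols <- if (c1[1] >= c2[1]) cbind(c1, c2) else cbind(c2, c1)
  stain_matrix(cols)
}

#' Solve per-pixel stain concentrations by least squares
#'
#' @param od `n x 3` matrix (or `H x W x 3` array) of optical densities.
#' @param stains a `stain_matrix`.
#' @return `n x 2` nonnegative concentration matrix.
#' @export
stain_concentrations <- function(od, stains) {
  odm <- matrix(od, ncol = 3)
  s <- unclass(stains)
  conc <- odm %*% s %*% solve(crossprod(s))
  pmax(conc, 0)
}

#' Normalise an image to a target stain basis
#'
#' Estimates the source stain basis (unless supplied), solves per-pixel
#' stain concentrations, rescales each stain's concentrations so that
#' their `concentration_percentile`-th percentile over tissue pixels
#' matches the target reference scale, and reconstructs the image in the
#' target basis.  Images with fewer than 100 tissue pixels (e.g. pure
#' background) are passed through unchanged.
#'
#' @inheritParams estimate_stain_matrix
#' @param target target `stain_matrix` (default [default_target_stain()]).
#' @param concentration_percentile percentile used for the concentration
#'   rescale (default 99).
#' @param reference length-2 target concentration scale
#'   (default [default_concentration_reference()]).
#' @param source_matrix optional pre-estimated source `stain_matrix`;
#'   when `NULL` it is estimated from `image`.
#' @return Normalised image, same class and dimensions as the input.
#' @export
normalise_stains <- function(image, target = default_target_stain(),
                             concentration_percentile = 99,
                             reference = default_concentration_reference(),
                             source_matrix = NULL,
                             od_threshold = 0.15, angle_percentile = 1,
                             background = 255) {
  px <- as_pixel_array(image)
  od <- to_optical_density(px, background)
  odm <- matrix(od, ncol = 3)
  tissue <- sqrt(rowSums(odm^2)) > od_threshold
  if (sum(tissue) < 100) {
    message("fewer than 100 tissue pixels; passing image through unchanged")
    return(image)
  }
  src <- source_matrix %||%
    estimate_stain_matrix(px, od_threshold, angle_percentile, background)
  conc <- stain_concentrations(odm, src)
  p <- apply(conc[tissue, , drop = FALSE], 2, stats::quantile,
             probs = concentration_percentile / 100, names = FALSE)
  scale <- ifelse(p > 0, reference / p, 1)
  conc <- sweep(conc, 2, scale, "*")
  out_od <- conc %*% t(unclass(target))
  out <- od_to_intensity(array(out_od, dim = dim(px)), background)
  if (inherits(image, "rgb_image")) rgb_image(out, image$um_per_px) else out
}
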