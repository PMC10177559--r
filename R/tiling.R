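#' Tissue mask by saturation thresholding
#'
#' Deterministic surrogate for interactive tissue masking: pixels are
#' called tissue when their HSV saturation is at or above
#' `saturation_threshold` (stained tissue is colourful, background glass
#' is grey/white).  The raw mask is then cleaned by morphological opening
#' and closing, true components smaller than `min_area` pixels are
#' removed, and enclosed holes smaller than `min_area` are filled.
#' Degenerate all-true / all-false masks are returned as-is (so a
#' threshold of 0 yields an all-true mask).
#'
#' @param image [rgb_image()] or `H x W x 3` array.
#' @param saturation_threshold HSV saturation cut-off in `[0, 1]`
#'   (default 0.07).
#' @param min_area minimum component/hole area in pixels (default 64).
#' @param brush_size diameter of the disc structuring element (odd,
#'   default 5).
#' @return Logical `H x W` matrix.
#' @export
tissue_mask <- function(image, saturation_threshold = 0.07,
                        min_area = 64, brush_size = 5) {
  px <- as_pixel_array(image)
  d <- dim(px)
  rgb <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
               as.vector(px[, , 3]))
  sat <- grDevices::rgb2hsv(rgb, maxColorValue = 255)[2, ]
  mask <- matrix(sat >= saturation_threshold, d[1], d[2])
  if (all(mask) || !any(mask)) return(mask)
  if (min(d[1:2]) > brush_size) {
    kern <- EBImage::makeBrush(brush_size, shape = "disc")
    m <- EBImage::closing(EBImage::opening(mask * 1, kern), kern)
    mask <- m > 0.5
  }
  mask <- drop_small_components(mask, min_area)
  fill_small_holes(mask, min_area)
}

drop_small_components <- function(mask, min_area) {
  if (!any(mask)) return(mask)
  lab <- EBImage::bwlabel(mask * 1)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

fill_small_holes <- function(mask, min_area) {
  if (all(mask)) return(mask)
  lab <- EBImage::bwlabel((!mask) * 1)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0])
  fill <- setdiff(which(sizes < min_area), border)
  if (length(fill)) mask[matrix(lab %in% fill, nrow(mask))] <- TRUE
  mask
}

#' Annotation set
#'
#' A list of polygons in 0-based pixel coordinates (x rightwards, y
#' downwards).  Each polygon is a list of closed vertex rings: the first
#' ring is the outer boundary, subsequent rings are holes (even-odd rule).
#'
#' @param polygons list of polygons; each polygon a list of `m x 2`
#'   coordinate matrices (`m >= 3` distinct vertices per ring).
#' @param labels optional class label per polygon.
#' @return Object of class `annotation_set`.
#' @export
annotation_set <- function(polygons, labels = rep(NA_character_,
                                                  length(polygons))) {
  stopifnot(length(labels) == length(polygons))
  polygons <- lapply(polygons, function(poly) {
    lapply(poly, function(ring) {
      ring <- as.matrix(ring)
      stopifnot(ncol(ring) == 2)
      # drop an explicit closing vertex; rings are implicitly closed
      if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
        ring <- ring[-nrow(ring), , drop = FALSE]
      if (nrow(ring) < 3) stop("annotation ring has fewer than 3 vertices")
      ring
    })
  })
  structure(list(polygons = polygons, labels = as.character(labels)),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d polygon(s)\n", length(x$polygons)))
  invisible(x)
}

#' Load QuPath-style GeoJSON annotations
#'
#' Parses a GeoJSON `FeatureCollection` of `Polygon` / `MultiPolygon`
#' geometries (the format QuPath exports).  MultiPolygons are split into
#' one polygon per part; interior rings (holes) are preserved.  An empty
#' collection yields an empty set with a warning; an unknown geometry type
#' is a format error naming the offending feature index.
#'
#' @param path path to a GeoJSON file.
#' @return An [annotation_set()].
#' @export
load_annotation <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(gj$type, "FeatureCollection"))
    stop("expected a GeoJSON FeatureCollection, found type '", gj$type, "'")
  feats <- gj$features %||% list()
  if (length(feats) == 0) {
    warning("empty FeatureCollection: no annotations loaded")
    return(annotation_set(list(), character(0)))
  }
  polygons <- list(); labels <- character(0)
  ring_to_matrix <- function(r)
    do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
  for (i in seq_along(feats)) {
    geom <- feats[[i]]$geometry
    lab <- feats[[i]]$properties$classification$name %||%
      feats[[i]]$properties$name %||% NA_character_
    if (identical(geom$type, "Polygon")) {
      polygons <- c(polygons, list(lapply(geom$coordinates, ring_to_matrix)))
      labels <- c(labels, lab)
    } else if (identical(geom$type, "MultiPolygon")) {
      for (part in geom$coordinates) {
        polygons <- c(polygons, list(lapply(part, ring_to_matrix)))
        labels <- c(labels, lab)
      }
    } else {
      stop(sprintf("feature %d has unsupported geometry type '%s'",
                   i, geom$type %||% "NULL"))
    }
  }
  annotation_set(polygons, labels)
}

# Even-odd point-in-polygon test, vectorised over points.
# pts: n x 2 matrix; ring: m x 2 matrix of vertices (implicitly closed).
points_in_ring <- function(pts, ring) {
  n <- nrow(pts); m <- nrow(ring)
  inside <- rep(FALSE, n)
  px <- pts[, 1]; py <- pts[, 2]
  j <- m
  for (i in seq_len(m)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

points_in_polygon <- function(pts, polygon) {
  inside <- rep(FALSE, nrow(pts))
  for (ring in polygon) inside <- xor(inside, points_in_ring(pts, ring))
  inside
}

#' Rasterize annotations to a pixel membership mask
#'
#' A pixel belongs to the annotation when its centre `(x + 0.5, y + 0.5)`
#' (0-based coordinates) lies inside some polygon under the even-odd rule
#' (holes excluded).
#'
#' @param annotations an [annotation_set()].
#' @param width,height image dimensions in pixels.
#' @return Logical `height x width` matrix.
#' @export
rasterize_annotations <- function(annotations, width, height) {
  mask <- matrix(FALSE, height, width)
  if (length(annotations$polygons) == 0) return(mask)
  xs <- rep(seq_len(width) - 0.5, each = height)
  ys <- rep(seq_len(height) - 0.5, times = width)
  pts <- cbind(xs, ys)
  inside <- rep(FALSE, nrow(pts))
  for (poly in annotations$polygons)
    inside <- inside | points_in_polygon(pts, poly)
  matrix(inside, height, width)
}

#' Patch set
#'
#' The non-overlapping fixed-size patches extracted from one image, with
#' their 0-based top-left origins (x = column, rightwards; y = row,
#' downwards).
#'
#' @param patient_id patient identifier.
#' @param patches list of `s x s x 3` arrays.
#' @param origins integer matrix with columns `x`, `y`.
#' @param patch_size side length in pixels.
#' @return Object of class `patch_set`.
#' @export
patch_set <- function(patient_id, patches, origins,
                      patch_size = 224L) {
  origins <- matrix(as.integer(origins), ncol = 2,
                    dimnames = list(NULL, c("x", "y")))
  stopifnot(length(patches) == nrow(origins))
  if (anyDuplicated(origins)) stop("duplicate patch origins")
  structure(list(patient_id = as.character(patient_id), patches = patches,
                 origins = origins, patch_size = as.integer(patch_size)),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %s: %d patch(es) of %d px\n",
              x$patient_id, length(x$patches), x$patch_size))
  invisible(x)
}

#' Extract non-overlapping annotated tissue patches
#'
#' Tiles the image with a stride-`patch_size` grid anchored at the
#' top-left corner of the annotation bounding box (at the image origin
#' when no annotations are given) and keeps a patch iff the fraction of
#' its pixels that are simultaneously inside some annotation polygon and
#' tissue-masked is at least `coverage_fraction`.  Residual border strips
#' narrower than a full patch are discarded; there is no padding.
#'
#' @param image [rgb_image()] or array, at the working resolution.
#' @param mask logical tissue mask from [tissue_mask()] (same dimensions).
#' @param annotations an [annotation_set()], or `NULL` to treat the whole
#'   image as annotated.
#' @param patch_size patch side in pixels (default 224).
#' @param coverage_fraction minimum in-annotation tissue fraction
#'   (default 0.5).
#' @param patient_id identifier recorded on the output.
#' @return A [patch_set()]; empty (with a warning) when the image is
#'   smaller than one patch.
#' @export
extract_patches <- function(image, mask = NULL, annotations = NULL,
                            patch_size = 224, coverage_fraction = 0.5,
                            patient_id = "unknown") {
  px <- as_pixel_array(image)
  h <- dim(px)[1]; w <- dim(px)[2]
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  stopifnot(identical(dim(mask), c(h, w)))
  if (patch_size > h || patch_size > w) {
    warning("image smaller than one patch; returning an empty patch set")
    return(patch_set(patient_id, list(),
                     matrix(integer(0), 0, 2), patch_size))
  }
  if (is.null(annotations)) {
    ann_mask <- matrix(TRUE, h, w)
    x0 <- 0L; y0 <- 0L
  } else {
    stopifnot(inherits(annotations, "annotation_set"))
    ann_mask <- rasterize_annotations(annotations, w, h)
    verts <- do.call(rbind, unlist(annotations$polygons, recursive = FALSE))
    if (is.null(verts)) {
      warning("no annotation polygons; returning an empty patch set")
      return(patch_set(patient_id, list(),
                       matrix(integer(0), 0, 2), patch_size))
    }
    x0 <- max(0L, as.integer(floor(min(verts[, 1]))))
    y0 <- max(0L, as.integer(floor(min(verts[, 2]))))
  }
  keepable <- ann_mask & mask
  patches <- list(); origins <- NULL
  for (oy in seq(y0, h - patch_size, by = patch_size)) {
    for (ox in seq(x0, w - patch_size, by = patch_size)) {
      rows <- (oy + 1):(oy + patch_size)
      cols <- (ox + 1):(ox + patch_size)
      frac <- mean(keepable[rows, cols])
      if (frac >= coverage_fraction) {
        patches <- c(patches, list(px[rows, cols, , drop = FALSE]))
        origins <- rbind(origins, c(ox, oy))
      }
    }
  }
  if (is.null(origins)) origins <- matrix(integer(0), 0, 2)
  patch_set(patient_id, patches, origins, patch_size)
}

#' Resample an image to a target resolution
#'
#' Bilinear resize to the requested micrometres-per-pixel scale.  The
#' image must carry its resolution (an `rgb_image`) or `um_per_px` must be
#' given.
#'
#' @param image [rgb_image()] (or array plus `um_per_px`).
#' @param target_um_per_px target scale (default 0.25).
#' @param um_per_px source scale, required for bare arrays.
#' @return [rgb_image()] at the target scale.
#' @export
resample_to <- function(image, target_um_per_px = 0.25, um_per_px = NULL) {
  if (inherits(image, "rgb_image")) um_per_px <- image$um_per_px
  if (is.null(um_per_px))
    stop("source um_per_px must be provided or carried by the image")
  px <- as_pixel_array(image)
  f <- um_per_px / target_um_per_px
  if (abs(f - 1) < 1e-9) return(rgb_image(px, target_um_per_px))
  d <- dim(px)
  out <- EBImage::resize(px / 255, w = round(d[1] * f), h = round(d[2] * f))
  rgb_image(pmin(pmax(round(out * 255), 0), 255), target_um_per_px)
}
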