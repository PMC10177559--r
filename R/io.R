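#' Read and write 8-bit PNG images
#'
#' Thin wrappers over the png package keeping the package's 0--255
#' integer convention and `um_per_px` bookkeeping.
#'
#' @param path file path.
#' @param image [rgb_image()] or array.
#' @param um_per_px resolution recorded on the loaded image.
#' @return `read_image_png()`: an [rgb_image()].
#' @export
read_image_png <- function(path, um_per_px = 0.25) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
  rgb_image(round(a * 255), um_per_px)
}

#' @rdname read_image_png
#' @details `read_image_tiff()` reads single-plane or multi-page TIFF
#'   (the first — highest-resolution — page of a pyramidal file) and
#'   needs the suggested tiff package.
#' @export
read_image_tiff <- function(path, um_per_px = 0.25) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF requires the 'tiff' package")
  a <- tiff::readTIFF(path, all = TRUE)[[1]]
  if (length(dim(a)) == 2) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] == 4) a <- a[, , 1:3, drop = FALSE]
  rgb_image(round(a * 255), um_per_px)
}

#' @rdname read_image_png
#' @export
write_image_png <- function(image, path) {
  px <- as_pixel_array(image)
  png::writePNG(px / 255, path)
  invisible(path)
}

#' Write / read a patch set as PNG files plus a TSV manifest
#'
#' Patches are written as `{patient}_{x}_{y}.png` and listed in
#' `manifest.tsv` with columns `patient_id`, `x`, `y`, `path`.
#'
#' @param patches a [patch_set()].
#' @param dir output directory.
#' @return `write_patches()`: the manifest path; `read_patches()`: a
#'   [patch_set()].
#' @export
write_patches <- function(patches, dir) {
  stopifnot(inherits(patches, "patch_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(patches$patches))
  for (i in seq_along(patches$patches)) {
    o <- patches$origins[i, ]
    paths[i] <- file.path(dir, sprintf("%s_%d_%d.png",
                                       patches$patient_id, o[1], o[2]))
    write_image_png(patches$patches[[i]], paths[i])
  }
  manifest <- data.frame(patient_id = patches$patient_id,
                         x = patches$origins[, 1],
                         y = patches$origins[, 2],
                         path = basename(paths))
  mp <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mp)
}

#' @rdname write_patches
#' @export
read_patches <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "manifest.tsv"),
                                stringsAsFactors = FALSE)
  pats <- unique(manifest$patient_id)
  stopifnot(length(pats) == 1)
  imgs <- lapply(file.path(dir, manifest$path), function(p)
    as_pixel_array(read_image_png(p)))
  patch_set(pats, imgs, as.matrix(manifest[, c("x", "y")]),
            patch_size = dim(imgs[[1]])[1])
}

#' Plain-text feature store
#'
#' Feature tensors are stored one TSV per patient
#' (`features/{id}.tsv`, N rows x F columns) plus a `store.tsv` manifest
#' recording patient id, patch count, feature dimension and backbone.
#'
#' @param features list of [feature_tensor()] objects.
#' @param dir store directory.
#' @return `write_feature_store()`: `dir`, invisibly;
#'   `read_feature_store()`: list of [feature_tensor()].
#' @export
write_feature_store <- function(features, dir) {
  stopifnot(all(vapply(features, inherits, TRUE, "feature_tensor")))
  dir.create(file.path(dir, "features"), showWarnings = FALSE,
             recursive = TRUE)
  manifest <- do.call(rbind, lapply(features, function(f) {
    path <- file.path(dir, "features", paste0(f$patient_id, ".tsv"))
    utils::write.table(f$values, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    data.frame(patient_id = f$patient_id, n_patches = nrow(f$values),
               n_features = ncol(f$values), backbone_id = f$backbone_id)
  }))
  utils::write.table(manifest, file.path(dir, "store.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_feature_store
#' @export
read_feature_store <- function(dir) {
  manifest <- utils::read.delim(file.path(dir, "store.tsv"),
                                stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    m <- as.matrix(utils::read.delim(
      file.path(dir, "features", paste0(manifest$patient_id[i], ".tsv")),
      header = FALSE))
    dimnames(m) <- NULL
    feature_tensor(manifest$patient_id[i], m, manifest$backbone_id[i])
  })
}

#' Read / write clinical tables as TSV
#'
#' @param table a `clinical_table` data frame.
#' @param path file path.
#' @return `read_clinical_tsv()`: a `clinical_table`.
#' @export
write_clinical_tsv <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical_tsv
#' @export
read_clinical_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "followup_time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("clinical table lacks columns: ", paste(miss, collapse = ", "))
  class(df) <- c("clinical_table", "data.frame")
  df
}
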