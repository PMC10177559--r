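#' Patch-level feature tensor
#'
#' Container for the `N x F` matrix of patch features of one patient
#' (`N` patches, `F` features per patch), tagged with the backbone that
#' produced it.
#'
#' @param patient_id patient identifier.
#' @param values `N x F` numeric matrix, all finite, `N >= 1`, `F >= 1`.
#' @param backbone_id identifier of the producing backbone.
#' @return Object of class `feature_tensor`.
#' @export
feature_tensor <- function(patient_id, values, backbone_id = "unknown") {
  values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 1 || any(!is.finite(values)))
    stop("feature tensor must be a finite N x F matrix with N, F >= 1")
  structure(list(patient_id = as.character(patient_id), values = values,
                 backbone_id = backbone_id),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat(sprintf("<feature_tensor> %s: %d patches x %d features [%s]\n",
              x$patient_id, nrow(x$values), ncol(x$values), x$backbone_id))
  invisible(x)
}

# ---- backbone registry ------------------------------------------------

.backbones <- new.env(parent = emptyenv())

#' Register a feature-extraction backbone
#'
#' A backbone is a function mapping one `224 x 224 x 3` patch array to a
#' length-`F` numeric feature vector.  The package ships a deterministic
#' `"toy"` backbone (see [toy_backbone_features()]); the five conventional
#' pretrained architectures are registered as named slots so that users
#' with a deep-learning runtime can attach real extractors via this
#' function.
#'
#' @param id backbone identifier.
#' @param fn function(patch) -> numeric vector, or `NULL` to register a
#'   placeholder slot without an implementation.
#' @param description short free-text description.
#' @export
register_backbone <- function(id, fn, description = "") {
  stopifnot(is.character(id), length(id) == 1)
  assign(id, list(fn = fn, description = description), envir = .backbones)
  invisible(id)
}

#' @rdname register_backbone
#' @export
list_backbones <- function() sort(ls(.backbones))

get_backbone <- function(id) {
  if (!exists(id, envir = .backbones))
    stop(sprintf("unknown backbone '%s'; registered ids: %s",
                 id, paste(list_backbones(), collapse = ", ")))
  b <- get(id, envir = .backbones)
  if (is.null(b$fn))
    stop(sprintf(
      "backbone '%s' is a placeholder slot with no feature function attached; use register_backbone() to plug one in, or use 'toy'",
      id))
  b$fn
}

#' Deterministic toy backbone
#'
#' A download-free stand-in for a pretrained network, used throughout the
#' test fixtures: the patch is converted to grey (channel mean), block-mean
#' downsampled to 16 x 16, scaled to `[0, 1]`, flattened column-major, and
#' projected by a fixed seeded random matrix to `F = 64` features.  The
#' projection matrix is a function of a hard-coded seed only, so the
#' backbone is a documented closed-form map.
#'
#' @param patch `H x W x 3` array (H and W divisible by 16).
#' @param n_features output dimension (default 64).
#' @return Numeric feature vector.
#' @export
toy_backbone_features <- function(patch, n_features = 64) {
  px <- as_pixel_array(patch)
  d <- dim(px)
  if (d[1] %% 16 != 0 || d[2] %% 16 != 0)
    stop("toy backbone needs patch sides divisible by 16")
  grey <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  by <- d[1] / 16; bx <- d[2] / 16
  small <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16)
    small[i, j] <- mean(grey[((i - 1) * by + 1):(i * by),
                             ((j - 1) * bx + 1):(j * bx)])
  v <- as.vector(small) / 255
  proj <- toy_projection(256L, as.integer(n_features))
  as.vector(v %*% proj)
}

toy_projection <- local({
  cache <- NULL
  function(d_in, d_out) {
    if (!is.null(cache) && all(dim(cache) == c(d_in, d_out))) return(cache)
    cache <<- with_seed(20230515L,
                        matrix(rnorm(d_in * d_out, sd = 1 / sqrt(d_in)),
                               d_in, d_out))
    cache
  }
})

local({
  register_backbone("toy", toy_backbone_features,
                    "seeded random projection of 16x16 grey downsample (F = 64)")
  for (id in c("efficientnet", "regnet", "densenet", "inception", "resnet"))
    register_backbone(id, NULL, "pretrained slot; attach an extractor with register_backbone()")
})

#' Extract patch-level features with a registered backbone
#'
#' @param patches a [patch_set()].
#' @param backbone backbone identifier (see [list_backbones()]).
#' @return A [feature_tensor()] with one row per patch, in patch order.
#' @export
extract_features <- function(patches, backbone = "toy") {
  stopifnot(inherits(patches, "patch_set"))
  fn <- get_backbone(backbone)
  if (length(patches$patches) == 0)
    stop("patch set is empty; nothing to extract")
  rows <- lapply(patches$patches, fn)
  f <- length(rows[[1]])
  values <- do.call(rbind, rows)
  stopifnot(ncol(values) == f)
  feature_tensor(patches$patient_id, values, backbone_id = backbone)
}

#' Aggregate a patch-feature tensor to one slide-level vector
#'
#' The slide-level representation is the arithmetic mean of the patch
#' feature vectors: `z[j] = (1/N) * sum_i x[i, j]`.  This is the step that
#' collapses the per-patch training problem to a per-patient one.
#'
#' @param features a [feature_tensor()] (or bare `N x F` matrix).
#' @return Object of class `aggregated_feature` with fields `patient_id`,
#'   `values` (length `F`), and `n_patches_used`.
#' @export
aggregate_features <- function(features) {
  if (is.matrix(features))
    features <- feature_tensor("unnamed", features)
  stopifnot(inherits(features, "feature_tensor"))
  x <- features$values
  if (nrow(x) < 1) stop("cannot aggregate an empty feature tensor")
  structure(list(patient_id = features$patient_id,
                 values = colMeans(x),
                 n_patches_used = nrow(x)),
            class = "aggregated_feature")
}

#' @export
print.aggregated_feature <- function(x, ...) {
  cat(sprintf("<aggregated_feature> %s: F = %d (from %d patches)\n",
              x$patient_id, length(x$values), x$n_patches_used))
  invisible(x)
}

#' Stack aggregated features into a patients x F matrix
#'
#' @param features list of [aggregate_features()] results, or a
#'   `synthetic_cohort` (whose tensors are aggregated first).
#' @return Numeric matrix with patient ids as row names.
#' @export
aggregate_cohort <- function(features) {
  if (inherits(features, "synthetic_cohort"))
    features <- lapply(features$features, aggregate_features)
  stopifnot(length(features) >= 1,
            all(vapply(features, inherits, TRUE, "aggregated_feature")))
  m <- do.call(rbind, lapply(features, function(a) a$values))
  rownames(m) <- vapply(features, function(a) a$patient_id, character(1))
  m
}
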