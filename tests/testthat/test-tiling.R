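test_that("tissue mask finds stained tissue and handles degenerate thresholds", {
  white <- rgb_image(array(255, c(50, 50, 3)))
  expect_false(any(tissue_mask(white)))
  expect_true(all(tissue_mask(white, saturation_threshold = 0)))
  d <- disc_image()
  m <- tissue_mask(d$image)
  expect_lt(abs(sum(m) - d$area) / d$area, 0.05)
})

test_that("GeoJSON annotation ingest handles polygons, multipolygons and errors", {
  path <- write_geojson(list(list(square_ring(0, 0, 448))))
  ann <- load_annotation(path)
  expect_length(ann$polygons, 1)
  ring <- ann$polygons[[1]][[1]]
  expect_equal(abs(sum(ring[, 1] * c(ring[-1, 2], ring[1, 2]) -
                         ring[, 2] * c(ring[-1, 1], ring[1, 1]))) / 2,
               448^2)  # shoelace area
  # MultiPolygon with two parts splits into two polygons
  mp <- write_geojson(list(list(square_ring(0, 0, 10)),
                           list(square_ring(20, 0, 10))))
  gj <- jsonlite::fromJSON(mp, simplifyVector = FALSE)
  merged <- list(type = "FeatureCollection", features = list(list(
    type = "Feature", properties = list(name = "tumour"),
    geometry = list(type = "MultiPolygon", coordinates = list(
      gj$features[[1]]$geometry$coordinates,
      gj$features[[2]]$geometry$coordinates)))))
  mp_path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(merged, mp_path, auto_unbox = TRUE, digits = NA)
  expect_length(load_annotation(mp_path)$polygons, 2)
  # empty collection warns, unknown geometry errors with the index
  empty <- tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = list()),
                       empty, auto_unbox = TRUE)
  expect_warning(a0 <- load_annotation(empty), "empty")
  expect_length(a0$polygons, 0)
  pt <- tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = list(
    list(type = "Feature", properties = NULL,
         geometry = list(type = "Point", coordinates = list(1, 2))))),
    pt, auto_unbox = TRUE)
  expect_error(load_annotation(pt), "feature 1.*Point")
})

test_that("patch extraction follows the stride-224 coverage rule", {
  img <- rgb_image(array(200, c(448, 448, 3)))
  full_mask <- matrix(TRUE, 448, 448)
  ann_all <- load_annotation(write_geojson(list(list(square_ring(0, 0, 448)))))
  ps <- extract_patches(img, full_mask, ann_all)
  expect_length(ps$patches, 4)
  expect_setequal(paste(ps$origins[, 1], ps$origins[, 2]),
                  c("0 0", "224 0", "0 224", "224 224"))
  expect_true(all(vapply(ps$patches, function(p)
    identical(dim(p), c(224L, 224L, 3L)), TRUE)))
  # left-half annotation at 50% coverage keeps the two left patches
  ann_half <- load_annotation(write_geojson(list(list(square_ring(0, 0, 224) *
    matrix(c(1, 2), 4, 2, byrow = TRUE)))))  # 224 wide x 448 tall
  ps2 <- extract_patches(img, full_mask, ann_half)
  expect_length(ps2$patches, 2)
  expect_true(all(ps2$origins[, 1] == 0))
  # all-false tissue mask gives no patches
  ps3 <- extract_patches(img, matrix(FALSE, 448, 448), ann_all)
  expect_length(ps3$patches, 0)
  # image smaller than one patch warns and yields an empty set
  expect_warning(
    ps4 <- extract_patches(rgb_image(array(200, c(100, 100, 3)))),
    "smaller")
  expect_length(ps4$patches, 0)
})

test_that("patch selection matches a brute-force scan and ignores ordering", {
  skip_if_not_installed("mgcv")
  set.seed(10)
  for (rep in 1:4) {
    h <- 96; w <- 96; s <- 32
    img <- rgb_image(array(sample(0:255, h * w * 3, TRUE), c(h, w, 3)))
    mask <- matrix(runif(h * w) < 0.7, h, w)
    # two random convex-ish quads
    polys <- lapply(1:2, function(i) {
      cx <- runif(1, 20, 76); cy <- runif(1, 20, 76)
      r <- runif(1, 12, 30)
      th <- sort(runif(5, 0, 2 * pi))
      list(cbind(cx + r * cos(th), cy + r * sin(th)))
    })
    ann <- load_annotation(write_geojson(polys))
    ps <- extract_patches(img, mask, ann, patch_size = s,
                          coverage_fraction = 0.3)
    # brute force with mgcv::in.out as the independent membership oracle
    verts <- do.call(rbind, lapply(ann$polygons, function(p)
      rbind(p[[1]], c(NA, NA))))
    x0 <- floor(min(verts[, 1], na.rm = TRUE))
    y0 <- floor(min(verts[, 2], na.rm = TRUE))
    n_keep <- 0; origins <- NULL
    for (oy in seq(max(0, y0), h - s, by = s)) {
      for (ox in seq(max(0, x0), w - s, by = s)) {
        pts <- expand.grid(x = (ox:(ox + s - 1)) + 0.5,
                           y = (oy:(oy + s - 1)) + 0.5)
        inside <- mgcv::in.out(verts, as.matrix(pts))
        msub <- mask[(oy + 1):(oy + s), (ox + 1):(ox + s)]
        # expand.grid varies x fastest; mask indexed [row=y, col=x]
        inside_m <- matrix(inside, s, s, byrow = TRUE)
        if (mean(inside_m & msub) >= 0.3) {
          n_keep <- n_keep + 1
          origins <- rbind(origins, c(ox, oy))
        }
      }
    }
    expect_equal(length(ps$patches), n_keep)
    if (n_keep > 0)
      expect_setequal(paste(ps$origins[, 1], ps$origins[, 2]),
                      paste(origins[, 1], origins[, 2]))
    # polygon list order and vertex rotation do not change the result
    polys_perm <- rev(lapply(polys, function(p)
      list(p[[1]][c(3:5, 1:2), ])))
    ann2 <- load_annotation(write_geojson(polys_perm))
    ps_perm <- extract_patches(img, mask, ann2, patch_size = s,
                               coverage_fraction = 0.3)
    expect_equal(ps_perm$origins, ps$origins)
  }
})
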