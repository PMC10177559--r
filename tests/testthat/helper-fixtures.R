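# Shared fixtures and independent oracles for the test suite.

# Stained disc (two stains) on a white background.
disc_image <- function(h = 120, w = 120, r = 40, conc = c(0.5, 0.3)) {
  cc <- array(0, c(h, w, 2))
  cx <- w / 2; cy <- h / 2
  for (i in seq_len(h)) for (j in seq_len(w))
    if ((i - cy)^2 + (j - cx)^2 <= r^2) cc[i, j, ] <- conc
  list(image = make_stain_image(default_target_stain(), cc),
       concentrations = cc, area = sum(cc[, , 1] > 0))
}

# Random two-stain image with concentrations scaled so the 99th
# percentile matches the package reference (in the generator's
# natural-log units).
reference_scale_image <- function(side = 64, seed = 1,
                                  stains = default_target_stain()) {
  set.seed(seed)
  conc <- array(runif(side * side * 2, 0, 1.2), c(side, side, 2))
  ref <- default_concentration_reference()
  for (j in 1:2)
    conc[, , j] <- conc[, , j] * ref[j] * log(10) /
      quantile(conc[, , j], 0.99)
  list(image = make_stain_image(stains, conc), concentrations = conc)
}

angle_deg <- function(u, v) {
  acos(min(1, max(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
}

# Write a GeoJSON FeatureCollection of polygons to a temp file.
# Each polygon: list of rings; each ring a matrix of xy vertices.
write_geojson <- function(polygons, type = "Polygon") {
  feats <- lapply(polygons, function(rings) {
    coords <- lapply(rings, function(ring) {
      ring <- rbind(ring, ring[1, ])          # close the ring
      lapply(seq_len(nrow(ring)), function(i) as.list(ring[i, ]))
    })
    list(type = "Feature", properties = list(name = "tumour"),
         geometry = list(type = type, coordinates = coords))
  })
  path <- tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  path
}

square_ring <- function(x0, y0, side) {
  rbind(c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side),
        c(x0, y0 + side))
}

# --- independent metric oracles ----------------------------------------

# Spearman rho + t-based p via explicit average ranks and the Pearson
# formula, written independently of the package implementation.
brute_spearman <- function(a, b) {
  avg_rank <- function(x) {
    o <- order(x); r <- numeric(length(x)); i <- 1
    while (i <= length(x)) {
      j <- i
      while (j < length(x) && x[o[j + 1]] == x[o[i]]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  ra <- avg_rank(a); rb <- avg_rank(b)
  n <- length(a)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  rho <- num / den
  p <- if (abs(rho) >= 1 - 1e-15) 0 else
    2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
  list(rho = rho, p = p)
}

# Benjamini-Hochberg step-up, spelled out.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  q <- numeric(m); q[o] <- pmin(q_sorted, 1)
  q
}

# AUROC as the fraction of correctly ordered (positive, negative) pairs
# with half credit for ties.
brute_auroc <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# All-pairs concordance oracle.
brute_cindex <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  num / den
}

# One-way ANOVA F statistic from explicit sums of squares.
brute_anova_f <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v)
    length(v) * (mean(v) - gm)^2))
  ss_within <- sum(tapply(values, groups, function(v)
    sum((v - mean(v))^2)))
  (ss_between / (k - 1)) / (ss_within / (n - k))
}

# Small cohort shared by several fast tests.
tiny_cohort <- function(seed = 3, noise_sd = 0.1)
  make_cohort(n_patients = 20, patches_per_patient = 5, n_features = 8,
              n_genes = 6, noise_sd = noise_sd, seed = seed)
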