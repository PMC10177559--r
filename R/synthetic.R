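#' Synthesize a two-stain tissue image by the Beer-Lambert law
#'
#' Given a stain basis and per-pixel stain concentrations, generates the
#' transmitted-light image `I = background * exp(-S %*% c)` channel-wise,
#' rounded to 8 bits.  Used as a ground-truth fixture for the stain
#' normalization stage: the generating columns can be compared against the
#' output of [estimate_stain_matrix()].
#'
#' @param stains a [stain_matrix()].
#' @param concentrations `H x W x 2` array of nonnegative stain
#'   concentrations (natural-log optical-density units).
#' @param background background (white) intensity, default 255.
#' @param um_per_px pixel size recorded on the output image.
#' @return An [rgb_image()].
#' @export
make_stain_image <- function(stains, concentrations, background = 255,
                             um_per_px = 0.25) {
  stains <- stain_matrix(stains)
  stopifnot(is.array(concentrations), length(dim(concentrations)) == 3L,
            dim(concentrations)[3] == 2L)
  if (anyNA(concentrations) || any(!is.finite(concentrations)))
    stop("concentrations must be finite")
  if (any(concentrations < 0))
    stop("concentrations must be nonnegative")
  d <- dim(concentrations)
  cm <- matrix(concentrations, ncol = 2)
  od <- cm %*% t(unclass(stains))
  px <- pmin(pmax(round(background * exp(-od)), 0), 255)
  rgb_image(array(px, dim = c(d[1], d[2], 3L)), um_per_px)
}

#' Synthetic patient cohort with a known feature-to-expression map
#'
#' Generates a cohort in which each patient has `patches_per_patient`
#' patch-feature rows drawn around a patient-specific latent mean
#' (rank-`latent_rank` structure, so patients differ systematically), and
#' log-scale expression is an exact linear map `B` of the patient's mean
#' feature vector plus Gaussian noise and a per-gene baseline shift that
#' keeps all values nonnegative and gives genes distinct typical levels.
#' Subtype labels are thresholds on the first two latent dimensions, which
#' makes the expression-to-subtype classifier learnable by construction.
#'
#' The returned object stores the generating coefficients `B`, the
#' realised noise and the per-gene shift, so the construction
#' `expression = mean_features %*% B + noise + shift` can be verified
#' exactly.  Identical seed and parameters give a bit-identical cohort.
#'
#' @param n_patients,patches_per_patient,n_features,n_genes cohort sizes,
#'   all >= 1.
#' @param noise_sd standard deviation of the additive expression noise
#'   (log scale), >= 0.  Default 0.1.
#' @param seed integer seed; the generator restores the caller's RNG state.
#' @param latent_rank rank of the per-patient latent structure (default 5).
#' @return An object of class `synthetic_cohort` with fields
#'   `patient_ids`, `features` (list of [feature_tensor()]),
#'   `true_coefficients`, `gene_shift`, `noise`, `expression`
#'   (an [expr_matrix()] on the log scale), `noise_sd`, `subtype_labels`,
#'   `latent`, and `seed`.
#' @export
make_cohort <- function(n_patients, patches_per_patient, n_features,
                        n_genes, noise_sd = 0.1, seed = 1,
                        latent_rank = 5) {
  if (n_features < 1 || n_genes < 1)
    stop("n_features and n_genes must be >= 1")
  stopifnot(n_patients >= 1, patches_per_patient >= 1, noise_sd >= 0)
  k <- max(2L, as.integer(latent_rank))
  with_seed(seed, {
    loadings <- matrix(rnorm(k * n_features, sd = 1 / sqrt(k)),
                       k, n_features)
    B <- matrix(rnorm(n_features * n_genes, sd = 1 / sqrt(n_features)),
                n_features, n_genes)
    latent <- matrix(rnorm(n_patients * k), n_patients, k)
    mu <- latent %*% loadings
    ids <- sprintf("P%03d", seq_len(n_patients))
    genes <- sprintf("G%03d", seq_len(n_genes))
    features <- lapply(seq_len(n_patients), function(p) {
      x <- matrix(rep(mu[p, ], each = patches_per_patient),
                  patches_per_patient, n_features) +
        matrix(rnorm(patches_per_patient * n_features),
               patches_per_patient, n_features)
      feature_tensor(ids[p], x, backbone_id = "synthetic")
    })
    noise <- matrix(rnorm(n_patients * n_genes, sd = noise_sd),
                    n_patients, n_genes)
    baseline <- runif(n_genes, 0, 4)
    meanfeat <- t(vapply(features, function(f) colMeans(f$values),
                         numeric(n_features)))
    raw <- meanfeat %*% B + noise
    gene_shift <- baseline + pmax(0, -apply(raw, 2, min))
    expr <- sweep(raw, 2, gene_shift, "+")
    dimnames(expr) <- list(ids, genes)
    labels <- factor(
      ifelse(latent[, 1] > 0,
             ifelse(latent[, 2] > 0, "LumA", "LumB"),
             ifelse(latent[, 2] > 0, "HER2", "Basal")),
      levels = subtype_levels())
    structure(list(
      patient_ids = ids, features = features, true_coefficients = B,
      gene_shift = gene_shift, noise = noise,
      expression = expr_matrix(expr, scale = "log2p1"),
      noise_sd = noise_sd, subtype_labels = labels, latent = latent,
      seed = seed,
      params = list(n_patients = n_patients,
                    patches_per_patient = patches_per_patient,
                    n_features = n_features, n_genes = n_genes,
                    latent_rank = k)),
      class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<synthetic_cohort> %d patients x %d patches x %d features -> %d genes (noise sd %.3g, seed %d)\n",
    p$n_patients, p$patches_per_patient, p$n_features, p$n_genes,
    x$noise_sd, x$seed))
  invisible(x)
}

#' Vocabulary of intrinsic subtype labels
#' @return Character vector `c("LumA", "LumB", "Basal", "HER2")`.
#' @export
subtype_levels <- function() c("LumA", "LumB", "Basal", "HER2")

#' Synthetic proportional-hazards survival data
#'
#' Draws exponential survival times whose rate is multiplied by
#' `hazard_ratio_lumB` for Luminal-B patients, with independent uniform
#' censoring over a follow-up window chosen (by root finding) so that the
#' expected censoring fraction equals `censor_rate`.  Independent null
#' clinicopathological covariates (grade, size, age, nodal status) are
#' attached so multivariate model calibration can be checked: by
#' construction they carry no survival signal.
#'
#' @param subtype_labels vector of labels from [subtype_levels()].
#' @param hazard_ratio_lumB hazard multiplier for LumB vs all others, > 0.
#' @param baseline_rate exponential event rate per month for non-LumB
#'   patients (default 0.02).
#' @param censor_rate expected fraction of censored patients, in `[0, 1)`.
#' @param seed integer seed.
#' @return A `data.frame` (class `clinical_table`) with columns
#'   `patient_id`, `followup_time` (months), `event`, `grade`, `size_mm`,
#'   `age_years`, `ln_status`, `ihc_subtype`, `predicted_subtype`.
#' @export
make_survival <- function(subtype_labels, hazard_ratio_lumB = 2,
                          baseline_rate = 0.02, censor_rate = 0.3,
                          seed = 1) {
  labs <- as.character(subtype_labels)
  bad <- setdiff(unique(labs), subtype_levels())
  if (length(bad))
    stop("unknown subtype labels: ", paste(bad, collapse = ", "))
  stopifnot(hazard_ratio_lumB > 0, baseline_rate > 0,
            censor_rate >= 0, censor_rate < 1)
  n <- length(labs)
  rate <- baseline_rate * ifelse(labs == "LumB", hazard_ratio_lumB, 1)
  with_seed(seed, {
    t_event <- rexp(n, rate)
    if (censor_rate == 0) {
      time <- t_event; event <- rep(1L, n)
    } else {
      # P(censored | window W) for uniform C ~ U(0, W), T ~ Exp(r):
      # mean over patients of (1 - exp(-r W)) / (r W), decreasing in W.
      pcens <- function(w) mean((1 - exp(-rate * w)) / (rate * w))
      w <- uniroot(function(w) pcens(w) - censor_rate,
                   lower = 1e-6, upper = 1e8, tol = 1e-10)$root
      c_time <- runif(n, 0, w)
      event <- as.integer(t_event <= c_time)
      time <- pmin(t_event, c_time)
    }
    out <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      followup_time = time,
      event = event,
      grade = sample(1:3, n, replace = TRUE, prob = c(0.3, 0.45, 0.25)),
      size_mm = round(rlnorm(n, log(20), 0.5), 1),
      age_years = round(runif(n, 35, 85)),
      ln_status = sample(c("pos", "neg"), n, replace = TRUE),
      ihc_subtype = labs,
      predicted_subtype = NA_character_,
      stringsAsFactors = FALSE)
    class(out) <- c("clinical_table", "data.frame")
    out
  })
}
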