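#' Parameter-recovery experiment on synthetic cohorts
#'
#' For each seed, generates a cohort of `n_train + n_test` patients,
#' trains the aggregation-based head on the first `n_train`, predicts the
#' held-out patients and evaluates.  Returns per-seed medians of the
#' per-patient and per-gene Spearman correlations and their medians over
#' seeds.  The default problem size (80 train / 40 test patients, 32
#' features, 20 genes, noise sd 0.1) is the package's scaled-down stand-in
#' for a cohort-level study and runs in minutes on one CPU.
#'
#' @param seeds integer vector of cohort/training seeds.
#' @param n_train,n_test patient counts.
#' @param n_features,n_genes,patches_per_patient,noise_sd cohort
#'   parameters (see [make_cohort()]).
#' @param config,train_cfg head and training configuration; defaults are
#'   the standard recipe with `output_dim` taken from the data.
#' @return List with `per_seed` (data frame) and `summary`
#'   (median over seeds of both medians).
#' @export
experiment_parameter_recovery <- function(seeds = 1:5, n_train = 80,
                                          n_test = 40, n_features = 32,
                                          n_genes = 20,
                                          patches_per_patient = 20,
                                          noise_sd = 0.1,
                                          config = head_config(),
                                          train_cfg = NULL) {
  rows <- lapply(seeds, function(s) {
    cohort <- make_cohort(n_train + n_test, patches_per_patient,
                          n_features, n_genes, noise_sd = noise_sd,
                          seed = s)
    agg <- aggregate_cohort(cohort)
    train_ids <- cohort$patient_ids[seq_len(n_train)]
    test_ids <- cohort$patient_ids[-seq_len(n_train)]
    tc <- train_cfg %||% train_config(seed = s)
    model <- train_head(
      agg[train_ids, , drop = FALSE],
      expr_matrix(unclass(cohort$expression)[train_ids, , drop = FALSE],
                  scale = "log2p1"),
      train_cfg = tc, config = config)
    pred <- predict(model, agg[test_ids, , drop = FALSE])
    rep <- evaluate_predictions(
      pred, unclass(cohort$expression)[test_ids, , drop = FALSE])
    data.frame(seed = s,
               median_per_patient_rho = rep$medians$per_patient_rho,
               median_per_gene_rho = rep$medians$per_gene_rho,
               n_epochs = nrow(model$history))
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       summary = list(
         median_per_patient_rho = median(per_seed$median_per_patient_rho),
         median_per_gene_rho = median(per_seed$median_per_gene_rho)))
}

#' Aggregation vs patch-based training efficiency experiment
#'
#' Trains the same head twice on a noiseless synthetic cohort: once on
#' aggregated per-patient records and once on per-patch records (the
#' conventional reference strategy), then compares held-out per-patient
#' correlation and the instrumented records-visited-per-epoch counters.
#' With `patches_per_patient` patches the patch trainer visits exactly
#' that many times more records per epoch.  A reduced head (64/128/128
#' channels) keeps the patch-based arm affordable on one CPU; the
#' records-per-epoch ratio is independent of head size.  Both arms
#' monitor the training loss for early stopping: the cohort is noiseless,
#' so the training loss is a clean monitor, whereas a validation split of
#' a few patients is too noisy to compare the two strategies fairly.
#'
#' @param seed experiment seed (the comparison is defined at a fixed
#'   seed; both arms share it).
#' @param n_train,n_test,patches_per_patient,n_features,n_genes cohort
#'   sizes.
#' @param config head configuration used for both arms.
#' @param max_epochs epoch cap applied to both arms.
#' @return List with `samples_per_epoch_aggregation`,
#'   `samples_per_epoch_patch`, `samples_ratio`, `rho_aggregation`,
#'   `rho_patch` (held-out median per-patient Spearman for each arm).
#' @export
experiment_efficiency <- function(seed = 1, n_train = 40, n_test = 20,
                                  patches_per_patient = 20,
                                  n_features = 32, n_genes = 20,
                                  config = head_config(
                                    conv_channels = c(64, 128, 128)),
                                  max_epochs = 150) {
  cohort <- make_cohort(n_train + n_test, patches_per_patient,
                        n_features, n_genes, noise_sd = 0, seed = seed)
  train_ids <- cohort$patient_ids[seq_len(n_train)]
  test_ids <- cohort$patient_ids[-seq_len(n_train)]
  targets <- expr_matrix(
    unclass(cohort$expression)[train_ids, , drop = FALSE],
    scale = "log2p1")
  truth <- unclass(cohort$expression)[test_ids, , drop = FALSE]
  tc <- train_config(seed = seed, max_epochs = max_epochs,
                     validation_fraction = 0)
  agg <- aggregate_cohort(cohort)
  agg_fit <- train_head(agg[train_ids, , drop = FALSE], targets,
                        train_cfg = tc, config = config)
  agg_pred <- predict(agg_fit, agg[test_ids, , drop = FALSE])
  train_feats <- cohort$features[match(train_ids, cohort$patient_ids)]
  test_feats <- cohort$features[match(test_ids, cohort$patient_ids)]
  patch_fit <- patch_based_reference_train(train_feats, targets,
                                           train_cfg = tc, config = config)
  patch_pred <- predict_patients(patch_fit, test_feats)
  rho_of <- function(pred)
    median(evaluate_across_patients(pred, truth)$rho, na.rm = TRUE)
  list(samples_per_epoch_aggregation = agg_fit$samples_per_epoch,
       samples_per_epoch_patch = patch_fit$samples_per_epoch,
       samples_ratio = patch_fit$samples_per_epoch /
         agg_fit$samples_per_epoch,
       rho_aggregation = rho_of(agg_pred),
       rho_patch = rho_of(patch_pred))
}

#' Hazard-ratio recovery experiment
#'
#' For each seed, draws subtype labels (30% Luminal B among luminal
#' patients), simulates proportional-hazards survival with the stated
#' Luminal-B hazard ratio, and refits the univariate Cox model.  Reports
#' the estimated hazard ratios and the fraction falling inside
#' `recovery_interval`.
#'
#' @param seeds integer vector.
#' @param n patients per replicate.
#' @param hazard_ratio_lumB generating hazard ratio.
#' @param censor_rate expected censoring fraction.
#' @param recovery_interval interval the estimate should fall in.
#' @return List with `hr_estimates`, `prop_recovered`,
#'   `recovery_interval`.
#' @export
experiment_hr_recovery <- function(seeds = 1:20, n = 400,
                                   hazard_ratio_lumB = 2,
                                   censor_rate = 0.2,
                                   recovery_interval = c(1.4, 2.8)) {
  hrs <- vapply(seeds, function(s) {
    labels <- with_seed(s + 10000L,
                        sample(c("LumA", "LumB"), n, replace = TRUE,
                               prob = c(0.7, 0.3)))
    clin <- make_survival(labels, hazard_ratio_lumB = hazard_ratio_lumB,
                          censor_rate = censor_rate, seed = s)
    dich <- suppressMessages(dichotomise(clin))
    fit <- cox_fit(dich, "luminal_group", mode = "univariate")
    fit$hr[1]
  }, numeric(1))
  list(hr_estimates = hrs,
       prop_recovered = mean(hrs >= recovery_interval[1] &
                               hrs <= recovery_interval[2]),
       recovery_interval = recovery_interval)
}

#' Null calibration of the concordance index
#'
#' Draws `replicates` cohorts of exponential survival times with
#' independent censoring and scores them with pure-noise risk scores; a
#' calibrated concordance index averages 0.5.
#'
#' @param replicates number of Monte-Carlo replicates.
#' @param n patients per replicate.
#' @param censor_rate expected censoring fraction.
#' @param seed master seed.
#' @return List with `mean_c_index` and `c_indices`.
#' @export
experiment_cindex_null <- function(replicates = 200, n = 200,
                                   censor_rate = 0.3, seed = 1) {
  cs <- with_seed(seed, vapply(seq_len(replicates), function(i) {
    t_event <- rexp(n, 0.05)
    c_time <- rexp(n, 0.05 * censor_rate / (1 - censor_rate))
    time <- pmin(t_event, c_time)
    event <- as.integer(t_event <= c_time)
    concordance_index(rnorm(n), time, event)$c_index
  }, numeric(1)))
  list(mean_c_index = mean(cs), c_indices = cs)
}

#' Null calibration of the log-rank test
#'
#' Simulates two-group survival data with a unit hazard ratio and reports
#' the rejection rate at level `alpha`; a calibrated test rejects at
#' about `alpha`.
#'
#' @param replicates number of replicates (>= 500 recommended).
#' @param n patients per replicate.
#' @param alpha significance level.
#' @param seed master seed.
#' @return List with `reject_rate` and `p_values`.
#' @export
experiment_logrank_null <- function(replicates = 500, n = 60,
                                    alpha = 0.05, seed = 1) {
  base <- (seed %% 1000L) * 1000000L  # keep derived seeds well below 2^31
  ps <- vapply(seq_len(replicates), function(i) {
    labels <- with_seed(base + 2L * i,
                        sample(c("LumA", "LumB"), n, replace = TRUE))
    clin <- make_survival(labels, hazard_ratio_lumB = 1,
                          censor_rate = 0.2, seed = base + 2L * i + 1L)
    logrank_test(clin$followup_time, clin$event, labels)$p
  }, numeric(1))
  list(reject_rate = mean(ps < alpha), p_values = ps)
}
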