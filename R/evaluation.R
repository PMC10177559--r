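#' Spearman correlation with a t-distribution p-value
#'
#' Rank correlation with average ranks for ties; the two-sided p-value is
#' taken from `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom, which is this package's declared convention for
#' correlation significance.  `|rho| = 1` gives `p = 0`; a constant input
#' is flagged as an undefined correlation (`NA`) rather than dropped
#' silently.
#'
#' @param a,b numeric vectors of equal length `n >= 3`.
#' @return List with `rho`, `p`, `n`, and `constant` (TRUE when either
#'   vector has no rank variation).
#' @export
spearman_with_p <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3) stop("need at least 3 paired observations")
  ra <- rank(a); rb <- rank(b)
  if (sd(ra) == 0 || sd(rb) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, constant = TRUE))
  rho <- cor(ra, rb)
  p <- if (abs(rho) >= 1 - 1e-15) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, constant = FALSE)
}

align_pred_truth <- function(pred, truth) {
  pred <- unclass(pred); truth <- unclass(truth)
  stopifnot(is.matrix(pred), is.matrix(truth))
  if (is.null(rownames(pred)) || is.null(rownames(truth)) ||
      is.null(colnames(pred)) || is.null(colnames(truth)))
    stop("prediction and truth matrices need patient and gene names")
  if (!setequal(rownames(pred), rownames(truth)) ||
      !setequal(colnames(pred), colnames(truth)))
    stop("prediction and truth matrices do not align (patients or genes differ)")
  list(pred = pred[rownames(truth), colnames(truth), drop = FALSE],
       truth = truth)
}

#' Per-patient correlation between predicted and true expression
#'
#' One Spearman correlation per patient, computed across the genes of the
#' panel.  This view rewards capturing each patient's overall expression
#' profile (which genes are high and which are low), and is typically the
#' stronger of the two views because much of that profile is shared
#' across patients.
#'
#' @param pred,truth aligned patients x genes matrices
#'   ([expr_matrix()] or plain named matrices).
#' @return `data.frame(patient_id, rho, p)`.
#' @export
evaluate_across_patients <- function(pred, truth) {
  al <- align_pred_truth(pred, truth)
  res <- lapply(seq_len(nrow(al$truth)), function(i)
    spearman_with_p(al$pred[i, ], al$truth[i, ]))
  data.frame(patient_id = rownames(al$truth),
             rho = vapply(res, `[[`, numeric(1), "rho"),
             p = vapply(res, `[[`, numeric(1), "p"),
             stringsAsFactors = FALSE)
}

#' Per-gene correlation, FDR adjustment and R-squared
#'
#' One Spearman correlation per gene across patients, with
#' Benjamini-Hochberg adjusted q-values over the panel, plus the per-gene
#' coefficient of determination `R2 = 1 - SS_res / SS_tot` (which can be
#' negative for genes predicted worse than their mean).  Genes with a
#' constant prediction or truth are reported with undefined correlation
#' rather than dropped, so significance counts stay transparent.
#'
#' @inheritParams evaluate_across_patients
#' @param fdr_threshold q-value threshold for the significance count.
#' @return List with `per_gene` (`data.frame(symbol, rho, p, q, r2)`) and
#'   `n_significant`.
#' @export
evaluate_across_genes <- function(pred, truth, fdr_threshold = 0.05) {
  al <- align_pred_truth(pred, truth)
  if (nrow(al$truth) < 3) stop("need at least 3 patients")
  res <- lapply(seq_len(ncol(al$truth)), function(j)
    spearman_with_p(al$pred[, j], al$truth[, j]))
  p <- vapply(res, `[[`, numeric(1), "p")
  q <- p.adjust(p, method = "BH")
  r2 <- vapply(seq_len(ncol(al$truth)), function(j) {
    y <- al$truth[, j]; yh <- al$pred[, j]
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - sum((y - yh)^2) / ss_tot
  }, numeric(1))
  per_gene <- data.frame(symbol = colnames(al$truth),
                         rho = vapply(res, `[[`, numeric(1), "rho"),
                         p = p, q = q, r2 = r2,
                         stringsAsFactors = FALSE)
  list(per_gene = per_gene,
       n_significant = sum(q < fdr_threshold, na.rm = TRUE))
}

#' Full evaluation report
#'
#' Combines the across-patient and across-gene views with their medians
#' and the FDR significance count.
#'
#' @inheritParams evaluate_across_genes
#' @return Object of class `eval_report` with fields `per_patient`,
#'   `per_gene`, `medians` (`per_patient_rho`, `per_gene_rho`),
#'   `n_significant_genes` and `fdr_threshold`.
#' @export
evaluate_predictions <- function(pred, truth, fdr_threshold = 0.05) {
  pp <- evaluate_across_patients(pred, truth)
  pg <- evaluate_across_genes(pred, truth, fdr_threshold)
  structure(list(
    per_patient = pp, per_gene = pg$per_gene,
    medians = list(per_patient_rho = median(pp$rho, na.rm = TRUE),
                   per_gene_rho = median(pg$per_gene$rho, na.rm = TRUE)),
    n_significant_genes = pg$n_significant,
    fdr_threshold = fdr_threshold),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> median rho: %.3f across %d patients, %.3f across %d genes; %d/%d genes significant at FDR %.2g\n",
    x$medians$per_patient_rho, nrow(x$per_patient),
    x$medians$per_gene_rho, nrow(x$per_gene),
    x$n_significant_genes, nrow(x$per_gene), x$fdr_threshold))
  invisible(x)
}

#' Write an evaluation report to CSV + JSON
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  stopifnot(inherits(report, "eval_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$per_patient,
                   file.path(dir, "per_patient.csv"), row.names = FALSE)
  utils::write.csv(report$per_gene,
                   file.path(dir, "per_gene.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(medians = report$medians,
         n_significant_genes = report$n_significant_genes,
         fdr_threshold = report$fdr_threshold),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Two-group t-test or multi-group one-way ANOVA
#'
#' Dispatches on the number of groups: two groups are compared with a
#' two-sided t-test (Welch by default), three or more with a one-way
#' ANOVA F-test.  Singleton groups are an error.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length.
#' @param var_equal use the pooled-variance Student t-test instead of
#'   Welch (two-group case only).
#' @return List with `method`, `statistic`, `p`, `df`, `group_means`.
#' @export
group_difference_tests <- function(values, groups, var_equal = FALSE) {
  groups <- factor(groups)
  stopifnot(length(values) == length(groups))
  counts <- table(groups)
  if (length(counts) < 2) stop("need at least 2 groups")
  if (any(counts < 2))
    stop("singleton group(s): ",
         paste(names(counts)[counts < 2], collapse = ", "))
  gm <- tapply(values, groups, mean)
  if (length(counts) == 2) {
    tt <- t.test(values ~ groups, var.equal = var_equal)
    list(method = if (var_equal) "student_t" else "welch_t",
         statistic = unname(tt$statistic), p = tt$p.value,
         df = unname(tt$parameter), group_means = gm)
  } else {
    fit <- anova(aov(values ~ groups))
    list(method = "anova_f", statistic = fit$`F value`[1],
         p = fit$`Pr(>F)`[1],
         df = c(fit$Df[1], fit$Df[2]), group_means = gm)
  }
}

# ---- subtype classification -------------------------------------------

#' Four-member soft-voting intrinsic-subtype classifier
#'
#' Fits a random forest, a single-hidden-layer perceptron, linear
#' discriminant analysis and multinomial logistic regression on the
#' subtype-panel genes, and predicts by soft voting: the arithmetic mean
#' of the four members' class-probability outputs, with the label taken
#' as the highest-probability class (ties broken by class order, which is
#' the factor level order of the training labels).
#'
#' @param expr an [expr_matrix()] (typically restricted to the PAM50-style
#'   flags via [select_panel()]) or plain patients x genes matrix.
#' @param labels subtype label per patient (factor or character); at
#'   least two classes must be present.
#' @param panel optional [gene_panel()]; when given, columns are first
#'   restricted to its `pam50`-flagged symbols.
#' @param seed integer seed controlling the stochastic members.
#' @return Object of class `subtype_model`.
#' @export
fit_subtype_classifier <- function(expr, labels, panel = NULL, seed = 1) {
  x <- unclass(expr)
  if (!is.null(panel)) {
    stopifnot(inherits(panel, "gene_panel"))
    x <- x[, intersect(panel$symbol[panel$pam50], colnames(x)),
           drop = FALSE]
  }
  y <- if (is.factor(labels)) droplevels(labels) else
    factor(labels, levels = intersect(subtype_levels(), unique(labels)))
  stopifnot(nrow(x) == length(y))
  if (nlevels(y) < 2) stop("need at least 2 classes in the labels")
  centre <- colMeans(x); spread <- apply(x, 2, sd)
  spread[spread == 0] <- 1
  xs <- scale(x, centre, spread)
  df <- data.frame(.y = y, xs, check.names = TRUE)
  with_seed(seed, {
    members <- list(
      rf = randomForest::randomForest(x = xs, y = y, ntree = 300),
      mlp = nnet::nnet(xs, nnet::class.ind(y), size = 16, decay = 0.01,
                       softmax = TRUE, maxit = 300, trace = FALSE,
                       MaxNWts = 50000),
      lda = MASS::lda(xs, grouping = y),
      lr = nnet::multinom(.y ~ ., data = df, decay = 0.01, trace = FALSE,
                          MaxNWts = 50000))
    structure(list(members = members, classes = levels(y),
                   centre = centre, spread = spread,
                   feature_names = colnames(x), seed = seed,
                   fitted = TRUE),
              class = "subtype_model")
  })
}

member_probabilities <- function(model, xs, df) {
  cls <- model$classes
  as_cls_matrix <- function(p) {
    if (is.null(dim(p))) {
      # two-class multinom returns P(second level)
      p <- cbind(1 - p, p)
      colnames(p) <- cls
    }
    p[, cls, drop = FALSE]
  }
  list(
    rf = as_cls_matrix(predict(model$members$rf, xs, type = "prob")),
    mlp = {
      p <- predict(model$members$mlp, xs, type = "raw")
      colnames(p) <- colnames(model$members$mlp$fitted.values)
      as_cls_matrix(p)
    },
    lda = as_cls_matrix(predict(model$members$lda, xs)$posterior),
    lr = as_cls_matrix(predict(model$members$lr, newdata = df,
                               type = "probs")))
}

#' Predict subtypes by soft voting
#'
#' @param model a fitted `subtype_model`.
#' @param expr expression matrix with the same genes the model was fitted
#'   on.
#' @return List with `labels` (factor) and `probabilities`
#'   (patients x classes matrix, rows summing to 1).
#' @export
predict_subtype <- function(model, expr) {
  stopifnot(inherits(model, "subtype_model"))
  x <- unclass(expr)
  miss <- setdiff(model$feature_names, colnames(x))
  if (length(miss))
    stop("expression matrix lacks model genes: ",
         paste(miss, collapse = ", "))
  x <- x[, model$feature_names, drop = FALSE]
  xs <- scale(x, model$centre, model$spread)
  df <- data.frame(xs, check.names = TRUE)
  probs <- member_probabilities(model, xs, df)
  voted <- Reduce(`+`, probs) / length(probs)
  labels <- factor(model$classes[apply(voted, 1, which.max)],
                   levels = model$classes)
  rownames(voted) <- rownames(x)
  names(labels) <- rownames(x)
  list(labels = labels, probabilities = voted,
       member_probabilities = probs)
}

#' Soft-vote averaging of member probabilities
#'
#' Exposed separately so the voting arithmetic is testable on its own:
#' the voted probability matrix is the element-wise arithmetic mean of
#' the member matrices; the voted label is the argmax with ties broken by
#' column (class) order.
#'
#' @param prob_list list of aligned probability matrices.
#' @return List with `probabilities` and `labels` (column-name labels).
#' @export
soft_vote <- function(prob_list) {
  stopifnot(length(prob_list) >= 1)
  voted <- Reduce(`+`, prob_list) / length(prob_list)
  list(probabilities = voted,
       labels = colnames(voted)[apply(voted, 1, which.max)])
}

#' Classification metrics: accuracy, macro-F1, one-vs-rest AUROC
#'
#' AUROC per class is computed one-vs-rest from the voted class
#' probabilities with the rank (Mann-Whitney) formula, which assigns
#' half credit to tied scores -- identical to the fraction of correctly
#' ordered (positive, negative) pairs.  A class absent from the truth has
#' undefined AUROC and is flagged with `NA`.
#'
#' @param truth true labels.
#' @param predicted predicted labels.
#' @param probabilities patients x classes probability matrix (needed for
#'   AUROC).
#' @return List with `accuracy`, `macro_f1`, `per_class_auroc`,
#'   `confusion`.
#' @export
classification_metrics <- function(truth, predicted,
                                   probabilities = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  stopifnot(length(truth) == length(predicted))
  classes <- sort(unique(c(truth, predicted)))
  acc <- mean(truth == predicted)
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & predicted == cl)
    fp <- sum(truth != cl & predicted == cl)
    fn <- sum(truth == cl & predicted != cl)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  auroc <- NULL
  if (!is.null(probabilities)) {
    auroc <- vapply(colnames(probabilities), function(cl) {
      pos <- truth == cl
      if (!any(pos) || all(pos)) return(NA_real_)
      auroc_rank(probabilities[, cl], pos)
    }, numeric(1))
  }
  list(accuracy = acc,
       macro_f1 = mean(f1[classes %in% truth], na.rm = TRUE),
       per_class_auroc = auroc,
       confusion = table(truth = truth, predicted = predicted))
}

# Mann-Whitney AUROC with average-rank (half-credit) tie handling.
auroc_rank <- function(scores, positive) {
  r <- rank(scores)
  np <- sum(positive); nn <- sum(!positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}
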