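test_that("rank correlation and its t p-value match a brute-force oracle", {
  expect_equal(spearman_with_p(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_with_p(1:10, (1:10)^2)$p, 0)
  expect_equal(spearman_with_p(1:10, rev(1:10))$rho, -1)
  set.seed(12)
  for (i in 1:10) {
    a <- rnorm(20)
    b <- if (i %% 2) rnorm(20) else sample(round(rnorm(20), 1))  # ties
    got <- spearman_with_p(a, b)
    ref <- brute_spearman(a, b)
    expect_equal(got$rho, ref$rho, tolerance = 1e-12)
    expect_equal(got$p, ref$p, tolerance = 1e-12)
  }
  cons <- spearman_with_p(rep(1, 5), rnorm(5))
  expect_true(cons$constant && is.na(cons$rho))
})

test_that("matrix evaluations agree with naive double loops", {
  set.seed(13)
  pred <- matrix(rnorm(80), 10, 8,
                 dimnames = list(sprintf("P%d", 1:10), sprintf("G%d", 1:8)))
  truth <- matrix(rnorm(80), 10, 8, dimnames = dimnames(pred))
  pp <- evaluate_across_patients(pred, truth)
  for (i in 1:10)
    expect_equal(pp$rho[i], brute_spearman(pred[i, ], truth[i, ])$rho,
                 tolerance = 1e-12)
  pg <- evaluate_across_genes(pred, truth)
  for (j in 1:8) {
    ref <- brute_spearman(pred[, j], truth[, j])
    expect_equal(pg$per_gene$rho[j], ref$rho, tolerance = 1e-12)
    expect_equal(pg$per_gene$p[j], ref$p, tolerance = 1e-12)
    r2 <- 1 - sum((truth[, j] - pred[, j])^2) /
      sum((truth[, j] - mean(truth[, j]))^2)
    expect_equal(pg$per_gene$r2[j], r2, tolerance = 1e-12)
  }
  expect_equal(pg$per_gene$q, brute_bh(pg$per_gene$p), tolerance = 1e-12)
  # perfect prediction: all rho and R2 equal one (within float epsilon)
  perf <- evaluate_across_genes(truth, truth)
  expect_equal(perf$per_gene$rho, rep(1, 8), tolerance = 1e-12)
  expect_equal(perf$per_gene$r2, rep(1, 8), tolerance = 1e-12)
  expect_true(all(perf$per_gene$p == 0))
  expect_equal(evaluate_across_patients(truth, truth)$rho, rep(1, 10),
               tolerance = 1e-12)
  # column-shuffled predictions have near-zero median patient correlation
  set.seed(14)
  meds <- replicate(60, {
    shuf <- truth[, sample(8)]; colnames(shuf) <- colnames(truth)
    median(evaluate_across_patients(shuf, truth)$rho)
  })
  expect_lt(abs(mean(meds)), 0.1)
})

test_that("FDR adjustment reproduces the hand-applied step-up and its bounds", {
  expect_equal(brute_bh(c(0.01, 0.02, 0.04, 0.5)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5), tolerance = 1e-12)
  expect_equal(p.adjust(c(0.01, 0.02, 0.04, 0.5), "BH"),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.5), tolerance = 1e-12)
  set.seed(15)
  p <- runif(40)^2
  qq <- p.adjust(p, "BH")
  expect_equal(qq, brute_bh(p), tolerance = 1e-12)
  expect_true(all(qq >= 0 & qq <= 1))
  # q equals p when there is a single test
  expect_equal(p.adjust(0.037, "BH"), 0.037)
  o <- order(p)
  expect_true(all(diff(qq[o]) >= -1e-15))
})

test_that("group difference tests dispatch correctly and match oracles", {
  x <- rnorm(12)
  same <- group_difference_tests(c(x, x), rep(c("a", "b"), each = 12))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  gap <- group_difference_tests(c(rnorm(15), rnorm(15) + 50),
                                rep(c("lo", "hi"), each = 15))
  expect_lt(gap$p, 1e-6)
  set.seed(16)
  v <- rnorm(30); g <- sample(c("a", "b", "c"), 30, TRUE)
  got <- group_difference_tests(v, g)
  expect_equal(got$method, "anova_f")
  expect_equal(got$statistic, brute_anova_f(v, g), tolerance = 1e-12)
  expect_error(group_difference_tests(1:5, c("a", "a", "a", "a", "b")),
               "singleton")
})

test_that("soft voting averages member probabilities with ordered tie-breaks", {
  mk <- function(v) matrix(v, 1, 3, dimnames = list("p", c("A", "B", "C")))
  vote <- soft_vote(list(mk(c(0.6, 0.2, 0.2)), mk(c(0.2, 0.6, 0.2)),
                         mk(c(0.2, 0.2, 0.6)), mk(c(0.4, 0.4, 0.2))))
  expect_equal(as.vector(vote$probabilities), c(0.35, 0.35, 0.30),
               tolerance = 1e-12)
  expect_equal(vote$labels, "A")  # tie broken by class order
  # unanimous members vote with probability one
  unan <- soft_vote(rep(list(mk(c(1, 0, 0))), 4))
  expect_equal(as.vector(unan$probabilities), c(1, 0, 0))
})

test_that("the voting classifier separates well-separated synthetic subtypes", {
  set.seed(17)
  classes <- subtype_levels()
  centroids <- matrix(rnorm(4 * 12, sd = 3), 4, 12,
                      dimnames = list(classes, sprintf("G%03d", 1:12)))
  n <- 240
  y <- factor(sample(classes, n, TRUE), levels = classes)
  x <- centroids[as.integer(y), ] + matrix(rnorm(n * 12, sd = 0.5), n, 12)
  rownames(x) <- sprintf("P%03d", 1:n)
  tr <- 1:160; te <- 161:240
  model <- fit_subtype_classifier(x[tr, ], y[tr], seed = 17)
  pred <- predict_subtype(model, x[te, ])
  metrics <- classification_metrics(y[te], pred$labels, pred$probabilities)
  expect_gt(metrics$accuracy, 0.9)
  expect_true(all(metrics$per_class_auroc > 0.95))
  expect_equal(length(model$members), 4)
  expect_equal(rowSums(pred$probabilities), rep(1, length(te)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # determinism under the seed
  model2 <- fit_subtype_classifier(x[tr, ], y[tr], seed = 17)
  pred2 <- predict_subtype(model2, x[te, ])
  expect_equal(pred$probabilities, pred2$probabilities, tolerance = 1e-12)
})

test_that("AUROC matches the pairwise oracle and behaves at the extremes", {
  set.seed(18)
  for (i in 1:5) {
    scores <- round(runif(30), 2)  # induce ties
    pos <- runif(30) < 0.4
    if (!any(pos) || all(pos)) next
    expect_equal(histexpr:::auroc_rank(scores, pos),
                 brute_auroc(scores, pos), tolerance = 1e-12)
  }
  # perfect separation and label-independent scores
  truth <- rep(c("A", "B"), each = 20)
  probs <- cbind(A = c(runif(20, 0.8, 1), runif(20, 0, 0.2)))
  probs <- cbind(probs, B = 1 - probs[, "A"])
  pred <- ifelse(probs[, "A"] > 0.5, "A", "B")
  m <- classification_metrics(truth, pred, probs)
  expect_equal(unname(m$per_class_auroc), c(1, 1))
  expect_equal(m$accuracy, 1)
  set.seed(19)
  null_auc <- replicate(200, {
    sc <- runif(40); lab <- rep(c(TRUE, FALSE), each = 20)
    histexpr:::auroc_rank(sc, lab)
  })
  expect_lt(abs(mean(null_auc) - 0.5), 0.02)
})
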