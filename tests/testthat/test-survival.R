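test_that("clinical dichotomisation follows the printed cut-offs with boundary rules", {
  clin <- data.frame(
    patient_id = sprintf("P%d", 1:6),
    followup_time = c(10, 20, 30, 40, 50, 60),
    event = c(1, 0, 1, 1, 0, 1),
    grade = c(1, 2, 3, 3, 2, 1),
    size_mm = c(20, 21, 19.9, 20.0001, 5, 60),
    age_years = c(55, 56, 54, 55, 70, 40),
    ln_status = c("pos", "neg", "pos", "neg", "pos", "neg"),
    ihc_subtype = c("LumA", "LumB", "Basal", "HER2", "LumA", "LumB"))
  d <- dichotomise(clin)
  expect_equal(as.character(d$grade_group),
               c("1-2", "1-2", "3", "3", "1-2", "1-2"))
  expect_equal(as.character(d$size_group),
               c("<=20", ">20", "<=20", ">20", "<=20", ">20"))
  expect_equal(as.character(d$age_group),
               c("<=55", ">55", "<=55", "<=55", ">55", "<=55"))
  expect_equal(as.character(d$ln_group),
               c("pos", "neg", "pos", "neg", "pos", "neg"))
  expect_equal(as.character(d$luminal_group),
               c("LumA", "LumB", NA, NA, "LumA", "LumB"))
  # missing values are excluded with a message
  clin$age_years[2] <- NA
  expect_message(d2 <- dichotomise(clin), "1 patient")
  expect_true(is.na(d2$age_group[2]))
})

test_that("Kaplan-Meier estimate matches the hand-worked interleaved example", {
  # subjects: event 1, censor 2, event 3, censor 4, event 5, event 6
  times <- 1:6
  events <- c(1, 0, 1, 0, 1, 1)
  km <- km_estimate(times, events)
  hand <- c(5 / 6,                 # t=1: 6 at risk, 1 event
            5 / 6,                 # t=2: censoring only
            5 / 6 * 3 / 4,         # t=3: 4 at risk
            5 / 6 * 3 / 4,         # t=4: censoring only
            5 / 6 * 3 / 4 * 1 / 2, # t=5: 2 at risk
            0)                     # t=6: last subject dies
  expect_equal(km$survival, hand, tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 0))
  # all censored: curve stays at 1
  expect_true(all(km_estimate(c(2, 4, 9), c(0, 0, 0))$survival == 1))
  # no censoring: curve equals the empirical survival fraction
  set.seed(20)
  t2 <- sample(1:100, 30)
  km2 <- km_estimate(t2, rep(1, 30))
  expect_equal(km2$survival, vapply(km2$time, function(u) mean(t2 > u),
                                    numeric(1)), tolerance = 1e-12)
})

test_that("log-rank test matches the survival package on random data", {
  set.seed(21)
  for (i in 1:8) {
    n <- sample(20:60, 1)
    time <- rexp(n, 0.05)
    ev <- rbinom(n, 1, 0.7)
    k <- sample(2:3, 1)
    g <- sample(letters[1:k], n, TRUE)
    if (length(unique(g)) < k) next
    got <- logrank_test(time, ev, g)
    ref <- survival::survdiff(survival::Surv(time, ev) ~ g)
    expect_equal(got$statistic, ref$chisq, tolerance = 1e-9)
    expect_equal(got$df, k - 1)
  }
  expect_error(logrank_test(1:4, rep(1, 4), rep("a", 4)), "2 groups")
  expect_error(logrank_test(1:4, rep(1, 4),
                            factor(rep("a", 4), levels = c("a", "b"))),
               "empty")
})

test_that("concordance index matches the all-pairs oracle and its anchors", {
  times <- c(3, 1, 4, 2, 6, 5)
  events <- rep(1, 6)
  expect_equal(concordance_index(-times, times, events)$c_index, 1)
  expect_equal(concordance_index(times, times, events)$c_index, 0)
  set.seed(22)
  for (i in 1:5) {
    n <- 60
    time <- round(rexp(n, 0.1), 1)
    ev <- rbinom(n, 1, 0.6)
    risk <- round(rnorm(n), 1)
    got <- concordance_index(risk, time, ev)
    expect_equal(got$c_index, brute_cindex(risk, time, ev),
                 tolerance = 1e-12)
  }
  expect_warning(res <- concordance_index(1:3, c(5, 5, 5), c(1, 1, 1)),
                 "no admissible")
  expect_true(is.na(res$c_index))
})

test_that("proportional-hazards fits recover null and real effects", {
  set.seed(23)
  # identical groups: HR near 1 with the CI covering 1
  time <- rexp(200, 0.05); ev <- rbinom(200, 1, 0.8)
  df <- data.frame(followup_time = time, event = ev,
                   g = factor(rep(c("ref", "alt"), 100),
                              levels = c("ref", "alt")))
  fit <- cox_fit(df, "g", mode = "univariate")
  expect_lt(abs(log(fit$hr)), 0.5)
  expect_true(fit$ci_lower < 1 && fit$ci_upper > 1)
  # multivariate fit with an independent null covariate stays calibrated
  cover <- vapply(1:40, function(s) {
    labs <- histexpr:::with_seed(300L + s,
                                 sample(c("LumA", "LumB"), 250, TRUE))
    clin <- make_survival(labs, hazard_ratio_lumB = 2, censor_rate = 0.2,
                          seed = 600L + s)
    d <- suppressMessages(dichotomise(clin))
    f <- cox_fit(d, c("luminal_group", "age_group"), "multivariate")
    row <- f[grepl("age_group", f$term), ]
    row$ci_lower < 1 && row$ci_upper > 1
  }, logical(1))
  expect_gt(mean(cover), 0.85)
})
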