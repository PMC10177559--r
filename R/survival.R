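#' Dichotomise clinical covariates into risk groups
#'
#' Applies the standard clinical cut-offs: tumour grade 1 & 2 vs 3,
#' tumour size > 20 vs <= 20 mm, age > 55 vs <= 55 years, lymph node
#' positive vs negative, and Luminal B vs Luminal A subtype.  Boundary
#' values fall in the "<=" (reference) group.  Rows with missing values
#' in a field get `NA` for that indicator; the number excluded per field
#' is reported via `message()`.
#'
#' @param table a `clinical_table` (see [make_survival()]) or data frame
#'   with columns `grade`, `size_mm`, `age_years`, `ln_status`, and a
#'   subtype column.
#' @param subtype_col which subtype column to dichotomise
#'   (default `"ihc_subtype"`; `"predicted_subtype"` for model output).
#' @return The input with factor columns `grade_group` (`"1-2"` ref /
#'   `"3"`), `size_group` (`"<=20"` / `">20"`), `age_group`
#'   (`"<=55"` / `">55"`), `ln_group` (`"neg"` / `"pos"`) and
#'   `luminal_group` (`"LumA"` / `"LumB"`, `NA` for other subtypes)
#'   appended.
#' @export
dichotomise <- function(table, subtype_col = "ihc_subtype") {
  df <- as.data.frame(table)
  need <- c("grade", "size_mm", "age_years", "ln_status", subtype_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  report_na <- function(x, what) {
    n <- sum(is.na(x))
    if (n > 0) message(sprintf("%d patient(s) excluded from %s (missing)",
                               n, what))
    x
  }
  grade <- report_na(df$grade, "grade")
  if (any(!is.na(grade) & !grade %in% 1:3))
    stop("grade values outside {1, 2, 3}")
  df$grade_group <- factor(ifelse(grade == 3, "3", "1-2"),
                           levels = c("1-2", "3"))
  df$size_group <- factor(
    ifelse(report_na(df$size_mm, "size") > 20, ">20", "<=20"),
    levels = c("<=20", ">20"))
  df$age_group <- factor(
    ifelse(report_na(df$age_years, "age") > 55, ">55", "<=55"),
    levels = c("<=55", ">55"))
  ln <- report_na(df$ln_status, "lymph node status")
  if (any(!is.na(ln) & !ln %in% c("pos", "neg")))
    stop("ln_status values outside {pos, neg}")
  df$ln_group <- factor(ln, levels = c("neg", "pos"))
  st <- report_na(df[[subtype_col]], subtype_col)
  df$luminal_group <- factor(ifelse(st %in% c("LumA", "LumB"), st, NA),
                             levels = c("LumA", "LumB"))
  df
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up times, >= 0.
#' @param events event indicators (1 = event, 0 = censored).
#' @return `data.frame(time, n_risk, n_event, n_censor, survival)` with
#'   one row per distinct observed time; the curve starts at 1, is
#'   non-increasing, and only drops at event times.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events), length(times) >= 1,
            all(times >= 0), all(events %in% c(0, 1)))
  tt <- sort(unique(times))
  n_risk <- vapply(tt, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(tt, function(t) sum(times == t & events == 1),
                    numeric(1))
  n_censor <- vapply(tt, function(t) sum(times == t & events == 0),
                     numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = tt, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, survival = surv)
}

#' Log-rank test across survival groups
#'
#' Standard log-rank chi-square on `k - 1` degrees of freedom comparing
#' observed and expected event counts under the hypergeometric model at
#' each distinct event time.
#'
#' @inheritParams km_estimate
#' @param groups group label per subject; every group must be non-empty.
#' @return List with `statistic`, `df`, `p`, `observed`, `expected`.
#' @export
logrank_test <- function(times, events, groups) {
  # keep declared-but-unobserved factor levels so they trip the
  # empty-group check rather than being dropped silently
  if (!is.factor(groups)) groups <- factor(groups)
  stopifnot(length(times) == length(events),
            length(times) == length(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0))
    stop("empty group(s): ",
         paste(levels(groups)[table(groups) == 0], collapse = ", "))
  k <- nlevels(groups)
  ev_times <- sort(unique(times[events == 1]))
  O <- numeric(k); E <- numeric(k); V <- matrix(0, k, k)
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    d <- sum(times == t & events == 1)
    ng <- vapply(levels(groups), function(g) sum(at_risk & groups == g),
                 numeric(1))
    dg <- vapply(levels(groups), function(g)
      sum(times == t & events == 1 & groups == g), numeric(1))
    O <- O + dg
    E <- E + d * ng / n
    if (n > 1) {
      frac <- ng / n
      V <- V + d * (n - d) / (n - 1) * (diag(frac) - tcrossprod(frac))
    }
  }
  i <- seq_len(k - 1)
  u <- (O - E)[i]
  Vi <- V[i, i, drop = FALSE]
  stat <- as.numeric(t(u) %*% solve(Vi, u))
  list(statistic = stat, df = k - 1,
       p = pchisq(stat, df = k - 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Concordance index of risk scores against survival times
#'
#' Over admissible pairs -- the earlier time belongs to a subject with an
#' event; pairs with tied times are inadmissible -- a pair is concordant
#' when the earlier subject has the higher risk score, counts half when
#' the risk scores are tied, and zero otherwise.  Random scores give 0.5,
#' a perfect risk ranking gives 1.
#'
#' @param risk_scores numeric risk scores (higher = worse prognosis).
#' @param times,events aligned survival data.
#' @return List with `c_index` (`NA`, with a warning, when no pair is
#'   admissible) and `n_pairs`.
#' @export
concordance_index <- function(risk_scores, times, events) {
  n <- length(times)
  stopifnot(length(risk_scores) == n, length(events) == n)
  dt <- outer(times, times, "<")              # [i, j]: t_i < t_j
  admissible <- dt & matrix(events == 1, n, n)
  n_pairs <- sum(admissible)
  if (n_pairs == 0) {
    warning("no admissible pairs; concordance undefined")
    return(list(c_index = NA_real_, n_pairs = 0L))
  }
  dr <- outer(risk_scores, risk_scores, "-") # [i, j]: r_i - r_j
  credit <- (dr > 0) + 0.5 * (dr == 0)
  list(c_index = sum(credit[admissible]) / n_pairs, n_pairs = n_pairs)
}

#' Proportional-hazards fit (univariate or multivariate)
#'
#' Cox regression via [survival::coxph()] with the Efron approximation
#' for tied event times; hazard ratios with Wald 95% confidence
#' intervals.  In univariate mode each covariate is fitted in its own
#' model; multivariate mode fits them jointly.  Non-convergence or other
#' fitting warnings are captured into the `flag` column rather than
#' failing silently.
#'
#' @param table data frame with `followup_time` and `event` columns (e.g.
#'   the output of [dichotomise()]).
#' @param covariates character vector of covariate column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param conf_level confidence level for the intervals.
#' @return `data.frame(parameter, term, n, hr, ci_lower, ci_upper, p,
#'   mode, flag)` -- one row per non-reference level of each covariate.
#' @export
cox_fit <- function(table, covariates,
                    mode = c("univariate", "multivariate"),
                    conf_level = 0.95) {
  mode <- match.arg(mode)
  df <- as.data.frame(table)
  stopifnot(all(c("followup_time", "event") %in% names(df)),
            all(covariates %in% names(df)))
  if (sum(df$event, na.rm = TRUE) < 1) stop("no events in the data")
  fit_one <- function(covs) {
    sub <- df[complete.cases(df[, c("followup_time", "event", covs)]), ]
    fml <- stats::as.formula(paste(
      "survival::Surv(followup_time, event) ~",
      paste(covs, collapse = " + ")))
    flag <- ""
    fit <- withCallingHandlers(
      survival::coxph(fml, data = sub, ties = "efron"),
      warning = function(w) {
        flag <<- paste(flag, conditionMessage(w), sep = "; ")
        invokeRestart("muffleWarning")
      })
    ci <- suppressMessages(confint(fit, level = conf_level))
    s <- summary(fit)
    rows <- rownames(s$coefficients)
    data.frame(
      parameter = rep(paste(covs, collapse = "+"), length(rows)),
      term = rows,
      n = s$n,
      hr = exp(s$coefficients[, "coef"]),
      ci_lower = exp(ci[, 1]),
      ci_upper = exp(ci[, 2]),
      p = s$coefficients[, "Pr(>|z|)"],
      mode = mode,
      flag = trimws(sub("^;", "", flag)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (mode == "univariate")
    do.call(rbind, lapply(covariates, fit_one))
  else fit_one(covariates)
}
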