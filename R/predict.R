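#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly chosen
#' positive case scores higher than a randomly chosen negative one, ties
#' counting one half.
#'
#' @param scores Numeric predictions (higher = more likely positive).
#' @param labels Logical (or 0/1) outcomes.
#' @return AUROC in `[0, 1]`; 0.5 when the scores are constant.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Wald p-value for a single-covariate logistic fit, falling back to the
# likelihood-ratio test when the fit is separated (divergent estimates make
# the Wald statistic meaningless).
logistic_p <- function(y, x) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  if (!sep && nrow(sm) >= 2 && is.finite(sm[2, 4]) && abs(sm[2, 1]) < 15) {
    list(p = sm[2, 4], or = exp(sm[2, 1]), method = "wald", separated = FALSE)
  } else {
    dev0 <- stats::glm(y ~ 1, family = stats::binomial())$deviance
    p <- stats::pchisq(dev0 - fit$deviance, df = 1, lower.tail = FALSE)
    list(p = p, or = exp(unname(stats::coef(fit)[2])), method = "lrt",
         separated = TRUE)
  }
}

#' Univariate screen of predictors of complete PEEP absorption
#'
#' One logistic regression per candidate covariate; Wald p-values, with a
#' likelihood-ratio fallback when the fit is separated.
#'
#' @param data Analysis data frame.
#' @param outcome Name of the logical outcome column.
#' @param candidates Character vector of candidate covariate names.
#' @param alpha Selection threshold on the p-value (default 0.05).
#' @return A data frame (one row per candidate, sorted by p) with columns
#'   `covariate`, `odds_ratio`, `p_value`, `method`, `selected`.
#' @export
univariate_screen <- function(data, outcome, candidates, alpha = 0.05) {
  missing <- setdiff(c(outcome, candidates), names(data))
  if (length(missing) > 0) {
    stop("columns not found in data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  y <- as.logical(data[[outcome]])
  rows <- lapply(candidates, function(nm) {
    r <- logistic_p(y, as.numeric(data[[nm]]))
    data.frame(covariate = nm, odds_ratio = r$or, p_value = r$p,
               method = r$method, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$selected <- out$p_value < alpha
  out[order(out$p_value), , drop = FALSE]
}

#' Multivariable logistic model with VIF-based collinearity pruning
#'
#' Fits the logistic model on the screened covariates; while any variance
#' inflation factor exceeds `vif_threshold` the worst offender is dropped
#' and the model refitted (the last remaining covariate is never dropped).
#'
#' @param data Analysis data frame.
#' @param outcome Name of the logical outcome column.
#' @param covariates Covariates entering the model.
#' @param vif_threshold VIF above which a covariate is pruned (default 5).
#' @return A list with the final `fit` (a `glm`), `covariates` kept,
#'   `dropped` (named vector of the VIFs at removal) and a `summary` table
#'   of odds ratios with 95 % profile CIs and p-values.
#' @export
fit_multivariable <- function(data, outcome, covariates, vif_threshold = 5) {
  y <- as.logical(data[[outcome]])
  kept <- covariates
  dropped <- numeric(0)
  repeat {
    df <- data.frame(.y = y, lapply(data[kept], as.numeric))
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = df, family = stats::binomial()))
    if (length(kept) < 2) break
    # a perfectly collinear design defeats vif(); drop aliased terms first
    al <- stats::alias(fit)$Complete
    if (!is.null(al)) {
      worst <- sub("^`|`$", "", rownames(al)[1])
      dropped[worst] <- Inf
      kept <- setdiff(kept, worst)
      next
    }
    v <- car::vif(fit)
    if (max(v) <= vif_threshold) break
    worst <- names(which.max(v))
    dropped[worst] <- max(v)
    kept <- setdiff(kept, worst)
  }
  sm <- summary(fit)$coefficients
  ci <- suppressMessages(suppressWarnings(stats::confint(fit)))
  tab <- data.frame(term = rownames(sm)[-1],
                    odds_ratio = exp(sm[-1, 1]),
                    ci_low = exp(ci[-1, 1]), ci_high = exp(ci[-1, 2]),
                    p_value = sm[-1, 4], stringsAsFactors = FALSE)
  list(fit = fit, covariates = kept, dropped = dropped, summary = tab)
}

#' Youden-optimal respiratory-rate threshold
#'
#' Scans the midpoints between consecutive unique respiratory-rate values;
#' a patient is called positive when RR < threshold. The threshold
#' maximizing Youden's J (sensitivity + specificity - 1) is returned, the
#' lowest such threshold on ties.
#'
#' @param rr Respiratory rates, breaths/min.
#' @param outcome Logical outcome (complete absorption).
#' @return A list with `threshold`, `youden`, `sensitivity`, `specificity`
#'   and `informative` (`FALSE` when no threshold beats chance, i.e.
#'   max J <= 0).
#' @export
choose_rr_threshold <- function(rr, outcome) {
  outcome <- as.logical(outcome)
  stopifnot(length(rr) == length(outcome))
  u <- sort(unique(rr))
  if (length(u) < 2) stop("at least two distinct rates required", call. = FALSE)
  cand <- (u[-1] + u[-length(u)]) / 2
  j <- vapply(cand, function(th) {
    pos <- rr < th
    mean(pos[outcome]) + mean(!pos[!outcome]) - 1
  }, 0)
  best <- which.max(j)  # which.max takes the first (lowest) on ties
  th <- cand[best]
  pos <- rr < th
  list(threshold = th, youden = j[best],
       sensitivity = mean(pos[outcome]), specificity = mean(!pos[!outcome]),
       informative = j[best] > 0)
}

#' Bedside probability of complete PEEP absorption
#'
#' Closed-form score from the two bedside predictors: logit(p) =
#' -5 + 3.5 x \[RR < 20\] + 2.9 x \[flow limited\].
#'
#' @param rr_below_threshold Logical: respiratory rate below 20/min.
#' @param flow_limited Logical: bedside flow-limitation verdict.
#' @return Predicted probability of complete absorption.
#' @examples
#' bedside_score(FALSE, FALSE)  # 0.0067
#' bedside_score(TRUE, FALSE)   # 0.182
#' bedside_score(TRUE, TRUE)    # 0.802
#' @export
bedside_score <- function(rr_below_threshold, flow_limited) {
  stats::plogis(-5 + 3.5 * as.numeric(rr_below_threshold) +
                  2.9 * as.numeric(flow_limited))
}

#' Diagnostic accuracy of a binary predictor
#'
#' Sensitivity, specificity, predictive values and their exact 95 %
#' Clopper-Pearson confidence intervals.
#'
#' @param predictor Logical test result.
#' @param outcome Logical reference outcome.
#' @return A data frame with one row per metric: `estimate`, `ci_low`,
#'   `ci_high`, `numerator`, `denominator`.
#' @export
diagnostic_metrics <- function(predictor, outcome) {
  predictor <- as.logical(predictor); outcome <- as.logical(outcome)
  cells <- list(
    sensitivity = c(sum(predictor & outcome), sum(outcome)),
    specificity = c(sum(!predictor & !outcome), sum(!outcome)),
    ppv = c(sum(predictor & outcome), sum(predictor)),
    npv = c(sum(!predictor & !outcome), sum(!predictor)))
  rows <- lapply(names(cells), function(nm) {
    x <- cells[[nm]][1]; n <- cells[[nm]][2]
    if (n == 0) {
      return(data.frame(metric = nm, estimate = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, numerator = x, denominator = n,
                        stringsAsFactors = FALSE))
    }
    ci <- stats::binom.test(x, n)$conf.int
    data.frame(metric = nm, estimate = x / n, ci_low = ci[1], ci_high = ci[2],
               numerator = x, denominator = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Mean absolute difference between predicted probabilities and observed
# event rates. With few distinct predictions (a score taking 3-4 values)
# the observed rate is computed per distinct value; otherwise a loess
# smooth of outcome on prediction is used.
calibration_mae <- function(pred, outcome) {
  outcome <- as.numeric(outcome)
  if (length(unique(round(pred, 10))) < 10) {
    obs <- stats::ave(outcome, round(pred, 10))
    mean(abs(pred - obs))
  } else {
    fit <- suppressWarnings(stats::loess(outcome ~ pred, degree = 1,
                                         span = 0.9))
    mean(abs(pred - pmin(pmax(stats::fitted(fit), 0), 1)))
  }
}

#' Cross-validated performance of a logistic prediction model
#'
#' Stratified k-fold cross-validation: the model is refitted on each
#' training split and out-of-fold probabilities are pooled; the corrected
#' AUROC is computed on the pooled out-of-fold predictions, with a patient
#' bootstrap percentile CI and a calibration mean absolute error.
#'
#' @param data Analysis data frame.
#' @param outcome Name of the logical outcome column.
#' @param covariates Model covariates.
#' @param k Number of folds (default 10).
#' @param n_boot Bootstrap replicates for the AUROC CI (default 2000).
#' @param seed Seed for fold assignment and the bootstrap.
#' @return A list with `auroc_apparent`, `auroc_corrected`, `auroc_ci`,
#'   `calibration_mae`, and the pooled `predictions`.
#' @export
cross_validate <- function(data, outcome, covariates, k = 10, n_boot = 2000,
                           seed = 1) {
  set.seed(as.integer(seed))
  y <- as.logical(data[[outcome]])
  n <- length(y)
  if (k < 2 || k > n) stop("k must lie between 2 and n", call. = FALSE)
  x <- data.frame(lapply(data[covariates], as.numeric))
  df <- data.frame(.y = y, x)
  # stratified fold labels: cycle folds within each outcome class
  fold <- integer(n)
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold == f
    fit <- suppressWarnings(
      stats::glm(.y ~ ., data = df[!test, , drop = FALSE],
                 family = stats::binomial()))
    pred[test] <- suppressWarnings(
      stats::predict(fit, newdata = df[test, , drop = FALSE],
                     type = "response"))
  }
  full <- suppressWarnings(stats::glm(.y ~ ., data = df,
                                      family = stats::binomial()))
  apparent <- auroc(stats::fitted(full), y)
  corrected <- auroc(pred, y)
  ci <- if (n_boot > 0) {
    boot <- vapply(seq_len(n_boot), function(b) {
      i <- sample.int(n, replace = TRUE)
      if (length(unique(y[i])) < 2) return(NA_real_)
      auroc(pred[i], y[i])
    }, 0)
    unname(stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  } else {
    c(NA_real_, NA_real_)
  }
  list(auroc_apparent = apparent,
       auroc_corrected = corrected,
       auroc_ci = ci,
       calibration_mae = calibration_mae(pred, y),
       predictions = pred, folds = fold)
}

#' Multinomial model of the three absorber classes
#'
#' Fits the three-class outcome (complete / high / low) with
#' `nnet::multinom`, using the low-absorber class as the reference.
#'
#' @param data Analysis data frame with a `label` factor column.
#' @param covariates Model covariates.
#' @return A list with the `fit`, the coefficient matrix and a
#'   relative-risk-ratio table.
#' @export
fit_multinomial <- function(data, covariates) {
  lab <- stats::relevel(factor(data$label,
                               levels = c("complete", "high", "low")),
                        ref = "low")
  df <- data.frame(.label = lab, lapply(data[covariates], as.numeric))
  fit <- nnet::multinom(.label ~ ., data = df, trace = FALSE)
  co <- stats::coef(fit)
  list(fit = fit, coefficients = co, rrr = exp(co))
}

#' Between-class comparisons of patient characteristics
#'
#' Continuous covariates are compared across the three absorber classes
#' with one-way ANOVA (Tukey HSD post hoc); binary covariates with the
#' chi-squared test, falling back to Fisher's exact test when an expected
#' cell count is below 5.
#'
#' @param data Analysis data frame with a `label` column.
#' @param covariates Covariates to compare.
#' @return A data frame with `covariate`, `test` and `p_value`; Tukey
#'   results are attached as the `tukey` attribute.
#' @export
group_comparisons <- function(data, covariates) {
  lab <- factor(data$label, levels = c("complete", "high", "low"))
  tukey <- list()
  rows <- lapply(covariates, function(nm) {
    x <- data[[nm]]
    if (is.logical(x) || length(unique(x)) <= 2) {
      tb <- table(as.logical(x), lab)
      ct <- suppressWarnings(stats::chisq.test(tb))
      exp_ok <- all(ct$expected >= 5)
      p <- if (exp_ok) ct$p.value else stats::fisher.test(tb)$p.value
      data.frame(covariate = nm, test = if (exp_ok) "chisq" else "fisher",
                 p_value = p, stringsAsFactors = FALSE)
    } else {
      fit <- stats::aov(as.numeric(x) ~ lab)
      tukey[[nm]] <<- stats::TukeyHSD(fit)$lab
      data.frame(covariate = nm, test = "anova",
                 p_value = summary(fit)[[1]][["Pr(>F)"]][1],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "tukey") <- tukey
  out
}
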