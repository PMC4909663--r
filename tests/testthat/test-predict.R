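# Brute-force pairwise AUROC used as an independent oracle.
auroc_brute <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

test_that("auroc matches the brute-force pairwise oracle (with ties)", {
  set.seed(42)
  for (r in 1:5) {
    y <- runif(60) < 0.4
    x <- round(rnorm(60) + y, 1)   # rounding creates ties
    expect_equal(auroc(x, y), auroc_brute(x, y))
  }
  y <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(auroc(c(2, 3, 0, 1), y), 1)
  expect_equal(auroc(c(0, 1, 2, 3), y), 0)
  expect_equal(auroc(rep(1, 4), y), 0.5)
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "both")
})

test_that("auroc agrees with the pROC reference implementation", {
  set.seed(7)
  y <- runif(200) < 0.35
  x <- rnorm(200) + 1.2 * y
  ref <- as.numeric(pROC::auc(pROC::roc(y, x, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auroc(x, y), ref, tolerance = 1e-12)
})

test_that("univariate screen finds real predictors and skips noise", {
  set.seed(1)
  n <- 300
  d <- data.frame(signal = rnorm(n), noise = rnorm(n))
  d$y <- runif(n) < plogis(-0.5 + 2 * d$signal)
  scr <- univariate_screen(d, "y", c("signal", "noise"))
  expect_true(scr$selected[scr$covariate == "signal"])
  expect_false(scr$selected[scr$covariate == "noise"])
  expect_gt(scr$odds_ratio[scr$covariate == "signal"], 1)
  expect_error(univariate_screen(d, "y", "absent"), "absent")
})

test_that("separated predictors fall back to the likelihood-ratio test", {
  d <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                  y = c(rep(FALSE, 20), rep(TRUE, 20)))
  scr <- univariate_screen(d, "y", "x")
  expect_equal(scr$method, "lrt")
  expect_lt(scr$p_value, 1e-6)
})

test_that("VIF pruning removes collinear covariates but keeps the rest", {
  set.seed(2)
  n <- 200
  d <- data.frame(x1 = rnorm(n), x3 = rnorm(n))
  d$x2 <- 2 * d$x1 + rnorm(n, sd = 0.01)    # near-perfect collinearity
  d$y <- runif(n) < plogis(d$x1 + d$x3)
  mv <- fit_multivariable(d, "y", c("x1", "x2", "x3"))
  expect_length(mv$covariates, 2)
  expect_true("x3" %in% mv$covariates)
  expect_length(intersect(c("x1", "x2"), mv$covariates), 1)
  expect_true(all(car::vif(mv$fit) <= 5))
  # exact collinearity (aliased column) is also handled
  d$x4 <- 2 * d$x1
  mv2 <- fit_multivariable(d, "y", c("x1", "x4", "x3"))
  expect_length(mv2$covariates, 2)
})

test_that("the Youden threshold separates two rate groups at their midpoint", {
  rr <- c(rep(18, 10), rep(22, 10))
  y <- rr == 18
  th <- choose_rr_threshold(rr, y)
  expect_equal(th$threshold, 20)
  expect_equal(th$youden, 1)
  expect_equal(th$sensitivity, 1)
  expect_equal(th$specificity, 1)
  expect_true(th$informative)
  # ties resolve to the lowest optimal threshold
  rr2 <- c(10, 20, 30, 40)
  y2 <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(choose_rr_threshold(rr2, y2)$threshold, 25)
  # an outcome independent of the rate is flagged uninformative
  rr3 <- rep(c(15, 25), 20)
  y3 <- rep(c(TRUE, FALSE, FALSE, TRUE), 10)
  expect_false(choose_rr_threshold(rr3, y3)$informative)
})

test_that("the bedside score equals the closed-form logistic values", {
  expect_equal(bedside_score(FALSE, FALSE), 1 / (1 + exp(5)),
               tolerance = 1e-12)
  expect_equal(bedside_score(TRUE, FALSE), 1 / (1 + exp(5 - 3.5)),
               tolerance = 1e-12)
  expect_equal(bedside_score(FALSE, TRUE), 1 / (1 + exp(5 - 2.9)),
               tolerance = 1e-12)
  expect_equal(bedside_score(TRUE, TRUE), 1 / (1 + exp(5 - 3.5 - 2.9)),
               tolerance = 1e-12)
  expect_equal(round(bedside_score(TRUE, TRUE), 3), 0.802)
  expect_equal(round(bedside_score(FALSE, FALSE), 4), 0.0067)
})

test_that("diagnostic metrics match hand-computed 2x2 tables", {
  # the study's flow-limitation table: complete 32/33 FL, others 29/67 FL
  pred <- c(rep(TRUE, 32), FALSE, rep(TRUE, 29), rep(FALSE, 38))
  truth <- c(rep(TRUE, 33), rep(FALSE, 67))
  dm <- diagnostic_metrics(pred, truth)
  expect_equal(round(dm$estimate, 2), c(0.97, 0.57, 0.52, 0.97))
  # property check against brute-force counting on random tables
  set.seed(3)
  for (r in 1:5) {
    p <- runif(50) < 0.5; t <- runif(50) < 0.5
    if (!any(p) || all(p)) next
    dm2 <- diagnostic_metrics(p, t)
    expect_equal(dm2$estimate[1], sum(p & t) / sum(t))
    expect_equal(dm2$estimate[2], sum(!p & !t) / sum(!t))
    expect_equal(dm2$estimate[3], sum(p & t) / sum(p))
    expect_equal(dm2$estimate[4], sum(!p & !t) / sum(!p))
    ci <- binom.test(sum(p & t), sum(t))$conf.int
    expect_equal(dm2$ci_low[1], ci[1])
    expect_equal(dm2$ci_high[1], ci[2])
  }
})

test_that("cross-validation returns chance AUROC for a useless predictor", {
  set.seed(4)
  d <- data.frame(x = rnorm(200), y = runif(200) < 0.4)
  cv <- cross_validate(d, "y", "x", n_boot = 200, seed = 1)
  expect_lt(abs(cv$auroc_corrected - 0.5), 0.12)
  expect_true(cv$auroc_ci[1] <= cv$auroc_corrected + 1e-9)
  expect_true(cv$auroc_ci[2] >= cv$auroc_corrected - 1e-9)
})

test_that("corrected AUROC does not exceed the apparent AUROC under overfitting", {
  set.seed(5)
  n <- 80
  d <- data.frame(matrix(rnorm(n * 6), n))
  names(d) <- paste0("x", 1:6)
  d$y <- runif(n) < 0.5
  cv <- cross_validate(d, "y", paste0("x", 1:6), n_boot = 100, seed = 2)
  expect_lt(cv$auroc_corrected, cv$auroc_apparent)
})

test_that("pooled out-of-fold predictions are complete and reproducible", {
  set.seed(6)
  d <- data.frame(x = rnorm(150))
  d$y <- runif(150) < plogis(1.5 * d$x)
  cv1 <- cross_validate(d, "y", "x", n_boot = 50, seed = 9)
  cv2 <- cross_validate(d, "y", "x", n_boot = 50, seed = 9)
  expect_identical(cv1$predictions, cv2$predictions)
  expect_true(all(cv1$predictions > 0 & cv1$predictions < 1))
  expect_equal(sort(unique(cv1$folds)), 1:10)
  expect_equal(cv1$auroc_corrected, auroc_brute(cv1$predictions, d$y))
  expect_lt(cv1$calibration_mae, 0.15)
})

test_that("the multinomial model uses low absorbers as reference with sane signs", {
  set.seed(8)
  ch <- generate_cohort(150, seed = 8)
  st <- run_study(ch, seed = 8)
  d <- st$data[st$data$eligible, ]
  d$rr_low <- d$respiratory_rate < 20
  mn <- fit_multinomial(d, c("rr_low", "flow_limited"))
  expect_setequal(rownames(mn$coefficients), c("complete", "high"))
  # flow limitation raises the odds of complete (vs low) absorption
  expect_gt(mn$coefficients["complete", "flow_limited"], 0)
  expect_gt(mn$rrr["complete", "flow_limited"], 1)
})

test_that("group comparisons pick the right test per covariate type", {
  set.seed(9)
  n <- 90
  d <- data.frame(label = rep(c("complete", "high", "low"), each = n / 3),
                  age = rnorm(n, 70, 10),
                  rare = c(rep(TRUE, 2), rep(FALSE, n - 2)),
                  common = runif(n) < 0.5)
  gc <- group_comparisons(d, c("age", "rare", "common"))
  expect_equal(gc$test[gc$covariate == "age"], "anova")
  expect_equal(gc$test[gc$covariate == "rare"], "fisher")
  expect_equal(gc$test[gc$covariate == "common"], "chisq")
  expect_true(all(gc$p_value >= 0 & gc$p_value <= 1))
  expect_true("age" %in% names(attr(gc, "tukey")))
})

test_that("calibration error is small for a well-specified discrete score", {
  set.seed(10)
  n <- 400
  rr <- runif(n) < 0.5; fl <- runif(n) < 0.5
  p <- bedside_score(rr, fl)
  y <- runif(n) < p
  d <- data.frame(rr_low = rr, flow_limited = fl, y = y)
  cv <- cross_validate(d, "y", c("rr_low", "flow_limited"), n_boot = 50,
                       seed = 3)
  expect_lt(cv$calibration_mae, 0.08)
})
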