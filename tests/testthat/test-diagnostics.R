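test_that("rank AUC matches the pairwise definition and known cases", {
  expect_equal(auc_rank(c(3, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 0.875)
  expect_equal(auc_rank(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(auc_rank(rep(4, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(auc_rank(1:4, rep(TRUE, 4)), "both classes")

  set.seed(41)
  for (i in 1:60) {
    n <- sample(5:200, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties
    labels <- runif(n) < 0.4
    if (!any(labels) || all(labels)) next
    a <- auc_rank(scores, labels)
    expect_equal(a, oracle_auc(scores, labels), tolerance = 1e-12)
    # complement identity and monotone-transform invariance
    expect_equal(a + auc_rank(-scores, labels), 1, tolerance = 1e-12)
    expect_equal(auc_rank(exp(scores / 3), labels), a, tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  set.seed(42)
  scores <- rnorm(80)
  labels <- runif(80) < 0.3
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<", quiet = TRUE)))
  expect_equal(auc_rank(scores, labels), as.numeric(ref), tolerance = 1e-12)
})

test_that("Youden cut-off maximises J over observed thresholds", {
  r <- roc_and_youden(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$youden_j, 1.0)
  expect_equal(r$youden_cutoff, 5)  # lowest observed positive score

  r <- roc_and_youden(rep(4, 6), rep(c(TRUE, FALSE), 3))
  expect_equal(r$youden_j, 0)

  r <- roc_and_youden(c(3, 2, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$youden_cutoff, 3)
  expect_equal(r$youden_j, 0.5)
  # sensitivity/specificity at the cut-off reproduce the confusion matrix
  scores <- c(3, 2, 1, 2); labels <- c(TRUE, TRUE, FALSE, FALSE)
  i <- which(r$thresholds == r$youden_cutoff)
  expect_equal(r$sensitivity[i], mean(scores[labels] >= r$youden_cutoff))
  expect_equal(r$specificity[i], mean(scores[!labels] < r$youden_cutoff))
  # curve monotonicity in the cut-off
  expect_true(all(diff(r$sensitivity) <= 0))
  expect_true(all(diff(r$specificity) >= 0))
})

test_that("Mann-Whitney U counts pairs; p-values behave at the extremes", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney(c(4, 5, 6), c(1, 2, 3))$U, 9)
  expect_gt(mann_whitney(c(1, 2, 3, 4), c(1, 2, 3, 4))$p_value, 0.9)
  sep <- mann_whitney(rnorm(20, 10), rnorm(20, 0))
  expect_equal(sep$U, 400)
  expect_lt(sep$p_value, 1e-6)
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")

  set.seed(43)
  for (i in 1:40) {
    x <- sample(round(rnorm(sample(2:12, 1)), 1))
    y <- sample(round(rnorm(sample(2:12, 1)), 1))
    expect_equal(mann_whitney(x, y)$U, oracle_u(x, y), tolerance = 1e-12)
  }
})

test_that("logistic association recovers a 2x2 odds ratio and flags separation", {
  exposure <- rep(c(1, 1, 0, 0), c(10, 5, 5, 10))
  outcome <- rep(c(TRUE, FALSE, TRUE, FALSE), c(10, 5, 5, 10))
  fit <- logistic_association(outcome, exposure)
  expect_false(fit$separation)
  expect_equal(fit$table$odds_ratio[fit$table$term == "predictor"], 4.0,
               tolerance = 1e-4)

  set.seed(44)
  x <- rnorm(2000)
  y <- runif(2000) < 0.3  # independent of x
  fit <- logistic_association(y, x)
  row <- fit$table[fit$table$term == "predictor", ]
  expect_true(row$ci_low < 1 && 1 < row$ci_high)

  xs <- rnorm(60)
  fit <- logistic_association(xs >= 0.2, xs)
  expect_true(fit$separation)
})

test_that("R-squared equals both the correlation and residual formulations", {
  x <- 1:20
  expect_equal(linear_r2(x, 2 * x + 1), 1.0, tolerance = 1e-12)
  x0 <- c(-1, 1, -1, 1); y0 <- c(-1, -1, 1, 1)  # orthogonal
  expect_equal(linear_r2(x0, y0), 0)
  set.seed(45)
  xr <- rnorm(50); yr <- 0.6 * xr + rnorm(50)
  expect_equal(linear_r2(xr, yr), summary(lm(yr ~ xr))$r.squared,
               tolerance = 1e-12)
  expect_error(linear_r2(rep(1, 5), rnorm(5)), "variance")
})

test_that("group summaries use the p(n+1) quartile convention", {
  gs <- group_summary(1:9)
  expect_equal(gs$median, 5)
  expect_equal(gs$q25, 2.5)
  expect_equal(gs$q75, 7.5)
  gs <- group_summary(4.2)
  expect_equal(c(gs$q25, gs$median, gs$q75), rep(4.2, 3))
  set.seed(46)
  v <- rnorm(31)
  expect_identical(group_summary(v), group_summary(sample(v)))
})
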