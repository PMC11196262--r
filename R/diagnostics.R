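#' Rank-based AUC
#'
#' Area under the ROC curve computed as the two-sample rank statistic:
#' the proportion of positive-negative pairs in which the positive scores
#' higher, counting ties as one half. Computed from midranks, which is
#' algebraically identical to the pairwise definition and to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric predictor values (higher = more positive-like).
#' @param labels Logical (or 0/1) outcome labels.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop("scores and labels must be equal-length and complete",
         call. = FALSE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("undefined AUC: both classes must be represented", call. = FALSE)
  r <- rank(scores)  # midranks
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve and Youden-optimal cut-off
#'
#' Sweeps every distinct observed score as a candidate cut-off under the
#' inclusive orientation (test positive when score >= cut-off), records
#' sensitivity and specificity at each, and selects the cut-off
#' maximising Youden's J = sensitivity + specificity - 1. When several
#' cut-offs tie on J, the largest (most specific) is returned; for
#' perfectly separated groups this is the lowest observed positive score,
#' the smallest threshold achieving J = 1.
#'
#' @inheritParams auc_rank
#' @return Object of class `roc_result`: `thresholds` (ascending distinct
#'   scores), `sensitivity`, `specificity`, `auc`, `youden_cutoff`,
#'   `youden_j`.
#' @export
roc_and_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  auc <- auc_rank(scores, labels)  # also validates
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[labels] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[!labels] < t), 0)
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[length(best)]  # ties: largest threshold, most specific
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc, youden_cutoff = thr[best], youden_j = j[best]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC %.3f, Youden cut-off %.4g (J = %.3f)\n",
              x$auc, x$youden_cutoff, x$youden_j))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two independent samples. U counts the
#' pairs in which an `x` value exceeds a `y` value (ties contribute one
#' half), computed via midranks; the p-value uses the normal
#' approximation with tie-corrected variance and continuity correction.
#' Note the orientation: `U = 0` when every `x` is below every `y`, and
#' `U = n_x * n_y` when every `x` is above; the complementary convention
#' is `n_x * n_y - U`.
#'
#' @param x,y Numeric samples.
#' @return List with `U`, `p_value`, and the sample sizes.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  r <- rank(c(x, y))
  nx <- length(x); ny <- length(y)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  p <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  list(U = U, p_value = p, n_x = nx, n_y = ny)
}

#' Binary logistic association with odds ratios
#'
#' Maximum-likelihood logistic regression of a binary outcome on a
#' predictor, optionally adjusted for covariates, reporting coefficients,
#' odds ratios, and Wald 95% confidence intervals. Perfect (or
#' quasi-perfect) separation is detected — fitted probabilities pinned at
#' 0/1 or a diverging coefficient — and flagged on the result rather than
#' raising an error, since a separated fit still identifies the predictor
#' as a perfect classifier even though its odds ratio is unbounded.
#'
#' @param labels Logical (or 0/1) outcome.
#' @param predictor Numeric predictor of interest.
#' @param covariates Optional data frame of adjustment covariates.
#' @return List with `table` (term, coefficient, odds ratio, Wald CI,
#'   p-value per row) and `separation` flag.
#' @export
logistic_association <- function(labels, predictor, covariates = NULL) {
  labels <- as.logical(labels)
  df <- data.frame(.y = labels, predictor = predictor)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 50)),
    warning = function(w) invokeRestart("muffleWarning"))
  co <- summary(fit)$coefficients
  p_hat <- stats::fitted(fit)
  separation <- any(abs(co[-1, "Estimate"]) > 15) ||
    (all(p_hat[labels] > 1 - 1e-8) && all(p_hat[!labels] < 1e-8))
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  tab <- data.frame(term = rownames(co), coefficient = est,
                    odds_ratio = exp(est),
                    ci_low = exp(est - 1.96 * se),
                    ci_high = exp(est + 1.96 * se),
                    p_value = co[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, separation = separation, converged = fit$converged)
}

#' Coefficient of determination of a simple linear regression
#'
#' R-squared of the least-squares line of `y` on `x`, equal to the
#' squared Pearson correlation.
#'
#' @param x,y Numeric vectors, n >= 3, each with positive variance.
#' @return R-squared in \[0, 1\].
#' @export
linear_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length x and y with n >= 3", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("zero variance in x or y", call. = FALSE)
  stats::cor(x, y)^2
}

#' Median and interquartile range of a group
#'
#' Group summary in the clinical reporting style "median (q25, q75)".
#' Quartiles use the weighted-average convention with interpolation index
#' p(n+1) (`stats::quantile` type 6), the method common clinical
#' statistics software applies, so summaries line up with tables produced
#' by such software.
#'
#' @param values Numeric vector, n >= 1.
#' @return List with `n`, `median`, `q25`, `q75`.
#' @export
group_summary <- function(values) {
  if (length(values) < 1 || anyNA(values))
    stop("values must be non-empty and complete", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  list(n = length(values), median = q[2], q25 = q[1], q75 = q[3])
}

format_group_summary <- function(gs, digits = 3) {
  sprintf("%s (%s, %s)", signif(gs$median, digits), signif(gs$q25, digits),
          signif(gs$q75, digits))
}
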