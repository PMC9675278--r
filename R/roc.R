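# ROC analysis, cutoff selection and exact binomial performance intervals.

#' Empirical ROC curve with Mann-Whitney AUC
#'
#' Thresholds are the midpoints between consecutive distinct scores, with
#' -Inf/+Inf sentinels; at each threshold a sample is test-positive when
#' its score strictly exceeds the threshold.  The AUC is computed by pair
#' counting: the fraction of case/control pairs the case wins, ties
#' counting one half (the Mann-Whitney statistic).  Its confidence
#' interval uses the asymptotic normal over the DeLong placement variance
#' (equivalent to DeLong's estimator in the two-class case).
#'
#' @param scores numeric vector of per-sample scores.
#' @param labels logical (or 0/1) vector; `TRUE` marks cases.
#' @param level confidence level for the AUC interval.
#' @return Object of class `roc_curve`: list with `thresholds`, `sens`,
#'   `spec`, `auc`, `auc_ci` (length-2 vector), `n_case`, `n_control`.
#' @examples
#' roc_curve(c(3, 5, 7, 2, 4, 6), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
roc_curve <- function(scores, labels, level = 0.95) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || any(is.na(scores)) ||
      any(is.na(labels))) {
    stop("validation error: scores and labels must be complete and aligned")
  }
  x <- scores[labels]                 # cases
  y <- scores[!labels]                # controls
  n1 <- length(x)
  n0 <- length(y)
  if (n1 == 0 || n0 == 0) {
    stop("validation error: both classes must be present")
  }

  u <- sort(unique(scores))
  thr <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  sens <- vapply(thr, function(t) mean(x > t), numeric(1))
  spec <- vapply(thr, function(t) mean(y <= t), numeric(1))

  # placements: V10[i] = P(case_i beats a control), ties half
  cmp <- outer(x, y, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  v10 <- rowMeans(cmp)
  v01 <- colMeans(cmp)
  auc <- mean(cmp)
  var_auc <- if (n1 > 1 && n0 > 1) {
    stats::var(v10) / n1 + stats::var(v01) / n0
  } else 0
  z <- qnorm(1 - (1 - level) / 2)
  ci <- pmin(pmax(auc + c(-1, 1) * z * sqrt(max(var_auc, 0)), 0), 1)

  structure(list(thresholds = thr, sens = sens, spec = spec,
                 auc = auc, auc_ci = ci, n_case = n1, n_control = n0),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d cases / %d controls, AUC = %.3f (%.3f-%.3f)\n",
              x$n_case, x$n_control, x$auc, x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}

#' Youden-optimal classification cutoff
#'
#' Returns the threshold maximizing Youden's J = sensitivity +
#' specificity - 1.  Ties are broken toward higher specificity, then
#' toward the higher threshold, so a fully degenerate curve (all scores
#' tied, J = 0 everywhere) returns the all-negative sentinel.
#'
#' @param roc a [roc_curve()].
#' @return The selected threshold (a score value).
#' @export
optimal_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$sens + roc$spec - 1
  best <- order(-j, -roc$spec, -roc$thresholds)[1]
  roc$thresholds[best]
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from beta-distribution quantiles, on the percent scale.
#'
#' @param k successes, `0 <= k <= n`.
#' @param n trials, `>= 1`.
#' @param level confidence level in `(0, 1)`.
#' @return Numeric `c(low, high)` in percent; `k = 0` gives `low = 0`,
#'   `k = n` gives `high = 100`.
#' @examples
#' clopper_pearson(32, 37)   # c(71.2, 95.5) at one decimal
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (any(n < 1) || any(k < 0) || any(k > n)) {
    stop("validation error: need 0 <= k <= n, n >= 1")
  }
  if (level <= 0 || level >= 1) {
    stop("validation error: level must lie in (0, 1)")
  }
  a <- 1 - level
  low <- ifelse(k == 0, 0, qbeta(a / 2, k, n - k + 1))
  high <- ifelse(k == n, 1, qbeta(1 - a / 2, k + 1, n - k))
  c(low = unname(low) * 100, high = unname(high) * 100)
}

#' Diagnostic performance at a fixed cutoff
#'
#' Classifies each sample (positive iff score strictly above `cutoff`) and
#' reports sensitivity and specificity with exact binomial intervals.
#'
#' @param scores numeric scores.
#' @param labels logical; `TRUE` marks cases.
#' @param cutoff classification cutoff.
#' @param level confidence level.
#' @return List with `cutoff`, counts `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity` and `specificity` (percent), and `sensitivity_ci` /
#'   `specificity_ci` (`c(low, high)` percent; `NA` for an empty class).
#' @export
performance_at_cutoff <- function(scores, labels, cutoff, level = 0.95) {
  labels <- as.logical(labels)
  pos <- classify_score(scores, cutoff) == "positive"
  tp <- sum(pos & labels)
  fn <- sum(!pos & labels)
  fp <- sum(pos & !labels)
  tn <- sum(!pos & !labels)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  list(cutoff = cutoff, tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens,
       sensitivity_ci = if (tp + fn > 0) clopper_pearson(tp, tp + fn, level)
                        else c(low = NA_real_, high = NA_real_),
       specificity = spec,
       specificity_ci = if (tn + fp > 0) clopper_pearson(tn, tn + fp, level)
                        else c(low = NA_real_, high = NA_real_))
}
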