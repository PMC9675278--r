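# Association tests between clinicopathological parameters and the binary
# methylation call: Fisher's exact test on 2x2 tables, Kruskal-Wallis for
# group-level score comparisons, and the Table-style association report.

#' Fisher's exact test for a 2x2 table (two-sided)
#'
#' Conditional on both margins, the two-sided p is the sum of
#' hypergeometric point probabilities not exceeding that of the observed
#' table (the conventional definition; a relative tolerance of 1e-7 guards
#' against floating-point ties).
#'
#' @param tab 2x2 matrix of non-negative counts; rows are parameter
#'   strata, columns methylation positive/negative.
#' @return Two-sided p value in `(0, 1]`.  A table with a zero row or
#'   column margin carries no information; p = 1 is returned with a
#'   warning.
#' @examples
#' fisher_exact(matrix(c(16, 10, 26, 2), 2, byrow = TRUE))  # ~0.008
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) ||
      any(tab != round(tab)) || any(!is.finite(tab))) {
    stop("validation error: need a 2x2 matrix of non-negative counts")
  }
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warning("degenerate margin in 2x2 table; p = 1 by convention")
    return(1)
  }
  n <- sum(tab)
  # hypergeometric support for the top-left cell with all margins fixed
  k <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- dhyper(k, cs[1], cs[2], rs[1])
  p_obs <- dhyper(tab[1, 1], cs[1], cs[2], rs[1])
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

#' Kruskal-Wallis rank-sum test
#'
#' Rank-based H statistic with the standard tie correction and a
#' chi-square reference distribution on k - 1 degrees of freedom.
#'
#' @param groups list of `>= 2` non-empty numeric vectors.
#' @return List `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("validation error: need >= 2 groups")
  }
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("validation error: every group must be non-empty")
  }
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  n <- length(x)
  if (n < 3) stop("validation error: need total n >= 3")
  r <- rank(x)
  rsum <- tapply(r, g, sum)
  nj <- tabulate(g)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / nj) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- if (corr > 0) h / corr else 0   # all values tied: no evidence
  df <- length(groups) - 1
  list(statistic = h, df = df, p_value = pchisq(h, df, lower.tail = FALSE))
}

#' Clinicopathological association table for one parameter
#'
#' Builds the 2x2 table of parameter stratum vs methylation call among
#' case samples, with per-stratum positivity and the Fisher exact p.
#' Strata follow the standard clinical dichotomies: sex male/female, age
#' below/at-or-above 65, stage Ta-T1 vs T2-T4, grade low vs high (samples
#' with unknown grade are excluded from the grade table).
#'
#' @param samples data.frame with columns `sex`, `age`, `stage`, `grade`
#'   and `call` (`"positive"`/`"negative"`); typically the cancer arm of a
#'   validation cohort.
#' @param parameter one of `"sex"`, `"age"`, `"stage"`, `"grade"`.
#' @param age_cut dichotomization age (years).
#' @return List `parameter`, `strata` (labels), `table` (2x2 matrix, rows
#'   = strata, cols = positive/negative), `n` (per-stratum totals),
#'   `positivity` (percent per stratum), `p_value`.
#' @export
association_table <- function(samples, parameter = c("sex", "age", "stage",
                                                     "grade"),
                              age_cut = 65) {
  parameter <- match.arg(parameter)
  if (!"call" %in% names(samples)) stop("schema error: missing column call")
  ok <- samples$call %in% c("positive", "negative")
  if (!all(ok)) stop("validation error: every sample needs a binary call")

  stratum <- switch(parameter,
    sex = factor(samples$sex, levels = c("male", "female")),
    age = factor(ifelse(samples$age < age_cut,
                        paste0("<", age_cut), paste0(">=", age_cut)),
                 levels = paste0(c("<", ">="), age_cut)),
    stage = factor(ifelse(samples$stage %in% c("Ta", "T1"), "Ta,T1",
                   ifelse(samples$stage %in% c("T2", "T3", "T4"), "T2-T4",
                          NA)),
                   levels = c("Ta,T1", "T2-T4")),
    grade = factor(ifelse(samples$grade %in% c("low", "high"),
                          samples$grade, NA),
                   levels = c("low", "high"))
  )
  keep <- !is.na(stratum)
  if (!any(keep)) {
    stop("validation error: parameter ", parameter,
         " undefined for all samples")
  }
  stratum <- droplevels(stratum[keep])
  pos <- samples$call[keep] == "positive"
  tab <- rbind(tapply(pos, stratum, sum), tapply(!pos, stratum, sum))
  tab[is.na(tab)] <- 0
  tab <- t(tab)
  colnames(tab) <- c("positive", "negative")
  n <- rowSums(tab)
  p <- if (nrow(tab) == 2) fisher_exact(tab) else NA_real_
  list(parameter = parameter, strata = rownames(tab), table = tab,
       n = n, positivity = 100 * tab[, "positive"] / n, p_value = p)
}
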