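# Independent brute-force oracles used across the suite.  These deliberately
# avoid the code paths they check.

# AUC by explicit enumeration of all case/control pairs (wins + half-ties).
auc_bruteforce <- function(scores, labels) {
  x <- scores[as.logical(labels)]
  y <- scores[!as.logical(labels)]
  tot <- 0
  for (a in x) for (b in y) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(x) * length(y))
}

# AUC by trapezoidal integration of the empirical ROC polygon.
auc_trapezoid <- function(roc) {
  fpr <- 1 - roc$spec
  ord <- order(fpr, roc$sens)
  fpr <- fpr[ord]
  sens <- roc$sens[ord]
  sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
}

# Youden cutoff by exhaustive search over every candidate threshold.
cutoff_exhaustive <- function(scores, labels) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best_j <- -Inf; best_spec <- -Inf; best_thr <- -Inf
  for (t in cand) {
    sens <- mean(scores[labels] > t)
    spec <- mean(scores[!labels] <= t)
    j <- sens + spec - 1
    if (j > best_j + 1e-12 ||
        (abs(j - best_j) <= 1e-12 && spec > best_spec + 1e-12) ||
        (abs(j - best_j) <= 1e-12 && abs(spec - best_spec) <= 1e-12 &&
         t > best_thr)) {
      best_j <- j; best_spec <- spec; best_thr <- t
    }
  }
  best_thr
}

# Naive quadratic Benjamini-Hochberg: adjusted_i = min over all j with
# p_j >= p_i of p_j * n / rank_j, capped at 1.
bh_naive <- function(p) {
  n <- length(p)
  cnt <- vapply(p, function(pj) sum(p <= pj), numeric(1))
  vapply(p, function(pi) min(1, min(p[p >= pi] * n / cnt[p >= pi])),
         numeric(1))
}

# Two-sided paired-t p value via numeric integration of the t density.
paired_p_integral <- function(tumor, normal) {
  d <- tumor - normal
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  df <- length(d) - 1
  2 * integrate(function(x) dt(x, df), abs(tstat), Inf,
                rel.tol = 1e-12)$value
}

# Kruskal-Wallis permutation p value for the H statistic.
kw_permutation_p <- function(groups, n_perm = 10000, seed = 1) {
  set.seed(seed)
  x <- unlist(groups)
  sizes <- vapply(groups, length, integer(1))
  h_of <- function(vals) {
    kruskal_wallis(split(vals, rep(seq_along(sizes), sizes)))$statistic
  }
  h_obs <- h_of(x)
  hits <- 0
  for (i in seq_len(n_perm)) {
    if (h_of(sample(x)) >= h_obs - 1e-12) hits <- hits + 1
  }
  hits / n_perm
}
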