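# Diagnostics layer: ROC/AUC, cutoff selection, exact intervals,
# association tests.

test_that("ROC handles the canonical toy cases", {
  # cases (3,5,7) vs controls (2,4,6): 6 wins, no ties among 9 pairs
  r <- roc_curve(c(3, 5, 7, 2, 4, 6),
                 c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r$auc, 6 / 9)
  expect_equal(r$auc, auc_bruteforce(c(3, 5, 7, 2, 4, 6),
                                     c(1, 1, 1, 0, 0, 0)))

  sep <- roc_curve(c(10, 11, 12, 1, 2, 3), c(1, 1, 1, 0, 0, 0))
  expect_equal(sep$auc, 1)

  tied <- roc_curve(rep(5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(tied$auc, 0.5)

  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("pair counting equals trapezoid and brute force on random data", {
  set.seed(101)
  for (i in 1:100) {
    n1 <- sample(3:15, 1)
    n0 <- sample(3:15, 1)
    scores <- c(rnorm(n1, 0.5), rnorm(n0))
    scores <- round(scores, sample(0:2, 1))    # induce ties
    labels <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- roc_curve(scores, labels)
    expect_equal(r$auc, auc_trapezoid(r), tolerance = 1e-9)
    expect_equal(r$auc, auc_bruteforce(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(r$sens) <= 1e-12))    # sens non-increasing
    expect_true(r$auc >= 0 && r$auc <= 1)
    expect_true(r$auc_ci[1] <= r$auc && r$auc <= r$auc_ci[2])
  }
})

test_that("ROC AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  scores <- round(c(rnorm(40, 1), rnorm(60)), 1)
  labels <- rep(c(1, 0), c(40, 60))
  r <- roc_curve(scores, labels)
  pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(unname(r$auc_ci), ci[c(1, 3)], tolerance = 1e-9)
})

test_that("Youden cutoff equals exhaustive search", {
  set.seed(55)
  for (i in 1:50) {
    n1 <- sample(4:12, 1)
    n0 <- sample(4:12, 1)
    scores <- round(c(rnorm(n1, 1.2), rnorm(n0)), 1)
    labels <- rep(c(TRUE, FALSE), c(n1, n0))
    r <- roc_curve(scores, labels)
    expect_equal(optimal_cutoff(r), cutoff_exhaustive(scores, labels))
  }
  # perfectly separated data: the between-class midpoint with J = 1
  sep <- roc_curve(c(8, 9, 1, 2), c(1, 1, 0, 0))
  cut <- optimal_cutoff(sep)
  expect_equal(cut, 5)
  expect_equal(mean(c(8, 9) > cut) + mean(c(1, 2) <= cut) - 1, 1)
  # fully tied scores: the all-negative sentinel
  expect_equal(optimal_cutoff(roc_curve(rep(3, 4), c(1, 1, 0, 0))), Inf)
})

test_that("Clopper-Pearson intervals: boundaries and bracket property", {
  expect_equal(clopper_pearson(0, 10)[["low"]], 0)
  expect_equal(clopper_pearson(10, 10)[["high"]], 100)
  set.seed(8)
  for (i in 1:25) {
    n <- sample(5:200, 1)
    k <- sample(0:n, 1)
    ci <- clopper_pearson(k, n)
    expect_true(ci[["low"]] <= 100 * k / n + 1e-9)
    expect_true(ci[["high"]] >= 100 * k / n - 1e-9)
  }
  expect_error(clopper_pearson(5, 3), "validation")
  # agreement with the exact binomial test's interval
  bt <- binom.test(32, 37)$conf.int * 100
  expect_equal(unname(clopper_pearson(32, 37)), as.numeric(bt),
               tolerance = 1e-9)
})

test_that("Clopper-Pearson achieves nominal coverage in simulation", {
  set.seed(12)
  for (p in c(0.1, 0.5, 0.9)) {
    for (n in c(20, 100)) {
      k <- rbinom(10000, n, p)
      lo <- ifelse(k == 0, 0, qbeta(0.025, k, n - k + 1))
      hi <- ifelse(k == n, 1, qbeta(0.975, k + 1, n - k))
      expect_gte(mean(lo <= p & p <= hi), 0.945)
    }
  }
})

test_that("Fisher exact reproduces published association p values", {
  expect_equal(round(fisher_exact(rbind(c(16, 10), c(26, 2))), 3), 0.008)
  expect_equal(round(fisher_exact(rbind(c(37, 13), c(5, 0))), 3), 0.324)
  expect_equal(round(fisher_exact(rbind(c(32, 11), c(10, 2))), 3), 0.709)
  expect_equal(round(fisher_exact(rbind(c(12, 7), c(30, 6))), 3), 0.109)
})

test_that("Fisher exact matches stats::fisher.test and its invariances", {
  set.seed(20)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact(tab)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-9)
    expect_true(p > 0 && p <= 1)
    # invariant under simultaneous row and column swap
    expect_equal(p, fisher_exact(tab[2:1, 2:1]), tolerance = 1e-12)
  }
  expect_warning(p0 <- fisher_exact(rbind(c(0, 0), c(3, 4))), "degenerate")
  expect_equal(p0, 1)
  expect_error(fisher_exact(rbind(c(-1, 2), c(3, 4))), "validation")
})

test_that("Kruskal-Wallis: hand-ranked oracle, ties, permutation null", {
  # identical groups carry no evidence
  kw0 <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)

  # no-tie case against the rank-sum formula worked by hand:
  # ranks 1..6, R1 = 6, R2 = 15, H = 12/(6*7) * (36/3 + 225/3) - 21
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21)

  # agreement with the standard implementation, with ties
  set.seed(31)
  g <- list(round(rnorm(8), 1), round(rnorm(7, 0.5), 1),
            round(rnorm(9, 1), 1))
  kw2 <- kruskal_wallis(g)
  ref <- kruskal.test(g)
  expect_equal(kw2$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(kw2$p_value, ref$p.value, tolerance = 1e-12)

  # chi-square p within approximation + Monte-Carlo error of a
  # permutation null for a moderate 3-group case
  g3 <- list(c(1.1, 2.3, 0.8, 1.9, 1.4), c(2.8, 3.1, 2.2, 3.5, 2.0),
             c(1.6, 2.5, 1.2, 2.9, 2.1))
  kw3 <- kruskal_wallis(g3)
  expect_lt(abs(kw3$p_value - kw_permutation_p(g3, n_perm = 10000)), 0.03)

  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("association tables reproduce the published validation cohort", {
  fx <- validation_fixture()
  bca <- fx[fx$group == "BCa", ]

  grade <- association_table(bca, "grade")
  expect_equal(round(unname(grade$positivity), 1), c(61.5, 92.9))
  expect_equal(round(grade$p_value, 3), 0.008)
  expect_equal(sum(grade$n), 54)            # unknown grade excluded

  sex <- association_table(bca, "sex")
  expect_equal(unname(sex$table[, "positive"]), c(32, 10))
  expect_equal(round(sex$p_value, 3), 0.709)

  # overall positivity is the column sum over any parameter's strata
  expect_equal(sum(sex$table[, "positive"]) / sum(sex$n), 42 / 55)

  # the stratum positive counts of sex, age and stage partitions all sum
  # to the same 42 of the 55-sample cohort
  for (par in c("sex", "age", "stage")) {
    a <- association_table(bca, par)
    expect_equal(sum(a$table[, "positive"]), 42)
    expect_equal(sum(a$n), 55)
  }

  all_neg <- bca
  all_neg$call <- "negative"
  expect_warning(an <- association_table(all_neg, "sex"), "degenerate")
  expect_equal(unname(an$positivity), c(0, 0))
  expect_equal(an$p_value, 1)
})

test_that("performance at cutoff reproduces published fraction pairs", {
  fx <- validation_fixture()
  eval_set <- fx[fx$group %in% c("BCa", "BUD", "healthy"), ]
  perf <- performance_at_cutoff(eval_set$score, eval_set$group == "BCa",
                                cutoff = 31.35)
  expect_equal(round(perf$sensitivity, 1), 76.4)    # 42/55
  expect_equal(round(perf$specificity, 1), 92.5)    # 98/106
  expect_equal(round(unname(perf$specificity_ci), 1), c(85.7, 96.7))

  # headline stratum: Ta high-grade + T1-T4 vs controls
  head_set <- eval_set[!(eval_set$group == "BCa" & eval_set$stage == "Ta" &
                           eval_set$grade == "low"), ]
  hp <- performance_at_cutoff(head_set$score, head_set$group == "BCa",
                              cutoff = 31.35)
  expect_equal(round(hp$sensitivity, 1), 86.5)      # 32/37
  expect_equal(round(unname(hp$sensitivity_ci), 1), c(71.2, 95.5))

  # empty case stratum reported as undefined, not an error
  none <- performance_at_cutoff(c(20, 35), c(FALSE, FALSE), 31.35)
  expect_true(is.na(none$sensitivity))
  expect_equal(none$specificity, 50)
})
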