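# Candidate-gene selection cascade.

test_that("paired probe test matches a numeric-integration oracle", {
  tumor <- c(2.1, 3.0, 4.2, 5.1, 5.9)
  normal <- c(1.0, 1.2, 2.1, 2.0, 3.1)
  res <- test_probe_paired(tumor, normal)
  expect_equal(res$raw_p, paired_p_integral(tumor, normal),
               tolerance = 1e-9)
  # and the standard implementation agrees
  expect_equal(res$raw_p,
               t.test(tumor, normal, paired = TRUE)$p.value,
               tolerance = 1e-12)
  expect_equal(res$statistic,
               unname(t.test(tumor, normal, paired = TRUE)$statistic),
               tolerance = 1e-12)
})

test_that("paired probe test degenerate inputs", {
  expect_error(test_probe_paired(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  # constant nonzero difference: infinite separation sentinel
  res <- test_probe_paired(c(2, 3, 4), c(1, 2, 3))
  expect_equal(res$raw_p, 0)
  expect_true(is.infinite(res$statistic) && res$statistic > 0)
  # strong separation with jitter
  set.seed(1)
  normal <- rnorm(9)
  res2 <- test_probe_paired(normal + 5 + rnorm(9, 0, 1e-3), normal)
  expect_lt(res2$raw_p, 1e-6)
  expect_error(test_probe_paired(1, 1), "pairs")
})

test_that("Benjamini-Hochberg matches hand-computed and naive oracles", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(benjamini_hochberg(0.37), 0.37)
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(42)
  for (i in 1:20) {
    p <- round(runif(30), 3)   # rounding forces ties
    adj <- benjamini_hochberg(p)
    expect_equal(adj, bh_naive(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12) && all(adj <= 1))
    # monotone: ordering of adjusted respects ordering of raw
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("selection recovers planted genes and respects direction", {
  cfg <- array_sim_config(n_gene_total = 200, n_planted_genes = 9,
                          probes_per_gene = 4, min_planted_probes = 2,
                          effect_size = 1.5, noise_sd = 0.5, n_pairs = 9,
                          seed = 1)
  ds <- generate_array_dataset(cfg)
  cand <- select_candidates(ds)
  expect_setequal(cand$gene_id, ds$planted_genes)

  # swapping tumor/normal gives hypomethylation: nothing selected
  swapped <- ds
  swapped$tumor <- ds$normal
  swapped$normal <- ds$tumor
  expect_equal(nrow(select_candidates(swapped)), 0)
})

test_that("selection is invariant to probe order and monotone in thresholds", {
  cfg <- array_sim_config(n_gene_total = 80, n_planted_genes = 6,
                          seed = 13)
  ds <- generate_array_dataset(cfg)
  perm <- sample(nrow(ds$probes))
  shuf <- ds
  shuf$probes <- ds$probes[perm, ]
  shuf$tumor <- ds$tumor[perm, ]
  shuf$normal <- ds$normal[perm, ]
  expect_equal(select_candidates(ds), select_candidates(shuf))

  base <- select_candidates(ds, alpha = 0.01, fc_min = 2, min_probes = 2)
  expect_true(all(select_candidates(ds, alpha = 0.001)$gene_id %in%
                    base$gene_id))
  expect_true(all(select_candidates(ds, fc_min = 3)$gene_id %in%
                    base$gene_id))
  expect_true(all(select_candidates(ds, min_probes = 3)$gene_id %in%
                    base$gene_id))
})

test_that("min_probes boundary acts on single-probe genes", {
  # two genes x two probes, 6 pairs; only probe 1 of gene A separates
  probes <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                       gene_id = c("A", "A", "B", "B"),
                       reliable = TRUE, stringsAsFactors = FALSE)
  set.seed(7)
  normal <- matrix(rnorm(24, 0, 0.3), 4)
  tumor <- normal + matrix(rnorm(24, 0, 0.3), 4)
  tumor[1, ] <- normal[1, ] + 3
  ds <- structure(list(probes = probes, pair_ids = paste0("pr", 1:6),
                       tumor = tumor, normal = normal,
                       planted_genes = "A", config = NULL),
                  class = "array_dataset")
  expect_equal(select_candidates(ds, min_probes = 1)$gene_id, "A")
  expect_equal(nrow(select_candidates(ds, min_probes = 2)), 0)
})

test_that("null arrays yield (almost) no selected genes", {
  hits <- vapply(1:10, function(s) {
    ds <- generate_array_dataset(array_sim_config(
      n_gene_total = 200, n_planted_genes = 0, effect_size = 0, seed = s))
    nrow(select_candidates(ds))
  }, numeric(1))
  expect_lte(sum(hits > 0), 2)   # >= 8 of 10 null seeds select nothing
})

test_that("empty reliable set returns empty result with a warning", {
  ds <- generate_array_dataset(array_sim_config(n_gene_total = 10,
                                                n_planted_genes = 2,
                                                seed = 1))
  ds$probes$reliable <- FALSE
  expect_warning(res <- probe_test_table(ds), "reliable")
  expect_equal(nrow(res), 0)
})
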