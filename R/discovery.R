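# Candidate-gene selection from paired tumor/nontumor arrays.
#
# The cascade: restrict to reliable probes; per-probe paired differential
# test; Benjamini-Hochberg correction; keep probes that are significant,
# hypermethylated in the tumor direction and above a fold-change floor;
# report genes supported by at least `min_probes` such "positive-call"
# probes.  With two conditions measured on the same specimens, the
# parametric ANOVA of a paired two-condition design reduces to the paired
# t-test, which is what the per-probe test computes.

#' Paired differential test for one probe
#'
#' Two-sided paired t-test of mean(tumor - normal) = 0 across specimen
#' pairs.
#'
#' @param tumor,normal numeric vectors of per-pair log-ratios, equal
#'   length `>= 2`.
#' @return List with `statistic` (paired t), `raw_p` (two-sided), `df`.
#'   If the differences have zero variance but a nonzero mean, the
#'   separation is infinite and `raw_p = 0` is returned with an infinite
#'   statistic (documented sentinel).  Zero variance with zero mean is a
#'   degenerate input and raises an error.
#' @examples
#' test_probe_paired(c(2, 3, 4, 5, 6), c(1, 1, 2, 2, 3))
#' @export
test_probe_paired <- function(tumor, normal) {
  if (length(tumor) != length(normal)) {
    stop("tumor and normal must have one value per specimen pair")
  }
  if (length(tumor) < 2) stop("need >= 2 specimen pairs")
  if (any(!is.finite(tumor)) || any(!is.finite(normal))) {
    stop("non-finite log-ratio values")
  }
  d <- tumor - normal
  m <- mean(d)
  s <- sd(d)
  n <- length(d)
  if (s == 0) {
    if (m == 0) {
      stop("degenerate input: tumor and normal are identical across pairs")
    }
    return(list(statistic = sign(m) * Inf, raw_p = 0, df = n - 1))
  }
  t <- m / (s / sqrt(n))
  list(statistic = t, raw_p = 2 * pt(-abs(t), df = n - 1), df = n - 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up adjustment (delegates to [stats::p.adjust()] after
#' input validation): sort ascending, multiply `p_(i)` by `n/i`, take the
#' cumulative minimum from the largest rank down, cap at 1.
#'
#' @param raw_ps numeric vector of p values in `[0, 1]`.
#' @return Adjusted p values, in the input order.
#' @export
benjamini_hochberg <- function(raw_ps) {
  if (length(raw_ps) == 0) return(numeric(0))
  if (any(!is.finite(raw_ps)) || any(raw_ps < 0) || any(raw_ps > 1)) {
    stop("validation error: p values must be finite and in [0, 1]")
  }
  stats::p.adjust(raw_ps, method = "BH")
}

# Vectorised paired t over the rows of two matrices; used internally so
# whole-array screens do not loop over stats::t.test.
paired_t_rows <- function(tumor, normal) {
  d <- tumor - normal
  n <- ncol(d)
  m <- rowMeans(d)
  s <- sqrt(rowSums((d - m)^2) / (n - 1))
  t <- ifelse(s == 0, sign(m) * Inf, m / (s / sqrt(n)))
  p <- ifelse(is.infinite(t), 0, 2 * pt(-abs(t), df = n - 1))
  p[is.infinite(t) & m == 0] <- NA_real_   # degenerate rows
  list(statistic = t, raw_p = p)
}

#' Per-probe differential-methylation test table
#'
#' Runs the paired test, BH correction and fold-change computation for
#' every reliable probe of a dataset.  Fold change is the ratio of mean
#' tumor to mean nontumor enrichment on the linear scale
#' (`mean(2^logratio)`).
#'
#' @param ds an `array_dataset` (see [generate_array_dataset()]).
#' @param alpha significance threshold applied to the adjusted p.
#' @param fc_min minimum linear fold change (`> 1`).
#' @return A data.frame with one row per reliable probe: `probe_id`,
#'   `gene_id`, `statistic`, `raw_p`, `adjusted_p`, `fold_change`,
#'   `positive_call`.
#' @export
probe_test_table <- function(ds, alpha = 0.01, fc_min = 2.0) {
  stopifnot(inherits(ds, "array_dataset"))
  keep <- ds$probes$reliable
  if (!any(keep)) {
    warning("empty reliable-probe set; no probes tested")
    return(data.frame(probe_id = character(0), gene_id = character(0),
                      statistic = numeric(0), raw_p = numeric(0),
                      adjusted_p = numeric(0), fold_change = numeric(0),
                      positive_call = logical(0)))
  }
  tum <- ds$tumor[keep, , drop = FALSE]
  nor <- ds$normal[keep, , drop = FALSE]
  tt <- paired_t_rows(tum, nor)
  adj <- benjamini_hochberg(tt$raw_p)
  fc <- rowMeans(2^tum) / rowMeans(2^nor)
  hyper <- rowMeans(tum) > rowMeans(nor)
  data.frame(
    probe_id = ds$probes$probe_id[keep],
    gene_id = ds$probes$gene_id[keep],
    statistic = tt$statistic,
    raw_p = tt$raw_p,
    adjusted_p = adj,
    fold_change = fc,
    positive_call = !is.na(adj) & adj < alpha & fc >= fc_min & hyper,
    stringsAsFactors = FALSE
  )
}

#' Select candidate genes by the multi-probe enrichment rule
#'
#' Full selection cascade: reliable probes only, paired test, BH at
#' `alpha`, hypermethylation direction, fold change `>= fc_min`; genes with
#' at least `min_probes` positive-call probes are returned, ranked by
#' number of positive probes and then mean fold change of those probes
#' (ties broken by gene id for determinism).
#'
#' @param ds an `array_dataset`.
#' @param alpha adjusted-p threshold in `(0, 1)`.
#' @param fc_min minimum linear fold change, `> 1`.
#' @param min_probes minimum positive probes per selected gene, `>= 1`.
#' @return A data.frame `gene_id`, `n_positive_probes`, `best_adjusted_p`,
#'   `mean_fold_change`, `member_probes` (semicolon-joined probe ids),
#'   sorted by rank.
#' @export
select_candidates <- function(ds, alpha = 0.01, fc_min = 2.0,
                              min_probes = 2L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (fc_min <= 1) stop("fc_min must be > 1")
  if (min_probes < 1) stop("min_probes must be >= 1")
  tab <- probe_test_table(ds, alpha = alpha, fc_min = fc_min)
  pos <- tab[tab$positive_call, , drop = FALSE]
  empty <- data.frame(gene_id = character(0), n_positive_probes = integer(0),
                      best_adjusted_p = numeric(0),
                      mean_fold_change = numeric(0),
                      member_probes = character(0), stringsAsFactors = FALSE)
  if (nrow(pos) == 0) return(empty)
  sp <- split(pos, pos$gene_id)
  res <- do.call(rbind, lapply(sp, function(g) {
    data.frame(gene_id = g$gene_id[1],
               n_positive_probes = nrow(g),
               best_adjusted_p = min(g$adjusted_p),
               mean_fold_change = mean(g$fold_change),
               member_probes = paste(sort(g$probe_id), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  res <- res[res$n_positive_probes >= min_probes, , drop = FALSE]
  if (nrow(res) == 0) return(empty)
  res <- res[order(-res$n_positive_probes, -res$mean_fold_change,
                   res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
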