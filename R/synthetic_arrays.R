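# Synthetic paired tumor/nontumor CpG-array datasets.
#
# The generator starts at normalised methylation-enrichment log2 ratios
# (image processing and dye normalisation are upstream concerns).  A
# "planted" gene is one whose probes carry a hypermethylation shift in the
# tumor channel; planted identities are recorded as ground truth so that
# selection procedures can be benchmarked.

#' Configuration for a simulated paired-array experiment
#'
#' @param n_gene_total number of genes on the array.
#' @param n_planted_genes number of genes carrying a hypermethylation shift
#'   (`<= n_gene_total`).
#' @param probes_per_gene probes tiling each gene's CpG island (`>= 1`).
#' @param n_pairs number of tumor/nontumor specimen pairs.
#' @param effect_size mean log2-ratio shift added to the tumor channel of
#'   planted probes (`>= 0`).
#' @param noise_sd marginal SD of each probe log-ratio (`> 0`).
#' @param min_planted_probes guaranteed minimum number of shifted probes per
#'   planted gene; must not exceed `probes_per_gene`.
#' @param pair_cor correlation between the tumor and nontumor log-ratios of
#'   a probe within a pair, induced by a shared specimen/hybridisation
#'   component.  Paired specimens from one patient share probe affinity and
#'   background methylation, so the default is 0.5.
#' @param seed integer seed.
#' @return An object of class `array_sim_config`.
#' @export
array_sim_config <- function(n_gene_total = 200L, n_planted_genes = 9L,
                             probes_per_gene = 4L, n_pairs = 9L,
                             effect_size = 1.5, noise_sd = 0.5,
                             min_planted_probes = 2L, pair_cor = 0.5,
                             seed = 1L) {
  if (n_planted_genes > n_gene_total) {
    stop("configuration error: n_planted_genes (", n_planted_genes,
         ") exceeds n_gene_total (", n_gene_total, ")")
  }
  if (effect_size < 0) stop("configuration error: effect_size must be >= 0")
  if (noise_sd <= 0) stop("configuration error: noise_sd must be > 0")
  if (probes_per_gene < 1) {
    stop("configuration error: probes_per_gene must be >= 1")
  }
  if (min_planted_probes > probes_per_gene) {
    stop("configuration error: min_planted_probes (", min_planted_probes,
         ") exceeds probes_per_gene (", probes_per_gene, ")")
  }
  if (n_pairs < 2) stop("configuration error: n_pairs must be >= 2")
  if (pair_cor < 0 || pair_cor >= 1) {
    stop("configuration error: pair_cor must lie in [0, 1)")
  }
  structure(
    list(n_gene_total = as.integer(n_gene_total),
         n_planted_genes = as.integer(n_planted_genes),
         probes_per_gene = as.integer(probes_per_gene),
         n_pairs = as.integer(n_pairs),
         effect_size = effect_size, noise_sd = noise_sd,
         min_planted_probes = as.integer(min_planted_probes),
         pair_cor = pair_cor, seed = as.integer(seed)),
    class = "array_sim_config"
  )
}

#' Generate a paired tumor/nontumor array dataset
#'
#' Probe log-ratios are drawn as `shared + channel noise`, where the shared
#' per-probe, per-pair component (variance `pair_cor * noise_sd^2`) models
#' specimen- and probe-level effects common to both channels of a pair, and
#' the channel noise (variance `(1 - pair_cor) * noise_sd^2`) is
#' independent.  Marginally each log-ratio has SD `noise_sd`.  Planted genes
#' have every probe shifted upward by `effect_size` in the tumor channel —
#' a CpG-island methylation event raises all probes tiling the island —
#' which guarantees at least `min_planted_probes` shifted probes per planted
#' gene.  Each specimen pair has its own random substream.
#'
#' @param cfg an [array_sim_config()].
#' @return An object of class `array_dataset`: a list with `probes` (a
#'   data.frame of `probe_id`, `gene_id`, `reliable`), `pair_ids`, matrices
#'   `tumor` and `normal` (probe x pair), and `planted_genes` (ground
#'   truth).
#' @export
generate_array_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "array_sim_config"))
  n_probe <- cfg$n_gene_total * cfg$probes_per_gene
  gene_ids <- sprintf("G%04d", seq_len(cfg$n_gene_total))
  probes <- data.frame(
    probe_id = sprintf("P%05d", seq_len(n_probe)),
    gene_id = rep(gene_ids, each = cfg$probes_per_gene),
    reliable = TRUE,
    stringsAsFactors = FALSE
  )
  planted <- gene_ids[seq_len(cfg$n_planted_genes)]
  shift <- ifelse(probes$gene_id %in% planted, cfg$effect_size, 0)

  sd_shared <- cfg$noise_sd * sqrt(cfg$pair_cor)
  sd_chan <- cfg$noise_sd * sqrt(1 - cfg$pair_cor)
  draw_pair <- function(j) {
    with_substream(cfg$seed, j, stream = 0L, {
      b <- rnorm(n_probe, 0, sd_shared)
      cbind(tumor = b + shift + rnorm(n_probe, 0, sd_chan),
            normal = b + rnorm(n_probe, 0, sd_chan))
    })
  }
  cols <- lapply(seq_len(cfg$n_pairs), draw_pair)
  tumor <- vapply(cols, function(m) m[, "tumor"], numeric(n_probe))
  normal <- vapply(cols, function(m) m[, "normal"], numeric(n_probe))
  pair_ids <- sprintf("pair%02d", seq_len(cfg$n_pairs))
  colnames(tumor) <- colnames(normal) <- pair_ids
  rownames(tumor) <- rownames(normal) <- probes$probe_id

  structure(
    list(probes = probes, pair_ids = pair_ids,
         tumor = tumor, normal = normal,
         planted_genes = planted, config = cfg),
    class = "array_dataset"
  )
}

#' @export
print.array_dataset <- function(x, ...) {
  cat("Paired CpG-array dataset:", nrow(x$probes), "probes /",
      length(unique(x$probes$gene_id)), "genes x", length(x$pair_ids),
      "tumor/nontumor pairs\n")
  cat("Planted hypermethylated genes:", length(x$planted_genes), "\n")
  invisible(x)
}
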