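# Bisulfite-pyrosequencing methylation index (MtI).
#
# Pyrosequencing reports, for each interrogated CpG of an amplicon, the
# methylated-cytosine fraction mC/(mC + C).  The gene-level methylation
# index is the arithmetic mean of those fractions, expressed as a percent.

#' Compute the methylation index for one sample/gene
#'
#' @param cpg_fractions numeric vector of per-CpG methylated fractions,
#'   each in `[0, 1]`, length `>= 1`.
#' @return MtI on the percent scale: `100 * mean(cpg_fractions)`.
#' @examples
#' compute_mti(c(0.2, 0.4, 0.6))  # 40
#' @export
compute_mti <- function(cpg_fractions) {
  if (length(cpg_fractions) < 1) {
    stop("validation error: need at least one CpG fraction")
  }
  if (any(!is.finite(cpg_fractions)) || any(cpg_fractions < 0) ||
      any(cpg_fractions > 1)) {
    stop("validation error: CpG fractions must lie in [0, 1]")
  }
  100 * mean(cpg_fractions)
}

#' Per-sample, per-gene MtI table from a pyrosequencing export
#'
#' @param pyro a data.frame with columns `sample_id`, `gene`,
#'   `methylated_fraction` (and any others, ignored).
#' @return A data.frame `sample_id`, `gene`, `mti` (percent), one row per
#'   sample/gene combination, ordered by sample then gene.
#' @export
mti_table <- function(pyro) {
  need <- c("sample_id", "gene", "methylated_fraction")
  miss <- setdiff(need, names(pyro))
  if (length(miss)) {
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "))
  }
  if (any(pyro$methylated_fraction < 0 | pyro$methylated_fraction > 1)) {
    stop("validation error: CpG fractions must lie in [0, 1]")
  }
  agg <- aggregate(methylated_fraction ~ sample_id + gene, data = pyro,
                   FUN = mean)
  out <- data.frame(sample_id = agg$sample_id, gene = agg$gene,
                    mti = 100 * agg$methylated_fraction,
                    stringsAsFactors = FALSE)
  out[order(out$sample_id, out$gene), , drop = FALSE]
}

#' Tissue-level methylation-positive call
#'
#' A patient's gene is called methylation-positive when the primary-tumor
#' MtI strictly exceeds the matched nontumor MtI.
#'
#' @param tumor,nontumor lists or data.frame rows with fields `gene_id`
#'   (or `gene`) and `mti`, from the same patient pair.
#' @return Logical.
#' @export
call_tissue_positive <- function(tumor, nontumor) {
  gene_of <- function(x) if (!is.null(x$gene_id)) x$gene_id else x$gene
  if (!identical(gene_of(tumor), gene_of(nontumor))) {
    stop("validation error: tumor and nontumor profiles are for different ",
         "genes (", gene_of(tumor), " vs ", gene_of(nontumor), ")")
  }
  isTRUE(tumor$mti > nontumor$mti)
}

#' Pyrosequencing batch QC on no-template controls
#'
#' Every pyrosequencing run includes no-template negative controls; a
#' control reporting any CpG fraction above `max_fraction` signals
#' contamination or assay failure and fails the batch.
#'
#' @param pyro data.frame with columns `sample_id`, `methylated_fraction`
#'   and logical `is_control`.
#' @param max_fraction tolerated control fraction (default 0.05).
#' @return List: `pass` (logical), `failed_controls` (character vector of
#'   offending control sample ids).
#' @export
qc_pyro_controls <- function(pyro, max_fraction = 0.05) {
  if (!"is_control" %in% names(pyro)) {
    stop("schema error: missing column is_control")
  }
  ctrl <- pyro[pyro$is_control, , drop = FALSE]
  bad <- unique(ctrl$sample_id[ctrl$methylated_fraction > max_fraction])
  list(pass = length(bad) == 0, failed_controls = bad)
}
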