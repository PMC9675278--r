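# Synthetic pyrosequencing cohorts.
#
# The generator emulates per-sample, per-gene methylation indices (MtI, on
# the 0-100 percent scale) for urine-sediment cohorts.  Group-level targets
# are the published mean +/- SD summaries; draws come from a [0,100]
# truncated normal whose post-truncation moments are calibrated to those
# targets (see calibrate_truncnorm).

#' Default urine-cohort MtI calibration table
#'
#' Published group summaries (mean +/- SD of MtI percent) for the three
#' pyrosequencing-verified genes in urine sediment DNA, by cohort: healthy
#' controls, benign urologic disease (BUD) patients, and bladder cancer
#' (BCa) patients.  `n` is the corresponding verification-cohort size.
#'
#' @return A data.frame with columns `group`, `gene`, `target_mean`,
#'   `target_sd`, `n`.
#' @export
mti_calibration_defaults <- function() {
  data.frame(
    group = rep(c("healthy", "BUD", "BCa"), each = 3),
    gene = rep(c("DMC1", "PENK", "SIM2"), times = 3),
    target_mean = c(10.7, 6.4, 7.5,
                    20.9, 13.3, 22.6,
                    33.6, 51.0, 45.4),
    target_sd = c(9.0, 5.4, 3.7,
                  13.6, 9.9, 14.2,
                  25.4, 23.2, 21.6),
    n = rep(c(12L, 23L, 16L), each = 3),
    stringsAsFactors = FALSE
  )
}

#' Specification for one simulated MtI cohort
#'
#' @param group_label cohort label, one of `"healthy"`, `"BUD"`, `"BCa"`.
#' @param gene gene identifier.
#' @param target_mean desired cohort mean MtI, percent in `[0, 100]`.
#' @param target_sd desired cohort SD, percent, `> 0`.
#' @param n number of samples, `>= 1`.
#' @param seed integer seed for the cohort's random stream.
#' @return An object of class `mti_cohort_spec`.
#' @export
mti_cohort_spec <- function(group_label, gene, target_mean, target_sd, n,
                            seed = 1L) {
  if (!group_label %in% c("healthy", "BUD", "BCa")) {
    stop("configuration error: group_label must be healthy, BUD or BCa")
  }
  if (target_mean < 0 || target_mean > 100) {
    stop("configuration error: target_mean must lie in [0, 100]")
  }
  if (target_sd <= 0) stop("configuration error: target_sd must be > 0")
  if (n < 1) stop("configuration error: n must be >= 1")
  structure(
    list(group_label = group_label, gene = gene,
         target_mean = target_mean, target_sd = target_sd,
         n = as.integer(n), seed = as.integer(seed)),
    class = "mti_cohort_spec"
  )
}

#' Generate a calibrated MtI cohort
#'
#' Draws `spec$n` per-sample MtI values from a `[0, 100]` truncated normal
#' whose post-truncation mean and SD match `spec$target_mean` /
#' `spec$target_sd`.  Each sample has its own random substream, so enlarging
#' a cohort never changes the values already drawn for earlier samples.
#'
#' @param spec an [mti_cohort_spec()].
#' @return Numeric vector of MtI values (percent), all in `[0, 100]`.
#' @examples
#' x <- generate_mti_cohort(mti_cohort_spec("BCa", "PENK", 51.0, 23.2, 1000,
#'                                          seed = 7))
#' mean(x)  # ~ 51
#' @export
generate_mti_cohort <- function(spec) {
  stopifnot(inherits(spec, "mti_cohort_spec"))
  par <- calibrate_truncnorm(spec$target_mean, spec$target_sd)
  vapply(seq_len(spec$n), function(i) {
    with_substream(spec$seed, i, stream = 0L,
                   rtruncnorm_(1L, par$mu, par$sigma, par$lo, par$hi))
  }, numeric(1))
}

#' Simulate a full pyrosequencing table for several cohorts
#'
#' Expands per-cohort MtI draws into a per-CpG table of methylated
#' fractions, the raw form a pyrosequencing run exports.  Each sample/gene
#' gets `n_cpg` CpG fractions whose mean equals the drawn MtI (fractions are
#' jittered around the MtI and renormalised, staying in `[0, 1]`).
#'
#' @param specs list of [mti_cohort_spec()] objects.
#' @param n_cpg CpG sites per amplicon (assay designs interrogate 3-5).
#' @param cpg_jitter_sd SD of the per-CpG spread around the gene MtI, on the
#'   fraction scale.
#' @return A data.frame with columns `sample_id`, `group`, `gene`,
#'   `cpg_index`, `methylated_fraction`.
#' @export
simulate_pyro_table <- function(specs, n_cpg = 4L, cpg_jitter_sd = 0.03) {
  stopifnot(length(specs) >= 1, n_cpg >= 1)
  out <- lapply(seq_along(specs), function(k) {
    spec <- specs[[k]]
    mti <- generate_mti_cohort(spec)
    rows <- lapply(seq_len(spec$n), function(i) {
      frac <- with_substream(spec$seed, i, stream = 1L, {
        f <- mti[i] / 100 + rnorm(n_cpg, 0, cpg_jitter_sd)
        f <- pmin(pmax(f, 0), 1)
        # recentre so the per-gene mean equals the drawn MtI exactly when
        # no clipping occurred
        f + (mti[i] / 100 - mean(f)) * (min(f) > 0 && max(f) < 1)
      })
      data.frame(
        sample_id = sprintf("%s_%s_%03d", spec$group_label, spec$gene, i),
        group = spec$group_label,
        gene = spec$gene,
        cpg_index = seq_len(n_cpg),
        methylated_fraction = pmin(pmax(frac, 0), 1),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}
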