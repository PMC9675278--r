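# Synthetic qMSP cycle-threshold cohorts.
#
# Each simulated sample is first assigned methylation-positive status by a
# Bernoulli draw at the stratum's positivity; CT pairs are then drawn so
# that positives score above the classification cutoff and negatives below
# it (or drop out entirely).  The reference gene is always detected within
# the reference-QC bound, emulating specimens with adequate
# bisulfite-converted DNA.

#' Specification for one simulated qMSP stratum
#'
#' @param group_label cohort/stage/grade stratum label (free text, e.g.
#'   `"BCa_TaLG"`, `"healthy"`).
#' @param n number of samples.
#' @param positivity probability in `[0, 1]` that a sample scores above the
#'   classification cutoff.
#' @param detected_ct_target_mean,detected_ct_target_sd cycles; location and
#'   spread of the target-gene CT for methylation-positive samples.
#' @param reference_ct_mean,reference_ct_sd cycles; reference-gene CT
#'   distribution.
#' @param dropout_prob probability that a methylation-negative sample has an
#'   undetected target CT (the remainder get detected CT pairs scoring below
#'   the cutoff).
#' @param cohort,stage,grade,sex,age optional sample-sheet metadata applied
#'   to every sample in the stratum (`NA` where not applicable).
#' @param seed integer seed.
#' @return An object of class `qmsp_sim_spec`.
#' @export
qmsp_sim_spec <- function(group_label, n, positivity,
                          detected_ct_target_mean = 33,
                          detected_ct_target_sd = 2.5,
                          reference_ct_mean = 30, reference_ct_sd = 1.5,
                          dropout_prob = 0.8,
                          cohort = NA_character_, stage = NA_character_,
                          grade = NA_character_, sex = NA_character_,
                          age = NA_real_, seed = 1L) {
  if (positivity < 0 || positivity > 1) {
    stop("configuration error: positivity must lie in [0, 1]")
  }
  if (n < 1) stop("configuration error: n must be >= 1")
  for (m in c(detected_ct_target_mean, reference_ct_mean)) {
    if (m <= 0 || m >= 40) {
      stop("configuration error: CT means must lie in (0, 40)")
    }
  }
  if (dropout_prob < 0 || dropout_prob > 1) {
    stop("configuration error: dropout_prob must lie in [0, 1]")
  }
  structure(
    list(group_label = group_label, n = as.integer(n),
         positivity = positivity,
         detected_ct_target_mean = detected_ct_target_mean,
         detected_ct_target_sd = detected_ct_target_sd,
         reference_ct_mean = reference_ct_mean,
         reference_ct_sd = reference_ct_sd,
         dropout_prob = dropout_prob,
         cohort = cohort, stage = stage, grade = grade, sex = sex,
         age = age, seed = as.integer(seed)),
    class = "qmsp_sim_spec"
  )
}

#' Generate a qMSP CT cohort for one stratum
#'
#' Positives receive detected CT pairs whose 40-deltaCT score strictly
#' exceeds `cutoff`; negatives receive an undetected target CT with
#' probability `dropout_prob` and a detected below-cutoff CT pair
#' otherwise.  Reference CT is always detected and kept within
#' `(0, ref_ct_max]`.  Per-sample substreams make the cohort extensible
#' without perturbing earlier samples.
#'
#' @param spec a [qmsp_sim_spec()].
#' @param cutoff classification cutoff on the 40-deltaCT scale.
#' @param ref_ct_max reference-gene QC bound (cycles).
#' @return A data.frame with columns `sample_id`, `group`, `cohort`,
#'   `stage`, `grade`, `sex`, `age`, `ct_target`, `ct_reference`,
#'   `target_detected`, `reference_detected`, `true_positive`.
#' @export
generate_qmsp_cohort <- function(spec, cutoff = 31.35, ref_ct_max = 38) {
  stopifnot(inherits(spec, "qmsp_sim_spec"))
  if (cutoff <= 0 || cutoff >= 40) {
    stop("configuration error: cutoff must lie in (0, 40)")
  }
  n <- spec$n
  ct_t <- rep(NA_real_, n)
  ct_r <- numeric(n)
  det <- logical(n)
  pos <- logical(n)
  for (i in seq_len(n)) {
    with_substream(spec$seed, i, stream = 2L, {
      pos[i] <- runif(1) < spec$positivity
      ct_r[i] <- rtruncnorm_(1L, spec$reference_ct_mean,
                              spec$reference_ct_sd, 1e-6, ref_ct_max)
      if (pos[i]) {
        # detected target with score = 40 - (ct_t - ct_r) > cutoff
        hi <- min(40 - 1e-9, ct_r[i] + (40 - cutoff) - 1e-9)
        ct_t[i] <- rtruncnorm_(1L, spec$detected_ct_target_mean,
                                spec$detected_ct_target_sd, 1e-6, hi)
        det[i] <- TRUE
      } else if (runif(1) >= spec$dropout_prob) {
        lo <- ct_r[i] + (40 - cutoff)
        if (lo < 40) {           # else no detected CT can score below cutoff
          ct_t[i] <- rtruncnorm_(1L,
                                  max(spec$detected_ct_target_mean, lo + 1),
                                  spec$detected_ct_target_sd, lo, 40 - 1e-9)
          det[i] <- TRUE
        }
      }
    })
  }
  data.frame(
    sample_id = sprintf("%s_%03d", spec$group_label, seq_len(n)),
    group = spec$group_label,
    cohort = spec$cohort, stage = spec$stage, grade = spec$grade,
    sex = spec$sex, age = spec$age,
    ct_target = ct_t, ct_reference = ct_r,
    target_detected = det, reference_detected = TRUE,
    true_positive = pos,
    stringsAsFactors = FALSE
  )
}

#' Default qMSP validation-cohort strata
#'
#' The published validation design: 55 bladder-cancer urine samples split
#' into a Ta low-grade stratum (n = 18, positivity 10/18) and a Ta
#' high-grade + T1-T4 stratum (n = 37, positivity 32/37), 25 benign
#' urologic disease and 81 healthy controls sharing the overall
#' false-positive rate 8/106, and 8 other urologic cancers with zero
#' positivity.  Only explicitly published fraction pairs are used; finer
#' per-stage splits are not uniquely determined by the published counts.
#'
#' @param seed integer; stratum seeds are derived from it.
#' @return A list of [qmsp_sim_spec()] objects.
#' @export
qmsp_validation_defaults <- function(seed = 1L) {
  fp <- 8 / 106
  list(
    qmsp_sim_spec("BCa_TaLG", 18L, 10 / 18, cohort = "BCa", stage = "Ta",
                  grade = "low", seed = substream_seed(seed, 1L, 10L)),
    qmsp_sim_spec("BCa_TaHG_T1T4", 37L, 32 / 37, cohort = "BCa",
                  stage = "T1", grade = "high",
                  seed = substream_seed(seed, 2L, 10L)),
    qmsp_sim_spec("BUD", 25L, fp, cohort = "BUD",
                  seed = substream_seed(seed, 3L, 10L)),
    qmsp_sim_spec("healthy", 81L, fp, cohort = "healthy",
                  seed = substream_seed(seed, 4L, 10L)),
    qmsp_sim_spec("other_cancer", 8L, 0, cohort = "other-cancer",
                  seed = substream_seed(seed, 5L, 10L))
  )
}
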