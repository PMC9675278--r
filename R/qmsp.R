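# qMSP 40-deltaCT scoring and classification.
#
# The relative level of methylated target in a specimen is scored as
# 40 - deltaCT, with deltaCT = CT(target) - CT(reference).  Higher scores
# mean more methylation.  The reference amplicon contains no CpGs, so its
# amplification only reflects the presence of amplifiable
# bisulfite-converted DNA: an undetected or late reference CT invalidates
# the specimen.  An undetected *target* CT in a valid specimen is imputed
# to a floor score of 25, just below the lowest observed detected score.

#' Assay constants carried into run reports
#'
#' Immutable metadata describing the methylation-specific PCR assay
#' (annealing temperature, cycle count, imputation floor, amplicon
#' coordinates as supplied by the assay design).  Not used in computation.
#'
#' @return Named list of constants.
#' @export
qmsp_assay_metadata <- function() {
  list(target_gene = "PENK", reference_gene = "COL2A1",
       annealing_c = 60, cycles = 40L, imputed_score = 25,
       amplicon = "+524 to +595 bp (72 bp)")
}

#' Score one qMSP specimen
#'
#' @param rec list or one-row data.frame with fields `sample_id`,
#'   `ct_target`, `ct_reference`, `target_detected`, `reference_detected`,
#'   and optionally `role` (must be `"specimen"` if present).
#' @param ref_ct_max reference-gene validity bound (cycles): the reference
#'   CT must be detected and `<= ref_ct_max`, otherwise the specimen lacks
#'   sufficient bisulfite-converted DNA and is invalid.
#' @return List with `sample_id`, `score` (40-deltaCT; `NA` if invalid),
#'   `call` (`"valid"`/`"invalid"`), `imputed` (logical).
#' @examples
#' score_sample(list(sample_id = "s1", ct_target = 38, ct_reference = 30,
#'                   target_detected = TRUE, reference_detected = TRUE))
#' @export
score_sample <- function(rec, ref_ct_max = 38) {
  if (!is.null(rec$role) && !is.na(rec$role) && rec$role != "specimen") {
    stop("contract error: score_sample expects role = specimen, got ",
         rec$role)
  }
  ref_ok <- isTRUE(as.logical(rec$reference_detected)) &&
    is.finite(rec$ct_reference) && rec$ct_reference <= ref_ct_max
  if (!ref_ok) {
    return(list(sample_id = rec$sample_id, score = NA_real_,
                call = "invalid", imputed = FALSE))
  }
  if (!isTRUE(as.logical(rec$target_detected)) || !is.finite(rec$ct_target)) {
    return(list(sample_id = rec$sample_id,
                score = qmsp_assay_metadata()$imputed_score,
                call = "valid", imputed = TRUE))
  }
  list(sample_id = rec$sample_id,
       score = 40 - (rec$ct_target - rec$ct_reference),
       call = "valid", imputed = FALSE)
}

#' Score a table of qMSP specimens
#'
#' Vectorised [score_sample()] over the rows of a CT export.
#'
#' @param records data.frame with the columns of [score_sample()].
#' @param ref_ct_max reference-gene validity bound.
#' @return `records` with added columns `score`, `call`, `imputed`.
#' @export
score_samples <- function(records, ref_ct_max = 38) {
  need <- c("sample_id", "ct_target", "ct_reference", "target_detected",
            "reference_detected")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("schema error: missing column(s) ", paste(miss, collapse = ", "))
  }
  if (!is.null(records$role) && any(records$role != "specimen")) {
    stop("contract error: score_samples expects role = specimen rows only")
  }
  ref_ok <- as.logical(records$reference_detected) &
    is.finite(records$ct_reference) & records$ct_reference <= ref_ct_max
  ref_ok[is.na(ref_ok)] <- FALSE
  tgt_ok <- as.logical(records$target_detected) &
    is.finite(records$ct_target)
  tgt_ok[is.na(tgt_ok)] <- FALSE
  floor_score <- qmsp_assay_metadata()$imputed_score
  records$score <- ifelse(!ref_ok, NA_real_,
                          ifelse(tgt_ok,
                                 40 - (records$ct_target -
                                         records$ct_reference),
                                 floor_score))
  records$call <- ifelse(ref_ok, "valid", "invalid")
  records$imputed <- ref_ok & !tgt_ok
  records
}

#' Classify a scored specimen at a cutoff
#'
#' Positive when the 40-deltaCT score strictly exceeds the cutoff (scores
#' exactly at the cutoff are negative; the convention is configurable only
#' by shifting the cutoff).
#'
#' @param score numeric 40-deltaCT score(s).
#' @param cutoff classification cutoff (default 31.35, the
#'   validation-study operating point).
#' @param call optional validity call(s) from [score_sample()];
#'   classification of an invalid specimen is refused.
#' @return Character vector `"positive"`/`"negative"`.
#' @export
classify_score <- function(score, cutoff = 31.35, call = NULL) {
  if (!is.null(call) && any(call == "invalid")) {
    stop("classification refused: invalid specimen(s) present")
  }
  if (any(!is.finite(score))) {
    stop("classification refused: non-finite score(s)")
  }
  ifelse(score > cutoff, "positive", "negative")
}

#' Per-run control QC
#'
#' Each run carries a fully methylated positive control, an unmethylated
#' negative control and a non-template control (NTC).  The run is valid
#' only if the positive control classifies positive, the negative control
#' has an undetected target (or classifies negative), and the NTC shows no
#' amplification in either channel.
#'
#' @param controls data.frame of control wells with columns `role` (one of
#'   `positive_control`, `negative_control`, `ntc`), `ct_target`,
#'   `ct_reference`, `target_detected`, `reference_detected`, plus
#'   `sample_id`.
#' @param cutoff classification cutoff.
#' @param ref_ct_max reference validity bound.
#' @return List `positive_control_ok`, `negative_control_ok`, `ntc_ok`,
#'   `run_valid`.
#' @export
qc_run <- function(controls, cutoff = 31.35, ref_ct_max = 38) {
  roles <- c("positive_control", "negative_control", "ntc")
  for (r in roles) {
    if (sum(controls$role == r) != 1) {
      stop("QC error: expected exactly one control with role ", r)
    }
  }
  ctl <- function(r) as.list(controls[controls$role == r, , drop = FALSE])

  pc <- ctl("positive_control")
  pc_score <- if (isTRUE(as.logical(pc$target_detected)) &&
                  isTRUE(as.logical(pc$reference_detected))) {
    40 - (pc$ct_target - pc$ct_reference)
  } else -Inf
  positive_control_ok <- pc_score > cutoff

  nc <- ctl("negative_control")
  negative_control_ok <- if (!isTRUE(as.logical(nc$target_detected))) {
    TRUE
  } else if (isTRUE(as.logical(nc$reference_detected))) {
    (40 - (nc$ct_target - nc$ct_reference)) <= cutoff
  } else FALSE

  ntc <- ctl("ntc")
  ntc_ok <- !isTRUE(as.logical(ntc$target_detected)) &&
    !isTRUE(as.logical(ntc$reference_detected))

  list(positive_control_ok = positive_control_ok,
       negative_control_ok = negative_control_ok,
       ntc_ok = ntc_ok,
       run_valid = positive_control_ok && negative_control_ok && ntc_ok)
}
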