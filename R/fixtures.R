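# Deterministic study fixtures.
#
# Two non-stochastic cohorts are built in code: the full urine-study
# sample sheet with the published marginal counts, and the 169-sample
# clinical-validation cohort with per-sample qMSP calls whose stratum
# margins reproduce the published association table exactly.  Attributes
# that the published margins do not constrain jointly (e.g. which male
# patients are also the older ones) are assigned deterministically in row
# order; within each call stratum every published margin is honoured.

rep_each_ <- function(values, counts) rep(values, times = counts)

#' Full urine-study sample sheet
#'
#' All urine specimens of the study design: 93 healthy controls, 48 benign
#' urologic disease (BUD) patients and 71 bladder-cancer patients, with
#' the published sex, stage and grade marginal counts (BCa: Ta 28, T1 35,
#' T2 4, T3 2, T4 2; grade low 35 / high 33 / unknown 3; 55 male / 16
#' female).  Ages are deterministic fills consistent with the published
#' ranges.
#'
#' @return Sample-sheet data.frame (`sample_id`, `group`, `stage`,
#'   `grade`, `sex`, `age`).
#' @export
table1_cohort <- function() {
  healthy <- data.frame(
    sample_id = sprintf("H%03d", 1:93), group = "healthy",
    stage = "", grade = "",
    sex = rep_each_(c("male", "female"), c(60, 33)),
    age = rep(c(40, 54, 68), length.out = 93),
    stringsAsFactors = FALSE
  )
  bud <- data.frame(
    sample_id = sprintf("B%03d", 1:48), group = "BUD",
    stage = "", grade = "",
    sex = rep_each_(c("male", "female"), c(29, 19)),
    age = rep(c(40, 53, 66), length.out = 48),
    stringsAsFactors = FALSE
  )
  bca <- data.frame(
    sample_id = sprintf("C%03d", 1:71), group = "BCa",
    stage = rep_each_(c("Ta", "T1", "T2", "T3", "T4"), c(28, 35, 4, 2, 2)),
    grade = c(rep_each_(c("low", "high"), c(18, 10)),     # Ta
              rep_each_(c("low", "high", "unknown"), c(17, 15, 3)),  # T1
              rep("high", 8)),                            # T2-T4
    sex = rep_each_(c("male", "female"), c(55, 16)),
    age = rep(c(60, 69, 78), length.out = 71),
    stringsAsFactors = FALSE
  )
  rbind(healthy, bud, bca)
}

#' Clinical-validation cohort fixture with qMSP calls
#'
#' The 169-sample validation design (55 BCa, 25 BUD, 81 healthy, 8 other
#' urologic cancers) with deterministic per-sample methylation calls whose
#' margins reproduce the published clinical-association counts exactly:
#' 42/55 BCa positive overall; by sex 32/43 male and 10/12 female; by age
#' 12/19 under 65 and 30/36 at 65 or older; by stage 37/50 Ta-T1 and 5/5
#' T2-T4; by grade 16/26 low and 26/28 high with one unknown-grade
#' negative; Ta low-grade 10/18 and high-grade T1 17/19 positive; 8/106
#' false positives among BUD and healthy controls; other cancers all
#' negative.  A synthetic 40-deltaCT score consistent with each call is
#' attached (`cutoff + 3` for positives, the imputation floor 25 for
#' negatives).
#'
#' @param cutoff classification cutoff used to synthesize scores.
#' @return Data.frame: sample sheet columns plus `call` and `score`.
#' @export
validation_fixture <- function(cutoff = 31.35) {
  strat <- data.frame(
    stage = c("Ta", "T1", "T1", "Ta", "T2", "T3", "T4",
              "Ta", "T1", "T1", "Ta"),
    grade = c("low", "low", "high", "high", "high", "high", "high",
              "low", "low", "high", "unknown"),
    call = rep(c("positive", "negative"), c(7, 4)),
    n = c(10, 6, 17, 4, 3, 1, 1,
          8, 2, 2, 1),
    stringsAsFactors = FALSE
  )
  bca <- data.frame(
    stage = rep_each_(strat$stage, strat$n),
    grade = rep_each_(strat$grade, strat$n),
    call = rep_each_(strat$call, strat$n),
    stringsAsFactors = FALSE
  )
  # sex and age margins are assigned within each call stratum
  bca$sex <- NA_character_
  bca$age <- NA_real_
  ipos <- bca$call == "positive"
  bca$sex[ipos] <- rep_each_(c("male", "female"), c(32, 10))
  bca$sex[!ipos] <- rep_each_(c("male", "female"), c(11, 2))
  bca$age[ipos] <- rep_each_(c(58, 72), c(12, 30))
  bca$age[!ipos] <- rep_each_(c(58, 72), c(7, 6))
  bca <- data.frame(sample_id = sprintf("V%03d", seq_len(55)),
                    group = "BCa", bca, stringsAsFactors = FALSE)

  controls <- data.frame(
    sample_id = c(sprintf("VB%03d", 1:25), sprintf("VH%03d", 1:81),
                  sprintf("VO%03d", 1:8)),
    group = rep_each_(c("BUD", "healthy", "other-cancer"), c(25, 81, 8)),
    stage = "", grade = "",
    sex = rep(c("male", "female"), length.out = 114),
    age = rep(c(45, 57, 66), length.out = 114),
    call = c(rep_each_(c("positive", "negative"), c(2, 23)),
             rep_each_(c("positive", "negative"), c(6, 75)),
             rep("negative", 8)),
    stringsAsFactors = FALSE
  )
  out <- rbind(bca[, names(controls)], controls)
  out$score <- ifelse(out$call == "positive", cutoff + 3, 25)
  rownames(out) <- NULL
  out
}
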