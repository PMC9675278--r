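# End-to-end orchestration: simulate -> discover -> MtI -> qMSP -> validate.
#
# All randomness flows from one top-level seed; every output file is
# staged and atomically renamed, and reports carry no timestamps, so a
# rerun with the same configuration is byte-identical.

write_atomic_ <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' @param seed top-level integer seed; stage seeds are derived from it.
#' @param fixture_qmsp if `TRUE`, the clinical-validation stage uses the
#'   deterministic [validation_fixture()] (published stratum counts held
#'   exactly) instead of stochastic qMSP simulation.
#' @param alpha,fc_min,min_probes discovery thresholds.
#' @param cutoff qMSP classification cutoff (40-deltaCT scale).
#' @param level confidence level for all intervals.
#' @return A `run_config` list.
#' @export
default_run_config <- function(seed = 1L, fixture_qmsp = FALSE,
                               alpha = 0.01, fc_min = 2.0, min_probes = 2L,
                               cutoff = 31.35, level = 0.95) {
  calib <- mti_calibration_defaults()
  mti_specs <- lapply(seq_len(nrow(calib)), function(i) {
    mti_cohort_spec(calib$group[i], calib$gene[i], calib$target_mean[i],
                    calib$target_sd[i], calib$n[i],
                    seed = substream_seed(seed, i, 20L))
  })
  structure(
    list(seed = as.integer(seed),
         array = array_sim_config(seed = substream_seed(seed, 1L, 30L)),
         mti_specs = mti_specs,
         qmsp_specs = qmsp_validation_defaults(seed = seed),
         fixture_qmsp = isTRUE(fixture_qmsp),
         alpha = alpha, fc_min = fc_min,
         min_probes = as.integer(min_probes),
         cutoff = cutoff, level = level),
    class = "run_config"
  )
}

fmt1 <- function(x) formatC(x, format = "f", digits = 1)
fmt3 <- function(x) formatC(x, format = "f", digits = 3)

#' Run the full pipeline
#'
#' Executes array simulation and candidate discovery, pyrosequencing
#' simulation and MtI group comparison, qMSP scoring and classification,
#' and the clinical-validation statistics; writes every intermediate table
#' plus a human-readable summary to `out_dir`.
#'
#' Written files: `probes.csv`, `candidates.csv`, `pyro.csv`, `mti.csv`,
#' `mti_summary.csv`, `qmsp_calls.csv`, `association.csv`, `summary.txt`,
#' `log.txt`.
#'
#' @param cfg a `run_config` from [default_run_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with the in-memory results: `candidates`,
#'   `mti`, `mti_tests`, `calls`, `roc`, `performance`, `associations`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name) function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  ## discovery arm
  res <- tryCatch({
    ds <- generate_array_dataset(cfg$array)
    write_atomic_(function(p) write_probe_table(ds, p),
                  file.path(out_dir, "probes.csv"))
    cand <- select_candidates(ds, alpha = cfg$alpha, fc_min = cfg$fc_min,
                              min_probes = cfg$min_probes)
    write_atomic_(function(p) write.csv(cand, p, row.names = FALSE),
                  file.path(out_dir, "candidates.csv"))
    list(ds = ds, cand = cand)
  }, error = stage("discover"))

  ## pyrosequencing arm
  mti_res <- tryCatch({
    pyro <- simulate_pyro_table(cfg$mti_specs)
    write_atomic_(function(p) write_pyro_table(pyro, p),
                  file.path(out_dir, "pyro.csv"))
    mti <- mti_table(pyro)
    mti$group <- pyro$group[match(mti$sample_id, pyro$sample_id)]
    write_atomic_(function(p) write.csv(mti, p, row.names = FALSE),
                  file.path(out_dir, "mti.csv"))
    genes <- sort(unique(mti$gene))
    tests <- lapply(genes, function(g) {
      sub <- mti[mti$gene == g, ]
      kw <- kruskal_wallis(split(sub$mti, sub$group))
      data.frame(gene = g,
                 mean_healthy = mean(sub$mti[sub$group == "healthy"]),
                 mean_BUD = mean(sub$mti[sub$group == "BUD"]),
                 mean_BCa = mean(sub$mti[sub$group == "BCa"]),
                 kw_H = kw$statistic, kw_p = kw$p_value,
                 stringsAsFactors = FALSE)
    })
    tests <- do.call(rbind, tests)
    write_atomic_(function(p) write.csv(tests, p, row.names = FALSE),
                  file.path(out_dir, "mti_summary.csv"))
    list(mti = mti, tests = tests)
  }, error = stage("mti"))

  ## qMSP arm
  calls <- tryCatch({
    if (cfg$fixture_qmsp) {
      validation_fixture(cutoff = cfg$cutoff)
    } else {
      raw <- do.call(rbind, lapply(cfg$qmsp_specs, generate_qmsp_cohort,
                                   cutoff = cfg$cutoff))
      scored <- score_samples(raw)
      valid <- scored$call == "valid"
      scored$call[valid] <- classify_score(scored$score[valid],
                                           cutoff = cfg$cutoff)
      names(scored)[names(scored) == "cohort"] <- "cohort_label"
      scored$group <- scored$cohort_label
      scored
    }
  }, error = stage("qmsp"))
  write_atomic_(function(p) write.csv(calls, p, row.names = FALSE),
                file.path(out_dir, "qmsp_calls.csv"))

  ## validation arm
  val <- tryCatch({
    eval_set <- calls[calls$group %in% c("BCa", "BUD", "healthy") &
                        calls$call %in% c("positive", "negative"), ]
    is_case <- eval_set$group == "BCa"
    roc <- roc_curve(eval_set$score, is_case, level = cfg$level)
    perf <- performance_at_cutoff(eval_set$score, is_case,
                                  cutoff = cfg$cutoff, level = cfg$level)
    bca <- eval_set[is_case, ]
    assoc <- list()
    for (par in c("sex", "age", "stage", "grade")) {
      ok <- tryCatch({
        assoc[[par]] <- association_table(bca, par)
        TRUE
      }, error = function(e) FALSE)
      if (!ok) assoc[par] <- NULL
    }
    assoc_df <- do.call(rbind, lapply(assoc, function(a) {
      data.frame(parameter = a$parameter, stratum = a$strata,
                 n = as.integer(a$n),
                 n_positive = as.integer(a$table[, "positive"]),
                 positivity_pct = fmt1(a$positivity),
                 fisher_p = fmt3(a$p_value),
                 stringsAsFactors = FALSE)
    }))
    write_atomic_(function(p) write.csv(assoc_df, p, row.names = FALSE),
                  file.path(out_dir, "association.csv"))
    list(roc = roc, perf = perf, assoc = assoc)
  }, error = stage("validate"))

  ## summary + log
  write_atomic_(function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    w <- function(...) writeLines(sprintf(...), con)
    w("== Candidate discovery ==")
    w("genes selected: %d (planted: %d)", nrow(res$cand),
      length(res$ds$planted_genes))
    w("selected: %s", paste(res$cand$gene_id, collapse = ", "))
    w("")
    w("== Urine MtI group comparison (Kruskal-Wallis) ==")
    for (i in seq_len(nrow(mti_res$tests))) {
      t <- mti_res$tests[i, ]
      w("%s: healthy %s / BUD %s / BCa %s, H = %s, p = %s", t$gene,
        fmt1(t$mean_healthy), fmt1(t$mean_BUD), fmt1(t$mean_BCa),
        fmt3(t$kw_H), fmt3(t$kw_p))
    }
    w("")
    w("== Clinical validation (cutoff %s) ==", fmt1(cfg$cutoff))
    w("AUC = %s (%s - %s)", fmt3(val$roc$auc), fmt3(val$roc$auc_ci[1]),
      fmt3(val$roc$auc_ci[2]))
    w("sensitivity = %s%% (%s - %s), specificity = %s%% (%s - %s)",
      fmt1(val$perf$sensitivity), fmt1(val$perf$sensitivity_ci[1]),
      fmt1(val$perf$sensitivity_ci[2]), fmt1(val$perf$specificity),
      fmt1(val$perf$specificity_ci[1]), fmt1(val$perf$specificity_ci[2]))
    for (a in val$assoc) {
      w("%s: %s, Fisher p = %s", a$parameter,
        paste(sprintf("%s %d/%d (%s%%)", a$strata,
                      as.integer(a$table[, "positive"]), as.integer(a$n),
                      fmt1(a$positivity)), collapse = "; "),
        fmt3(a$p_value))
    }
  }, file.path(out_dir, "summary.txt"))

  write_atomic_(function(p) {
    writeLines(c(
      paste0("methmark version: ",
             as.character(utils::packageVersion("methmark"))),
      paste0("seed: ", cfg$seed),
      paste0("alpha: ", cfg$alpha),
      paste0("fc_min: ", cfg$fc_min),
      paste0("min_probes: ", cfg$min_probes),
      paste0("cutoff: ", cfg$cutoff),
      paste0("confidence level: ", cfg$level),
      paste0("qmsp mode: ",
             if (cfg$fixture_qmsp) "fixture" else "stochastic")
    ), p)
  }, file.path(out_dir, "log.txt"))

  invisible(list(candidates = res$cand, mti = mti_res$mti,
                 mti_tests = mti_res$tests, calls = calls,
                 roc = val$roc, performance = val$perf,
                 associations = val$assoc))
}
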