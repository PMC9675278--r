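# Delimited-text I/O for the pipeline's table contracts.
#
# All files are comma-separated UTF-8 with a one-line header and "."
# decimal.  Undetected CT wells are encoded as an empty field plus a
# logical *_detected column, never as a magic number.

write_csv_ <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

require_cols_ <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  }
}

#' Read / write a sample sheet
#'
#' Columns: `sample_id`, `group` (healthy / BUD / BCa / other-cancer),
#' `stage` (Ta/T1/T2/T3/T4, empty for non-cancer), `grade`
#' (low/high/unknown, empty for non-cancer), `sex`, `age`.  Unknown extra
#' columns are preserved on read.
#'
#' @param path file path.
#' @return `read_sample_sheet`: a data.frame of sample records.
#' @export
read_sample_sheet <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_cols_(df, c("sample_id", "group", "stage", "grade", "sex", "age"),
                path)
  bad_age <- which(!is.na(df$age) & df$age <= 0)
  if (length(bad_age)) {
    stop("malformed row ", bad_age[1] + 1, " in ", path,
         ": age must be positive")
  }
  df
}

#' @rdname read_sample_sheet
#' @param records data.frame of sample records.
#' @export
write_sample_sheet <- function(records, path) {
  require_cols_(records,
                c("sample_id", "group", "stage", "grade", "sex", "age"),
                "sample sheet")
  write_csv_(records, path)
  invisible(path)
}

#' Read / write a long-format probe table
#'
#' Columns: `probe_id`, `gene`, `pair_id`, `tumor_logratio`,
#' `normal_logratio` (one row per probe/pair).  `read_probe_table`
#' reassembles the probe x pair matrices into an `array_dataset`.
#'
#' @param ds an `array_dataset`.
#' @param path file path.
#' @export
write_probe_table <- function(ds, path) {
  stopifnot(inherits(ds, "array_dataset"))
  long <- do.call(rbind, lapply(seq_along(ds$pair_ids), function(j) {
    data.frame(probe_id = ds$probes$probe_id,
               gene = ds$probes$gene_id,
               pair_id = ds$pair_ids[j],
               tumor_logratio = ds$tumor[, j],
               normal_logratio = ds$normal[, j],
               stringsAsFactors = FALSE)
  }))
  write_csv_(long, path)
  invisible(path)
}

#' @rdname write_probe_table
#' @export
read_probe_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_cols_(df, c("probe_id", "gene", "pair_id", "tumor_logratio",
                      "normal_logratio"), path)
  probe_ids <- unique(df$probe_id)
  pair_ids <- unique(df$pair_id)
  shape <- function(col) {
    m <- matrix(NA_real_, length(probe_ids), length(pair_ids),
                dimnames = list(probe_ids, pair_ids))
    m[cbind(match(df$probe_id, probe_ids), match(df$pair_id, pair_ids))] <-
      df[[col]]
    m
  }
  probes <- unique(df[, c("probe_id", "gene")])
  structure(
    list(probes = data.frame(probe_id = probes$probe_id,
                             gene_id = probes$gene,
                             reliable = TRUE, stringsAsFactors = FALSE),
         pair_ids = pair_ids,
         tumor = shape("tumor_logratio"),
         normal = shape("normal_logratio"),
         planted_genes = character(0),
         config = NULL),
    class = "array_dataset"
  )
}

#' Read / write a pyrosequencing table
#'
#' Columns: `sample_id`, `gene`, `cpg_index`, `methylated_fraction`.
#'
#' @param pyro data.frame in the pyrosequencing layout.
#' @param path file path.
#' @export
write_pyro_table <- function(pyro, path) {
  require_cols_(pyro, c("sample_id", "gene", "cpg_index",
                        "methylated_fraction"), "pyro table")
  write_csv_(pyro, path)
  invisible(path)
}

#' @rdname write_pyro_table
#' @export
read_pyro_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_cols_(df, c("sample_id", "gene", "cpg_index",
                      "methylated_fraction"), path)
  df
}

#' Read / write a qMSP CT export
#'
#' Columns: `sample_id`, `ct_target`, `ct_reference`, `target_detected`,
#' `reference_detected` (optionally `role`, `run_id` and sample-sheet
#' metadata).  Undetected wells have an empty CT field and detected =
#' FALSE.
#'
#' @param records data.frame of CT records.
#' @param path file path.
#' @export
write_ct_table <- function(records, path) {
  require_cols_(records, c("sample_id", "ct_target", "ct_reference",
                           "target_detected", "reference_detected"),
                "CT table")
  write_csv_(records, path)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  require_cols_(df, c("sample_id", "ct_target", "ct_reference",
                      "target_detected", "reference_detected"), path)
  df$target_detected <- as.logical(df$target_detected)
  df$reference_detected <- as.logical(df$reference_detected)
  df
}
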