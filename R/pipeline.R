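# End-to-end orchestration: simulate fixture cohorts, analyze directories of
# records, and score calls against labels. These functions back the thin
# command-line wrapper in inst/cli/ecglvh.

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                  paste0(...)))
}

#' Write a synthetic cohort to disk
#'
#' Writes every record in the requested format(s), the cohort manifest
#' (record_id, sex, lvmi_g_per_m2, lvh_label), a ground-truth beat table, and
#' prints a one-line summary.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir output directory (created if needed).
#' @param format `"csv"`, `"wfdb"`, or `"both"`.
#' @return the cohort manifest, invisibly.
#' @export
run_simulate <- function(spec, out_dir, format = c("csv", "wfdb", "both")) {
  format <- match.arg(format)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cohort <- generate_cohort(spec)
  truth_rows <- list()
  for (s in cohort$subjects) {
    if (format %in% c("csv", "both"))
      write_ecg_csv(s$record, file.path(out_dir, paste0(s$record$record_id, ".csv")))
    if (format %in% c("wfdb", "both"))
      write_wfdb(s$record, out_dir)
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      record_id = s$record$record_id, beat = seq_along(s$truth$fiducial_s),
      fiducial_s = s$truth$fiducial_s)
  }
  man <- cohort_manifest(cohort)
  utils::write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, truth_rows),
                   file.path(out_dir, "ground_truth_beats.csv"),
                   row.names = FALSE)
  cat(sprintf("simulated %d records (%d LVH, %d female) -> %s\n",
              nrow(man), sum(man$lvh_label), sum(man$sex == "female"), out_dir))
  invisible(man)
}

read_any_record <- function(path, sampling_rate_hz = NULL, sex = "unknown") {
  if (grepl("\\.hea$", path)) read_wfdb(path, sex = sex)
  else read_ecg_csv(path, sampling_rate_hz, sex = sex)
}

#' Analyze a directory of ECG records
#'
#' For each record: QRS detection, amplitude measurement, QC, the selected
#' criteria, and binary calls; results are written as a calls CSV and one JSON
#' report per record. When a labels CSV is given (columns record_id,
#' lvh_label, optional lvmi_g_per_m2, sex), each criterion is additionally
#' scored with [eval_report()] and written as JSON. Unreadable or QC-failing
#' records are logged, skipped, and counted in the returned summary -- no
#' record is silently dropped.
#'
#' @param records_dir directory containing `.csv` and/or `.hea` records.
#' @param out_dir output directory.
#' @param sampling_rate_hz sampling rate for CSV records (WFDB headers carry
#'   their own).
#' @param labels_csv optional path to a labels CSV.
#' @param config a [threshold_config()].
#' @param criteria criteria to run.
#' @param override_qc proceed despite QC failures.
#' @param params a [christov_params()].
#' @return list: calls (data frame), evals (per-criterion `eval_report`s or
#'   NULL), skipped (data frame of record_id, reason).
#' @export
run_analyze <- function(records_dir, out_dir, sampling_rate_hz = NULL,
                        labels_csv = NULL, config = threshold_config(),
                        criteria = CRITERION_NAMES, override_qc = FALSE,
                        params = christov_params()) {
  criteria <- match.arg(criteria, CRITERION_NAMES, several.ok = TRUE)
  if (!dir.exists(records_dir)) stop("no such directory: ", records_dir)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- sort(c(list.files(records_dir, "\\.hea$", full.names = TRUE),
                  list.files(records_dir, "\\.csv$", full.names = TRUE)))
  files <- files[!basename(files) %in%
                   c("manifest.csv", "ground_truth_beats.csv", "labels.csv")]
  if (length(files) == 0) stop("no records found in ", records_dir)
  labels <- NULL
  if (!is.null(labels_csv)) {
    labels <- utils::read.csv(labels_csv)
    if (!all(c("record_id", "lvh_label") %in% names(labels)))
      stop("labels CSV must have columns record_id and lvh_label")
  }
  all_calls <- list()
  skipped <- list()
  for (f in files) {
    rid <- sub("\\.(hea|csv)$", "", basename(f))
    sex <- "unknown"
    if (!is.null(labels) && "sex" %in% names(labels)) {
      m <- match(rid, labels$record_id)
      if (!is.na(m)) sex <- labels$sex[m]
    }
    res <- tryCatch({
      rec <- read_any_record(f, sampling_rate_hz, sex = sex)
      evaluate_record(rec, config, criteria, override_qc, params)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log_msg("WARN", "skipping ", rid, ": ", conditionMessage(res))
      skipped[[length(skipped) + 1L]] <- data.frame(record_id = rid,
                                                   reason = conditionMessage(res))
      next
    }
    all_calls[[length(all_calls) + 1L]] <- res
    per_rec <- lapply(res$results, function(r) list(
      mmcv_mv = r$mmcv_mv, threshold_mv = r$threshold_mv,
      positive = r$positive,
      combination_medians_mv = as.list(r$per_combination_median_mv)))
    jsonlite::write_json(list(record_id = res$record_id, qc = res$qc,
                              n_beats = res$n_beats, criteria = per_rec),
                         file.path(out_dir, paste0(rid, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (length(all_calls) == 0) stop("every record failed; nothing to report")
  calls_df <- calls_table(all_calls)
  utils::write.csv(calls_df, file.path(out_dir, "calls.csv"), row.names = FALSE)
  skipped_df <- if (length(skipped)) do.call(rbind, skipped)
                else data.frame(record_id = character(0), reason = character(0))
  utils::write.csv(skipped_df, file.path(out_dir, "skipped.csv"),
                   row.names = FALSE)
  evals <- NULL
  if (!is.null(labels)) {
    evals <- score_calls(calls_df, labels)
    for (cr in names(evals))
      write_eval_json(evals[[cr]], file.path(out_dir, paste0("eval_", cr, ".json")))
  }
  log_msg("INFO", length(all_calls), " records analyzed, ",
          nrow(skipped_df), " skipped")
  list(calls = calls_df, evals = evals, skipped = skipped_df)
}

# join calls with labels and build one eval_report per criterion
score_calls <- function(calls_df, labels) {
  out <- list()
  for (cr in unique(calls_df$criterion)) {
    sub <- calls_df[calls_df$criterion == cr, ]
    m <- match(sub$record_id, labels$record_id)
    ok <- !is.na(m)
    if (sum(ok) < 2) next
    lvmi <- if ("lvmi_g_per_m2" %in% names(labels))
      labels$lvmi_g_per_m2[m[ok]] else NULL
    out[[cr]] <- eval_report(sub$positive[ok], sub$mmcv_mv[ok],
                             as.logical(labels$lvh_label[m[ok]]), lvmi)
  }
  out
}

#' Score an existing calls table against labels
#'
#' The statistics layer without waveform access: a calls CSV (record_id,
#' criterion, mmcv_mv, positive) plus a labels CSV (record_id, lvh_label,
#' optional lvmi_g_per_m2) yield one evaluation report per criterion.
#'
#' @param calls_csv path to the calls CSV.
#' @param labels_csv path to the labels CSV.
#' @param out_dir output directory for the JSON reports.
#' @return named list of `eval_report`s.
#' @export
run_evaluate <- function(calls_csv, labels_csv, out_dir) {
  calls_df <- utils::read.csv(calls_csv)
  labels <- utils::read.csv(labels_csv)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  evals <- score_calls(calls_df, labels)
  for (cr in names(evals))
    write_eval_json(evals[[cr]], file.path(out_dir, paste0("eval_", cr, ".json")))
  evals
}
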