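# The four ECG voltage criteria for LVH, computed per heartbeat from the
# amplitude matrix and aggregated to one value per ECG as the maximum over
# lead combinations of the median across beats (MMCV).

CRITERION_NAMES <- c("WS", "SOKOLOW_LYON", "CORNELL", "PEGUERO_LO_PRESTI")

amp_col <- function(amps, lead) {
  if (!lead %in% amps$lead_names) stop("lead not present in amplitudes: ", lead)
  lead
}

#' Adjacent-precordial-overlap (Witteles-Somani) per-beat values
#'
#' For each adjacent precordial pair V_i, V_{i+1} (i = 1..5), the per-beat
#' value is the S-wave magnitude of V_i plus the R-wave amplitude of V_{i+1}.
#' The visual correlate is overlap of the QRS complexes of the two leads on a
#' standard display; the automated rule calls overlap when the sum exceeds
#' 20 mm (2 mV at 10 mm/mV).
#'
#' @param amps an `amplitude_matrix`.
#' @return beats x 5 matrix (columns `"V1-V2"` ... `"V5-V6"`), mV.
#' @export
ws_per_beat <- function(amps) {
  out <- vapply(1:5, function(i) {
    amps$s_amp_mv[, amp_col(amps, paste0("V", i))] +
      amps$r_amp_mv[, amp_col(amps, paste0("V", i + 1))]
  }, numeric(nrow(amps$s_amp_mv)))
  if (!is.matrix(out)) out <- matrix(out, nrow = 1)
  colnames(out) <- paste0("V", 1:5, "-V", 2:6)
  out
}

#' Sokolow-Lyon per-beat values
#'
#' S(V1) + R(V5) and S(V1) + R(V6); the classical cutoff is 35 mm (3.5 mV).
#'
#' @param amps an `amplitude_matrix`.
#' @return beats x 2 matrix (columns `"SV1+RV5"`, `"SV1+RV6"`), mV.
#' @export
sokolow_per_beat <- function(amps) {
  s1 <- amps$s_amp_mv[, amp_col(amps, "V1")]
  out <- cbind(s1 + amps$r_amp_mv[, amp_col(amps, "V5")],
               s1 + amps$r_amp_mv[, amp_col(amps, "V6")])
  colnames(out) <- c("SV1+RV5", "SV1+RV6")
  out
}

#' Cornell per-beat values
#'
#' R(aVL) + S(V3); the cutoff is sex-specific (28 mm men, 20 mm women).
#'
#' @param amps an `amplitude_matrix`.
#' @return beats x 1 matrix (column `"RaVL+SV3"`), mV.
#' @export
cornell_per_beat <- function(amps) {
  out <- cbind(amps$r_amp_mv[, amp_col(amps, "aVL")] +
                 amps$s_amp_mv[, amp_col(amps, "V3")])
  colnames(out) <- "RaVL+SV3"
  out
}

#' Peguero-Lo Presti per-beat values
#'
#' The deepest S wave in any available lead plus S(V4) (V4 may supply both
#' terms when its S is the deepest, per the original definition); cutoffs are
#' sex-specific (28 mm men, 23 mm women).
#'
#' @param amps an `amplitude_matrix`.
#' @return beats x 1 matrix (column `"SD+SV4"`), mV.
#' @export
peguero_per_beat <- function(amps) {
  sd_any <- apply(amps$s_amp_mv, 1, max)
  out <- cbind(sd_any + amps$s_amp_mv[, amp_col(amps, "V4")])
  colnames(out) <- "SD+SV4"
  out
}

#' MMCV: maximum over combinations of the median across beats
#'
#' The ECG-level criterion statistic: within each lead combination take the
#' median of the per-beat values (even counts average the middle two), then
#' take the maximum over combinations. Used both for the binary call and as
#' the ROC score, keeping the two internally consistent.
#'
#' @param per_beat_values beats x combinations numeric matrix.
#' @return scalar mV.
#' @export
mmcv <- function(per_beat_values) {
  if (!is.matrix(per_beat_values)) per_beat_values <- cbind(per_beat_values)
  if (nrow(per_beat_values) < 1 || ncol(per_beat_values) < 1)
    stop("MMCV needs at least one beat and one combination")
  max(apply(per_beat_values, 2, stats::median))
}

#' Criterion thresholds and calibration
#'
#' Thresholds are stated in display millimetres at the given calibration and
#' converted to mV once here; all downstream comparisons are in mV. The
#' adjacent-overlap (WS) criterion uses a strict inequality ("exceeding"
#' 20 mm); Sokolow-Lyon uses >=, Cornell > and Peguero-Lo Presti >= per their
#' original definitions. Unknown sex falls back to the stricter (male) cutoff
#' of sex-specific criteria with a warning.
#'
#' Sex-adjusted WS mode shifts the threshold by `ws_sex_offset_mm`: the
#' default direction lowers the female threshold (raising sensitivity in
#' women); `ws_adjust_direction = "raise_male"` raises the male threshold
#' instead.
#'
#' @param ws_mm WS threshold, display mm (default 20).
#' @param sokolow_mm Sokolow-Lyon threshold, mm (default 35).
#' @param cornell_mm named `c(male=, female=)` thresholds, mm (28 / 20).
#' @param peguero_mm named `c(male=, female=)` thresholds, mm (28 / 23).
#' @param ws_sex_adjusted logical; apply the sex offset to WS.
#' @param ws_sex_offset_mm offset magnitude, mm (default 10 -- two large
#'   boxes on a standard display).
#' @param ws_adjust_direction `"lower_female"` or `"raise_male"`.
#' @param calibration_mm_per_mv display calibration (default 10).
#' @return an object of class `threshold_config` with all thresholds in mV.
#' @export
threshold_config <- function(ws_mm = 20, sokolow_mm = 35,
                             cornell_mm = c(male = 28, female = 20),
                             peguero_mm = c(male = 28, female = 23),
                             ws_sex_adjusted = FALSE, ws_sex_offset_mm = 10,
                             ws_adjust_direction = c("lower_female", "raise_male"),
                             calibration_mm_per_mv = 10) {
  ws_adjust_direction <- match.arg(ws_adjust_direction)
  ws_male_mm <- ws_mm
  ws_female_mm <- ws_mm
  if (ws_sex_adjusted) {
    if (ws_adjust_direction == "lower_female")
      ws_female_mm <- ws_mm - ws_sex_offset_mm
    else ws_male_mm <- ws_mm + ws_sex_offset_mm
  }
  thr <- list(
    WS = c(male = mm_to_mv(ws_male_mm, calibration_mm_per_mv),
           female = mm_to_mv(ws_female_mm, calibration_mm_per_mv)),
    SOKOLOW_LYON = c(male = mm_to_mv(sokolow_mm, calibration_mm_per_mv),
                     female = mm_to_mv(sokolow_mm, calibration_mm_per_mv)),
    CORNELL = c(male = mm_to_mv(cornell_mm[["male"]], calibration_mm_per_mv),
                female = mm_to_mv(cornell_mm[["female"]], calibration_mm_per_mv)),
    PEGUERO_LO_PRESTI = c(male = mm_to_mv(peguero_mm[["male"]], calibration_mm_per_mv),
                          female = mm_to_mv(peguero_mm[["female"]], calibration_mm_per_mv))
  )
  if (any(unlist(thr) <= 0)) stop("thresholds must be positive after conversion")
  structure(list(thresholds_mv = thr,
                 strict = c(WS = TRUE, SOKOLOW_LYON = FALSE, CORNELL = TRUE,
                            PEGUERO_LO_PRESTI = FALSE),
                 ws_sex_adjusted = ws_sex_adjusted,
                 calibration_mm_per_mv = calibration_mm_per_mv),
            class = "threshold_config")
}

#' Binary LVH call from an MMCV value
#'
#' @param value MMCV in mV.
#' @param criterion one of `"WS"`, `"SOKOLOW_LYON"`, `"CORNELL"`,
#'   `"PEGUERO_LO_PRESTI"`.
#' @param sex `"male"`, `"female"`, or `"unknown"` (falls back to the male
#'   cutoff with a warning when the criterion is sex-specific).
#' @param config a [threshold_config()].
#' @return logical call; attribute `threshold_mv` gives the cutoff applied.
#' @export
classify_mmcv <- function(value, criterion, sex = "unknown",
                          config = threshold_config()) {
  stopifnot(inherits(config, "threshold_config"))
  criterion <- match.arg(criterion, CRITERION_NAMES)
  thr <- config$thresholds_mv[[criterion]]
  sex_specific <- thr[["male"]] != thr[["female"]]
  if (sex == "unknown") {
    if (sex_specific)
      warning("sex unknown: applying the stricter (male) cutoff for ", criterion)
    use <- "male"
  } else use <- match.arg(sex, c("male", "female"))
  t <- thr[[use]]
  pos <- if (config$strict[[criterion]]) value > t else value >= t
  attr(pos, "threshold_mv") <- t
  pos
}

#' Evaluate every criterion on one record
#'
#' Runs the full chain: QRS detection, amplitude measurement, QC, per-beat
#' criterion values, MMCV aggregation, and the binary call at the configured
#' thresholds. Deterministic for fixed input and configuration. Records
#' flagged `TOO_FEW_BEATS` (or with no detectable beats) raise an error
#' unless `override_qc = TRUE`; other flags are attached to the result.
#'
#' @param record an `ecg_record`.
#' @param config a [threshold_config()].
#' @param criteria subset of criterion names to compute.
#' @param override_qc proceed despite QC failure.
#' @param params a [christov_params()].
#' @return a list of class `lvh_calls`: one `criterion_result` per criterion
#'   (fields `criterion_name`, `per_beat_values_mv`, `combination_labels`,
#'   `per_combination_median_mv`, `mmcv_mv`, `threshold_mv`, `sex_used`,
#'   `positive`), plus `record_id`, `qc` and `n_beats`.
#' @export
evaluate_record <- function(record, config = threshold_config(),
                            criteria = CRITERION_NAMES, override_qc = FALSE,
                            params = christov_params()) {
  stopifnot(inherits(record, "ecg_record"))
  criteria <- match.arg(criteria, CRITERION_NAMES, several.ok = TRUE)
  beats <- detect_beats(record, params)
  if (length(beats$fiducial_samples) == 0) {
    if (!override_qc)
      stop("QC failure on ", record$record_id, ": no beats detected [",
           paste(beats$flags, collapse = ","), "]")
    stop("no beats detected; criteria cannot be computed even with override")
  }
  amps <- measure_amplitudes(record, beats, params)
  qc <- qc_flags(record, beats, amps)
  if ("TOO_FEW_BEATS" %in% qc && !override_qc)
    stop("QC failure on ", record$record_id, ": TOO_FEW_BEATS (",
         length(beats$fiducial_samples), " beats); set override_qc = TRUE to force")
  fns <- list(WS = ws_per_beat, SOKOLOW_LYON = sokolow_per_beat,
              CORNELL = cornell_per_beat, PEGUERO_LO_PRESTI = peguero_per_beat)
  results <- lapply(criteria, function(cr) {
    pb <- fns[[cr]](amps)
    med <- apply(pb, 2, stats::median)
    m <- max(med)
    pos <- classify_mmcv(m, cr, record$sex, config)
    structure(list(criterion_name = cr, per_beat_values_mv = pb,
                   combination_labels = colnames(pb),
                   per_combination_median_mv = med, mmcv_mv = m,
                   threshold_mv = attr(pos, "threshold_mv"),
                   sex_used = if (record$sex == "unknown") "male" else record$sex,
                   positive = as.logical(pos)), class = "criterion_result")
  })
  names(results) <- criteria
  structure(list(results = results, record_id = record$record_id, qc = qc,
                 n_beats = nrow(amps$r_amp_mv)), class = "lvh_calls")
}

#' @export
print.criterion_result <- function(x, ...) {
  cat(sprintf("<criterion_result> %s: MMCV %.3f mV %s %.3f mV -> %s\n",
              x$criterion_name, x$mmcv_mv,
              if (x$positive) ">" else "<=", x$threshold_mv,
              if (x$positive) "POSITIVE" else "negative"))
  invisible(x)
}

#' @export
print.lvh_calls <- function(x, ...) {
  cat(sprintf("<lvh_calls> %s (%d beats%s)\n", x$record_id, x$n_beats,
              if (length(x$qc)) paste0("; QC: ", paste(x$qc, collapse = ","))
              else ""))
  for (r in x$results) print(r)
  invisible(x)
}

#' Flatten per-record calls to a data frame
#' @param calls an `lvh_calls` object or a list of them.
#' @return data frame: record_id, criterion, mmcv_mv, threshold_mv, positive.
#' @export
calls_table <- function(calls) {
  if (inherits(calls, "lvh_calls")) calls <- list(calls)
  do.call(rbind, lapply(calls, function(cl) {
    do.call(rbind, lapply(cl$results, function(r) data.frame(
      record_id = cl$record_id, criterion = r$criterion_name,
      mmcv_mv = r$mmcv_mv, threshold_mv = r$threshold_mv,
      positive = r$positive, row.names = NULL
    )))
  }))
}
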