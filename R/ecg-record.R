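#' @keywords internal
"_PACKAGE"

#' Canonical 12-lead order
#'
#' Signals are stored in this order internally; criteria address leads by
#' name, never by column position in the source file.
#' @export
CANONICAL_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF",
                     "V1", "V2", "V3", "V4", "V5", "V6")

#' @rdname CANONICAL_LEADS
#' @export
PRECORDIAL_LEADS <- c("V1", "V2", "V3", "V4", "V5", "V6")

#' Construct a 12-lead ECG record
#'
#' Bundles a multichannel waveform (in millivolts) with its sampling rate and
#' metadata. Signals are stored leads-by-samples with leads reordered into the
#' canonical order I, II, III, aVR, aVL, aVF, V1--V6; any extra channels are
#' kept after the canonical ones and ignored by the LVH criteria. The
#' precordial leads V1--V6 are mandatory because every supported criterion
#' reads them.
#'
#' @param signals numeric matrix, one row per lead, with rownames giving lead
#'   names (matched case-insensitively against the canonical names).
#' @param sampling_rate_hz sampling rate in Hz; rates below 100 Hz are
#'   rejected because QRS morphology is unresolvable there.
#' @param record_id identifier carried through to outputs.
#' @param sex one of `"male"`, `"female"`, `"unknown"`.
#' @param age_years optional age in years.
#' @param calibration_mm_per_mv display calibration, default 10 mm per mV.
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(signals, sampling_rate_hz, record_id = "record",
                       sex = c("unknown", "male", "female"), age_years = NULL,
                       calibration_mm_per_mv = 10) {
  sex <- match.arg(sex)
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("`signals` must be a numeric matrix (leads x samples)")
  if (is.null(rownames(signals)))
    stop("`signals` must have rownames giving lead names")
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      !is.finite(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("`sampling_rate_hz` must be a positive number")
  if (sampling_rate_hz < 100)
    stop("sampling rates below 100 Hz are rejected: QRS morphology is not resolvable")
  if (calibration_mm_per_mv <= 0)
    stop("`calibration_mm_per_mv` must be positive")
  rownames(signals) <- normalize_lead_names(rownames(signals))
  missing_prec <- setdiff(PRECORDIAL_LEADS, rownames(signals))
  if (length(missing_prec) > 0)
    stop("missing precordial lead(s): ", paste(missing_prec, collapse = ", "))
  if (any(!is.finite(signals)))
    stop("non-finite samples in signal matrix")
  # canonical leads first, extras after, original order among extras kept
  canon <- intersect(CANONICAL_LEADS, rownames(signals))
  extra <- setdiff(rownames(signals), CANONICAL_LEADS)
  signals <- signals[c(canon, extra), , drop = FALSE]
  structure(list(
    record_id = as.character(record_id),
    sampling_rate_hz = sampling_rate_hz,
    leads = rownames(signals),
    signals = signals,
    duration_s = ncol(signals) / sampling_rate_hz,
    sex = sex,
    age_years = age_years,
    calibration_mm_per_mv = calibration_mm_per_mv
  ), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %s: %d leads x %d samples, %g Hz (%.1f s), sex=%s\n",
              x$record_id, nrow(x$signals), ncol(x$signals),
              x$sampling_rate_hz, x$duration_s, x$sex))
  invisible(x)
}

# Case-insensitive normalization onto the canonical lead names; unknown names
# are passed through untouched.
normalize_lead_names <- function(nms) {
  idx <- match(toupper(trimws(nms)), toupper(CANONICAL_LEADS))
  ifelse(is.na(idx), trimws(nms), CANONICAL_LEADS[idx])
}

#' Get one lead's signal by name
#' @param record an `ecg_record`.
#' @param lead lead name, e.g. `"V5"`.
#' @return numeric vector in mV.
#' @export
lead_signal <- function(record, lead) {
  stopifnot(inherits(record, "ecg_record"))
  lead <- normalize_lead_names(lead)
  if (!lead %in% record$leads) stop("lead not present: ", lead)
  record$signals[lead, ]
}

#' Convert display millimetres to millivolts (and back)
#'
#' Conventional 12-lead displays are calibrated at 10 mm per mV, so a 20 mm
#' deflection equals 2 mV. Thresholds configured in display mm are converted
#' once, at configuration time, and all internal amplitudes are mV.
#'
#' @param display_mm deflection in display millimetres.
#' @param calibration_mm_per_mv calibration, mm per mV (default 10).
#' @return amplitude in mV.
#' @export
mm_to_mv <- function(display_mm, calibration_mm_per_mv = 10) {
  if (!is.numeric(calibration_mm_per_mv) || any(calibration_mm_per_mv <= 0))
    stop("calibration must be positive")
  display_mm / calibration_mm_per_mv
}

#' @rdname mm_to_mv
#' @param mv amplitude in mV.
#' @export
mv_to_mm <- function(mv, calibration_mm_per_mv = 10) {
  if (!is.numeric(calibration_mm_per_mv) || any(calibration_mm_per_mv <= 0))
    stop("calibration must be positive")
  mv * calibration_mm_per_mv
}

#' Read an ECG record from CSV
#'
#' Dialect: comma-separated, UTF-8, decimal point, one mandatory header row of
#' lead names, one column per lead, samples in mV. Unknown columns are carried
#' through but ignored by the criteria.
#'
#' @param path path to the CSV file.
#' @param sampling_rate_hz sampling rate of the stored samples, Hz.
#' @param ... passed to [ecg_record()] (record_id, sex, ...).
#' @return an `ecg_record`.
#' @export
read_ecg_csv <- function(path, sampling_rate_hz, ...) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("parse error: empty file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0) stop("parse error: no data rows in ", path)
  mat <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  if (nrow(df) == 1) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, names(df)))
  if (any(is.na(mat))) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("parse error: non-numeric cell at row %d, column '%s'",
                 bad[["row"]], colnames(mat)[bad[["col"]]]))
  }
  args <- list(...)
  if (is.null(args$record_id))
    args$record_id <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  do.call(ecg_record, c(list(signals = t(mat), sampling_rate_hz = sampling_rate_hz),
                        args))
}

#' Write an ECG record as CSV
#' @param record an `ecg_record`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ecg_csv <- function(record, path) {
  stopifnot(inherits(record, "ecg_record"))
  df <- as.data.frame(t(record$signals))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
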