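#' Score beat detection against ground-truth fiducials
#'
#' Greedy one-to-one matching of detected to true fiducials within a time
#' window (closest pairs first). Sensitivity is matched / true beats and
#' positive predictivity matched / detected beats, the standard beat-level
#' scores.
#'
#' @param detected_s detected fiducial times, s.
#' @param truth_s ground-truth fiducial times, s.
#' @param window_s matching window (default 0.075 s).
#' @return list: n_true, n_detected, n_matched, sensitivity, ppv.
#' @export
beat_detection_stats <- function(detected_s, truth_s, window_s = 0.075) {
  if (length(truth_s) == 0) stop("no ground-truth beats")
  if (length(detected_s) == 0)
    return(list(n_true = length(truth_s), n_detected = 0L, n_matched = 0L,
                sensitivity = 0, ppv = NA_real_))
  d <- abs(outer(detected_s, truth_s, "-"))
  d[d > window_s] <- NA
  used_det <- logical(length(detected_s))
  used_tru <- logical(length(truth_s))
  matched <- 0L
  repeat {
    if (all(is.na(d))) break
    ij <- arrayInd(which.min(d), dim(d))
    used_det[ij[1]] <- TRUE
    used_tru[ij[2]] <- TRUE
    matched <- matched + 1L
    d[ij[1], ] <- NA
    d[, ij[2]] <- NA
  }
  list(n_true = length(truth_s), n_detected = length(detected_s),
       n_matched = matched,
       sensitivity = matched / length(truth_s),
       ppv = matched / length(detected_s))
}

#' Aggregate beat-detection performance over a cohort
#'
#' Runs [detect_beats()] on every record of a synthetic cohort and pools the
#' matched counts against the generator's ground truth.
#'
#' @param cohort an `ecg_cohort` from [generate_cohort()].
#' @param window_s matching window, s.
#' @param params a [christov_params()].
#' @return list: n_true, n_detected, n_matched, sensitivity, ppv (pooled).
#' @export
cohort_detection_stats <- function(cohort, window_s = 0.075,
                                   params = christov_params()) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  tot <- c(true = 0L, det = 0L, match = 0L)
  for (s in cohort$subjects) {
    bs <- detect_beats(s$record, params)
    st <- beat_detection_stats(bs$fiducial_s, s$truth$fiducial_s, window_s)
    tot <- tot + c(st$n_true, st$n_detected, st$n_matched)
  }
  list(n_true = tot[["true"]], n_detected = tot[["det"]],
       n_matched = tot[["match"]],
       sensitivity = tot[["match"]] / tot[["true"]],
       ppv = tot[["match"]] / tot[["det"]])
}
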