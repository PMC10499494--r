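# Christov-style QRS detection: a filtered cross-lead "complex lead" scanned
# with three adaptive thresholds (steep-slope M, integrating F, beat
# expectation R). Constants follow the published reference design and are
# exposed through christov_params().

# centered moving average with reflection padding; preserves length
ma_reflect <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  n <- length(x)
  half <- w %/% 2L
  if (n <= w) stop("signal shorter than filter span (", w, " samples)")
  pad <- c(x[half:1], x, x[n:(n - (w - half) + 1L)])
  cs <- c(0, cumsum(pad))
  (cs[(w + 1):(w + n)] - cs[1:n]) / w
}

# rolling max over the trailing w samples (inclusive); edges use what exists
roll_max_trailing <- function(x, w) {
  n <- length(x)
  out <- x
  if (w <= 1L) return(out)
  shifted <- lapply(1:(w - 1L), function(k) c(rep(-Inf, k), x[1:(n - k)]))
  do.call(pmax, c(list(out), shifted))
}

#' Detector tuning parameters
#'
#' Defaults follow the cited adaptive-threshold design: the steep-slope
#' threshold M is seeded from the first seconds of the complex lead and decays
#' after each detection; the integrating threshold F tracks the recent signal
#' level; the beat-expectation threshold R lowers the combined threshold when
#' the next beat is overdue. All times are seconds.
#'
#' @param powerline_hz power-line frequency suppressed by the first moving
#'   average (50 or 60).
#' @param refractory_s no second detection within this interval of the last.
#' @param init_s length of the startup segment used to seed M.
#' @param edge_s fiducials are ineligible within this distance of either end
#'   (filters use reflection padding; the exclusion avoids boundary artifacts
#'   in the amplitude windows).
#' @param m_seed_frac fraction of the startup complex-lead maximum used as the
#'   initial steep-slope value.
#' @param m_decay_frac M decays linearly to this fraction between
#'   `m_decay_start_s` and `m_decay_end_s` after a detection.
#' @param m_decay_start_s,m_decay_end_s decay interval bounds after detection.
#' @param m_limit_ratio,m_limit_replace a new steep-slope value larger than
#'   `m_limit_ratio` times the previous is replaced by `m_limit_replace` times
#'   the previous (guards against artifact spikes).
#' @param f_window_s,f_lag_s,f_gain integrating-threshold update: F moves by
#'   (max over the trailing `f_window_s` minus max over the same-length window
#'   lagged `f_lag_s`) divided by `f_gain`, every sample.
#' @param r_expect_frac R stays zero until this fraction of the mean RR
#'   interval has elapsed since the last beat.
#' @param r_drop_frac R then falls linearly to minus this fraction of M over
#'   the remaining third of the expected interval.
#' @param peak_search_s fiducial is the complex-lead maximum within this span
#'   after the threshold crossing.
#' @return a list of class `christov_params`.
#' @export
christov_params <- function(powerline_hz = 50, refractory_s = 0.2, init_s = 5,
                            edge_s = 0.5, m_seed_frac = 0.6,
                            m_decay_frac = 0.6, m_decay_start_s = 0.2,
                            m_decay_end_s = 1.2, m_limit_ratio = 1.5,
                            m_limit_replace = 1.1, f_window_s = 0.05,
                            f_lag_s = 0.3, f_gain = 150,
                            r_expect_frac = 2 / 3, r_drop_frac = 0.3,
                            peak_search_s = 0.14) {
  structure(as.list(environment()), class = "christov_params")
}

#' Build the cross-lead complex lead
#'
#' Per lead: a moving average over one power-line period, a 28 ms moving
#' average (muscle-noise suppression), the absolute centered difference
#' `|x[i+1] - x[i-1]|`, and a 40 ms moving average; the per-lead results are
#' summed into a single channel. Differencing removes constants exactly and
#' the first moving average nulls the power-line frequency.
#'
#' @param record an `ecg_record`.
#' @param params a [christov_params()].
#' @return numeric vector, same length as the record.
#' @export
christov_complex_lead <- function(record, params = christov_params()) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$sampling_rate_hz
  w_pl <- max(1L, round(fs / params$powerline_hz))
  w_28 <- max(1L, round(0.028 * fs))
  w_40 <- max(1L, round(0.040 * fs))
  n <- ncol(record$signals)
  if (n <= max(w_pl, w_28, w_40) + 2L)
    stop("record shorter than filter span")
  leads <- intersect(CANONICAL_LEADS, record$leads)
  out <- numeric(n)
  for (ld in leads) {
    x <- ma_reflect(record$signals[ld, ], w_pl)
    x <- ma_reflect(x, w_28)
    d <- abs(c(x[2] - x[1], x[3:n] - x[1:(n - 2)], x[n] - x[n - 1]))
    out <- out + ma_reflect(d, w_40)
  }
  out
}

#' Detect QRS complexes with adaptive thresholds
#'
#' Scans the complex lead with the combined threshold M + F + R. After each
#' detection the fiducial is placed at the complex-lead maximum of the
#' detection region, the steep-slope buffer (last five values) is updated, and
#' detection is suppressed for the refractory period. All thresholds scale
#' with the signal, so detection is invariant to global amplitude scaling. A
#' flat record yields an empty beat set with a `LOW_SIGNAL` flag rather than
#' an error.
#'
#' @param record an `ecg_record`, at least 2 s long.
#' @param params a [christov_params()].
#' @return an object of class `beat_set` with `fiducial_samples` (strictly
#'   increasing), `fiducial_s`, `detection_lead`, `complex_lead`, and a
#'   `flags` character vector (e.g. `LOW_SIGNAL` for flat input).
#' @export
detect_beats <- function(record, params = christov_params()) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$sampling_rate_hz
  if (record$duration_s < 2) stop("record must be at least 2 s long")
  Y <- christov_complex_lead(record, params)
  n <- length(Y)
  edge <- round(params$edge_s * fs)
  lo <- edge + 1L
  hi <- n - edge + 1L  # samples at exactly edge_s from either end are eligible
  flags <- character(0)
  peak_amp <- max(Y[lo:hi])
  if (peak_amp <= 1e-9) {
    return(structure(list(fiducial_samples = integer(0), fiducial_s = numeric(0),
                          detection_lead = "christov-complex",
                          sampling_rate_hz = fs, complex_lead = Y,
                          flags = "LOW_SIGNAL"), class = "beat_set"))
  }
  init_n <- min(hi, lo + round(params$init_s * fs))
  M <- params$m_seed_frac * max(Y[lo:init_n])
  MM <- rep(M, 5)
  # integrating threshold F, precomputed: cumulative drift of the difference
  # between the recent and the lagged rolling maxima
  w_f <- max(1L, round(params$f_window_s * fs))
  lag_f <- round(params$f_lag_s * fs)
  rmax <- roll_max_trailing(Y, w_f)
  start_f <- lag_f + w_f + 1L
  F0 <- mean(Y[seq_len(min(n, lag_f + w_f))])
  dF <- numeric(n)
  idx <- start_f:n
  dF[idx] <- (rmax[idx] - rmax[idx - lag_f]) / params$f_gain
  Fv <- pmax(0, F0 + cumsum(dF))
  refr <- round(params$refractory_s * fs)
  dec0 <- round(params$m_decay_start_s * fs)
  dec1 <- round(params$m_decay_end_s * fs)
  peak_w <- round(params$peak_search_s * fs)
  fid <- integer(0)
  rr_buf <- numeric(0)
  last <- -Inf
  Mmean <- mean(MM)
  i <- lo
  while (i <= hi) {
    dt <- i - last
    if (dt <= refr) { i <- i + 1L; next }
    # steep-slope threshold with post-beat decay
    Mi <- if (!is.finite(dt) || dt <= dec0) Mmean
          else if (dt >= dec1) params$m_decay_frac * Mmean
          else Mmean * (1 - (1 - params$m_decay_frac) * (dt - dec0) / (dec1 - dec0))
    # beat-expectation threshold
    Ri <- 0
    if (length(rr_buf) > 0 && is.finite(dt)) {
      rm <- mean(rr_buf)
      thr0 <- params$r_expect_frac * rm
      if (dt > thr0)
        Ri <- -params$r_drop_frac * Mmean *
          min(1, (dt - thr0) / (rm * (1 - params$r_expect_frac)))
    }
    if (Y[i] > Mi + Fv[i] + Ri) {
      region <- i:min(hi, i + peak_w)
      pk <- region[which.max(Y[region])]
      newM <- params$m_seed_frac * max(Y[region])
      if (newM > params$m_limit_ratio * MM[5]) newM <- params$m_limit_replace * MM[5]
      MM <- c(MM[-1], newM)
      Mmean <- mean(MM)
      if (length(fid) > 0) {
        rr_buf <- c(rr_buf, (pk - fid[length(fid)]))
        if (length(rr_buf) > 5) rr_buf <- rr_buf[-1]
      }
      fid <- c(fid, pk)
      last <- pk
      i <- pk + refr + 1L
    } else i <- i + 1L
  }
  if (length(fid) == 0) flags <- c(flags, "NO_BEATS")
  structure(list(fiducial_samples = fid, fiducial_s = (fid - 1) / fs,
                 detection_lead = "christov-complex", sampling_rate_hz = fs,
                 complex_lead = Y, flags = flags), class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d beats on %s%s\n", length(x$fiducial_samples),
              x$detection_lead,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Advisory quality-control flags for a record
#'
#' `WIDE_QRS` when the median QRS duration exceeds 120 ms (a proxy for bundle
#' branch block or paced rhythm, whose exclusion otherwise needs machine
#' interpretation statements), `TOO_FEW_BEATS` below 3 detected beats, and
#' `LOW_SIGNAL` when the complex-lead peak is below an absolute floor. Flags
#' are advisory: the caller decides whether to exclude.
#'
#' @param record an `ecg_record`.
#' @param beats a `beat_set` from [detect_beats()].
#' @param amps an `amplitude_matrix` from [measure_amplitudes()], supplying
#'   QRS durations.
#' @param wide_qrs_ms,low_signal_floor flag thresholds.
#' @return character vector of flags (possibly empty).
#' @export
qc_flags <- function(record, beats, amps, wide_qrs_ms = 120,
                     low_signal_floor = 0.05) {
  flags <- character(0)
  if (length(beats$fiducial_samples) < 3) flags <- c(flags, "TOO_FEW_BEATS")
  if (length(beats$complex_lead) > 0 && max(beats$complex_lead) < low_signal_floor)
    flags <- c(flags, "LOW_SIGNAL")
  if (!missing(amps) && !is.null(amps) && length(amps$qrs_duration_ms) > 0 &&
      stats::median(amps$qrs_duration_ms, na.rm = TRUE) > wide_qrs_ms)
    flags <- c(flags, "WIDE_QRS")
  unique(c(beats$flags, flags))
}

#' Write detected beats as an annotation table
#' @param beats a `beat_set`.
#' @param path output CSV path (columns: sample, time_s).
#' @return `path`, invisibly.
#' @export
write_beats_csv <- function(beats, path) {
  utils::write.csv(data.frame(sample = beats$fiducial_samples,
                              time_s = beats$fiducial_s),
                   path, row.names = FALSE)
  invisible(path)
}
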