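#' Beat morphology template for the synthetic 12-lead generator
#'
#' Each beat is a sum of five Gaussian-shaped waves (P, Q, R, S, T) per lead,
#' an ECGSYN-style simplification with independent per-lead amplitudes: the
#' LVH criteria consume only R- and S-wave amplitudes, so full torso physics
#' is out of scope. The default template mimics normal R-wave progression:
#' deep S waves in V1--V2, transition around V3--V4, tall R waves in V5--V6.
#'
#' @param r_amp_mv,s_amp_mv,q_amp_mv,p_amp_mv,t_amp_mv named numeric vectors
#'   of per-lead wave amplitudes in mV (signed; Q and S must be <= 0, R >= 0).
#' @param centers_s named numeric vector of wave-center offsets from the beat
#'   fiducial in seconds (P before QRS before T).
#' @param widths_s named numeric vector of Gaussian standard deviations in
#'   seconds, all positive.
#' @param heart_rate_bpm mean heart rate, beats per minute.
#' @param rr_jitter_sd_s standard deviation of Gaussian RR-interval jitter, s.
#' @param noise_sd_mv standard deviation of additive white noise, mV.
#' @param baseline_wander_amp_mv,baseline_wander_hz amplitude (mV) and
#'   frequency (Hz) of sinusoidal baseline wander.
#' @return an object of class `beat_morphology`.
#' @export
beat_morphology <- function(
    r_amp_mv = c(I = 0.60, II = 1.00, III = 0.50, aVR = 0.15, aVL = 0.35,
                 aVF = 0.75, V1 = 0.25, V2 = 0.45, V3 = 0.90, V4 = 1.30,
                 V5 = 1.50, V6 = 1.20),
    s_amp_mv = c(I = -0.15, II = -0.20, III = -0.25, aVR = -0.60, aVL = -0.20,
                 aVF = -0.20, V1 = -1.10, V2 = -1.40, V3 = -0.90, V4 = -0.45,
                 V5 = -0.30, V6 = -0.20),
    q_amp_mv = stats::setNames(rep(-0.04, 12), CANONICAL_LEADS),
    p_amp_mv = stats::setNames(c(rep(0.10, 6), 0.05, rep(0.08, 5)), CANONICAL_LEADS),
    t_amp_mv = stats::setNames(c(rep(0.20, 6), 0.15, 0.35, 0.35, 0.30, 0.25, 0.20),
                               CANONICAL_LEADS),
    centers_s = c(P = -0.160, Q = -0.028, R = 0, S = 0.028, T = 0.300),
    widths_s = c(P = 0.022, Q = 0.009, R = 0.010, S = 0.009, T = 0.055),
    heart_rate_bpm = 60, rr_jitter_sd_s = 0.01, noise_sd_mv = 0.02,
    baseline_wander_amp_mv = 0.05, baseline_wander_hz = 0.33) {
  for (v in list(r_amp_mv, s_amp_mv, q_amp_mv, p_amp_mv, t_amp_mv))
    if (!all(CANONICAL_LEADS %in% names(v)))
      stop("wave amplitude vectors must name all 12 canonical leads")
  if (any(widths_s <= 0)) stop("wave widths must be positive")
  if (any(r_amp_mv < 0)) stop("R amplitudes must be >= 0")
  if (any(s_amp_mv > 0) || any(q_amp_mv > 0))
    stop("Q and S amplitudes must be <= 0")
  if (!(centers_s[["P"]] < centers_s[["Q"]] && centers_s[["Q"]] < centers_s[["R"]] &&
        centers_s[["R"]] < centers_s[["S"]] && centers_s[["S"]] < centers_s[["T"]]))
    stop("wave centers must be ordered P < Q < R < S < T")
  if (heart_rate_bpm <= 0) stop("heart rate must be positive")
  if (rr_jitter_sd_s < 0 || noise_sd_mv < 0 || baseline_wander_amp_mv < 0)
    stop("jitter, noise and wander amplitudes must be non-negative")
  structure(list(
    r_amp_mv = r_amp_mv[CANONICAL_LEADS], s_amp_mv = s_amp_mv[CANONICAL_LEADS],
    q_amp_mv = q_amp_mv[CANONICAL_LEADS], p_amp_mv = p_amp_mv[CANONICAL_LEADS],
    t_amp_mv = t_amp_mv[CANONICAL_LEADS],
    centers_s = centers_s, widths_s = widths_s,
    heart_rate_bpm = heart_rate_bpm, rr_jitter_sd_s = rr_jitter_sd_s,
    noise_sd_mv = noise_sd_mv,
    baseline_wander_amp_mv = baseline_wander_amp_mv,
    baseline_wander_hz = baseline_wander_hz
  ), class = "beat_morphology")
}

#' Generate one synthetic 12-lead ECG with ground truth
#'
#' The first beat fiducial is placed at 0.5 s (the detector's edge-exclusion
#' zone) and subsequent fiducials follow at the mean RR interval plus Gaussian
#' jitter, as long as a full beat fits before the record end. Each lead is the
#' sum of the per-beat Gaussian waves, sinusoidal baseline wander with a
#' seeded random phase, and white noise. The ground truth stores the noise-free
#' fiducials and per-beat, per-lead R amplitudes and S magnitudes.
#'
#' @param morphology a [beat_morphology()].
#' @param duration_s record length, s (must fit at least one beat).
#' @param sampling_rate_hz sampling rate, Hz.
#' @param seed integer seed; the same seed reproduces the record bit-for-bit.
#' @param record_id,sex passed to [ecg_record()].
#' @return a list with elements `record` (an `ecg_record`) and `truth` (class
#'   `ecg_ground_truth`: `fiducial_s`, `fiducial_sample`, and beats x leads
#'   matrices `r_amp_mv`, `s_amp_mv`).
#' @export
generate_ecg <- function(morphology = beat_morphology(), duration_s = 10,
                         sampling_rate_hz = 500, seed = 1,
                         record_id = "synth", sex = "unknown") {
  stopifnot(inherits(morphology, "beat_morphology"))
  m <- morphology
  rr <- 60 / m$heart_rate_bpm
  if (duration_s < 1)
    stop("duration too short for one beat (needs >= 1 s)")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  # beats live in [0.5, duration - 0.5]: the detector's edge-exclusion zones
  beats <- 0.5
  repeat {
    nxt <- beats[length(beats)] + rr +
      if (m$rr_jitter_sd_s > 0) stats::rnorm(1, 0, m$rr_jitter_sd_s) else 0
    if (nxt > duration_s - 0.5) break
    beats <- c(beats, nxt)
  }
  n <- round(duration_s * sampling_rate_hz)
  t <- (seq_len(n) - 1) / sampling_rate_hz
  wander_phase <- stats::runif(1, 0, 2 * pi)
  sig <- matrix(0, nrow = 12, ncol = n, dimnames = list(CANONICAL_LEADS, NULL))
  waves <- list(P = m$p_amp_mv, Q = m$q_amp_mv, R = m$r_amp_mv,
                S = m$s_amp_mv, T = m$t_amp_mv)
  for (w in names(waves)) {
    ctr <- m$centers_s[[w]]
    wid <- m$widths_s[[w]]
    # one Gaussian bump per beat, shared across leads up to the lead amplitude
    bump <- rowSums(vapply(beats, function(b) exp(-(t - b - ctr)^2 / (2 * wid^2)),
                           numeric(n)))
    sig <- sig + outer(waves[[w]], bump)
  }
  if (m$baseline_wander_amp_mv > 0)
    sig <- sig + matrix(rep(m$baseline_wander_amp_mv *
                              sin(2 * pi * m$baseline_wander_hz * t + wander_phase),
                            each = 12), nrow = 12)
  if (m$noise_sd_mv > 0)
    sig <- sig + matrix(stats::rnorm(12 * n, 0, m$noise_sd_mv), nrow = 12)
  rec <- ecg_record(sig, sampling_rate_hz, record_id = record_id, sex = sex)
  nb <- length(beats)
  truth <- structure(list(
    fiducial_s = beats,
    fiducial_sample = round(beats * sampling_rate_hz) + 1L,
    r_amp_mv = matrix(rep(m$r_amp_mv, each = nb), nrow = nb,
                      dimnames = list(NULL, CANONICAL_LEADS)),
    s_amp_mv = matrix(rep(abs(m$s_amp_mv), each = nb), nrow = nb,
                      dimnames = list(NULL, CANONICAL_LEADS))
  ), class = "ecg_ground_truth")
  list(record = rec, truth = truth)
}

#' Specification of a synthetic ECG-echo cohort
#'
#' Defines a cohort with a planted monotone relationship between LV mass index
#' (LVMI) and precordial voltage: each subject's LVMI is drawn from a
#' class-conditional normal (truncated at 30 g/m^2), and the S amplitudes of
#' V1--V3 and R amplitudes of V4--V6 are shifted by
#' `voltage_effect * (lvmi - reference_lvmi)` plus per-lead Gaussian amplitude
#' noise (clamped so S stays <= 0 and R >= 0). The reference LVH label is the
#' sex-specific LVMI cutoff applied with strict inequality.
#'
#' @param n_subjects number of subjects.
#' @param lvh_prevalence probability a subject is drawn from the LVH class;
#'   class-conditional LVMI draws are truncated to the class's side of the
#'   sex cutoff, so this is also the exact label prevalence.
#' @param lvmi_lvh_mean,lvmi_lvh_sd,lvmi_normal_mean,lvmi_normal_sd
#'   class-conditional LVMI distributions, g/m^2.
#' @param voltage_effect slope linking LVMI to voltage, mV per g/m^2.
#' @param reference_lvmi LVMI at which the template amplitudes apply, g/m^2.
#' @param amplitude_noise_sd_mv per-subject, per-lead amplitude noise, mV.
#' @param sex_ratio_female probability a subject is female.
#' @param lvh_cutoffs named vector `c(male=, female=)` of LVMI cutoffs, g/m^2.
#' @param duration_s,sampling_rate_hz per-record waveform parameters.
#' @param morphology baseline [beat_morphology()] template.
#' @param seed integer master seed; each subject's RNG stream is derived from
#'   `(seed, subject index)` so adding or removing subjects does not reshuffle
#'   the others.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 200, lvh_prevalence = 0.4,
                        lvmi_lvh_mean = 130, lvmi_lvh_sd = 20,
                        lvmi_normal_mean = 80, lvmi_normal_sd = 15,
                        voltage_effect = 0.01, reference_lvmi = 100,
                        amplitude_noise_sd_mv = 0.05, sex_ratio_female = 0.5,
                        lvh_cutoffs = c(male = 95, female = 115),
                        duration_s = 10, sampling_rate_hz = 500,
                        morphology = beat_morphology(), seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (lvh_prevalence < 0 || lvh_prevalence > 1)
    stop("lvh_prevalence must lie in [0, 1]")
  if (sex_ratio_female < 0 || sex_ratio_female > 1)
    stop("sex_ratio_female must lie in [0, 1]")
  if (amplitude_noise_sd_mv < 0) stop("amplitude_noise_sd_mv must be >= 0")
  if (!all(c("male", "female") %in% names(lvh_cutoffs)))
    stop("lvh_cutoffs must name male and female")
  structure(as.list(environment()), class = "cohort_spec")
}

# Per-subject RNG stream: a fixed odd multiplier keeps streams distinct and
# stable under insertion/removal of other subjects.
subject_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 2011L + i * 7919L
}

#' Generate a synthetic cohort with reference LVH labels
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `ecg_cohort`: a list of subjects, each with
#'   `record`, `truth`, `sex`, `lvmi_g_per_m2`, `lvh_label`; the manifest is
#'   available via [cohort_manifest()].
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    si <- subject_seed(spec$seed, i)
    set.seed(si)
    sex <- if (stats::runif(1) < spec$sex_ratio_female) "female" else "male"
    is_lvh_class <- stats::runif(1) < spec$lvh_prevalence
    mu <- if (is_lvh_class) spec$lvmi_lvh_mean else spec$lvmi_normal_mean
    sd <- if (is_lvh_class) spec$lvmi_lvh_sd else spec$lvmi_normal_sd
    # class-consistent truncation: LVH-class subjects lie above their sex's
    # cutoff and normal-class subjects at or below it, so lvh_prevalence is
    # the exact label prevalence
    cut <- spec$lvh_cutoffs[[sex]]
    repeat {
      lvmi <- stats::rnorm(1, mu, sd)
      if (lvmi > 30 && (lvmi > cut) == is_lvh_class) break
    }
    delta <- spec$voltage_effect * (lvmi - spec$reference_lvmi)
    m <- spec$morphology
    s <- m$s_amp_mv
    r <- m$r_amp_mv
    noise <- stats::rnorm(12, 0, spec$amplitude_noise_sd_mv)
    s[c("V1", "V2", "V3")] <- pmin(0, s[c("V1", "V2", "V3")] - delta + noise[1:3])
    r[c("V4", "V5", "V6")] <- pmax(0, r[c("V4", "V5", "V6")] + delta + noise[4:6])
    m$s_amp_mv <- s
    m$r_amp_mv <- r
    id <- sprintf("synth%04d", i)
    ge <- generate_ecg(m, duration_s = spec$duration_s,
                       sampling_rate_hz = spec$sampling_rate_hz,
                       seed = si + 1L, record_id = id, sex = sex)
    subjects[[i]] <- list(record = ge$record, truth = ge$truth, sex = sex,
                          lvmi_g_per_m2 = lvmi,
                          lvh_label = lvmi > spec$lvh_cutoffs[[sex]])
  }
  structure(list(subjects = subjects, spec = spec), class = "ecg_cohort")
}

#' Cohort manifest as a data frame
#' @param cohort an `ecg_cohort`.
#' @return data frame with record_id, sex, lvmi_g_per_m2, lvh_label.
#' @export
cohort_manifest <- function(cohort) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  do.call(rbind, lapply(cohort$subjects, function(s) data.frame(
    record_id = s$record$record_id, sex = s$sex,
    lvmi_g_per_m2 = s$lvmi_g_per_m2, lvh_label = s$lvh_label
  )))
}

#' @export
print.ecg_cohort <- function(x, ...) {
  man <- cohort_manifest(x)
  cat(sprintf("<ecg_cohort> %d subjects, %d (%.0f%%) LVH-labelled, %d female\n",
              nrow(man), sum(man$lvh_label), 100 * mean(man$lvh_label),
              sum(man$sex == "female")))
  invisible(x)
}
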