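# Shared fixtures. Cohorts are expensive (waveform generation + detection),
# so they are built once per test session and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a quiet morphology: no noise, no wander, no jitter
clean_morphology <- function(...) {
  beat_morphology(rr_jitter_sd_s = 0, noise_sd_mv = 0,
                  baseline_wander_amp_mv = 0, ...)
}

# widened QRS (about 1.8x the default, ~160 ms) for the WIDE_QRS flag
wide_qrs_morphology <- function() {
  beat_morphology(
    centers_s = c(P = -0.220, Q = -0.028 * 1.8, R = 0, S = 0.028 * 1.8, T = 0.320),
    widths_s = c(P = 0.022, Q = 0.009 * 1.8, R = 0.010 * 1.8, S = 0.009 * 1.8,
                 T = 0.055))
}

# hand-built amplitude matrix for criterion unit tests: r and s are named
# lists/vectors per lead, recycled across beats
make_amps <- function(r = NULL, s = NULL, n_beats = 1,
                      leads = c("I", "II", "III", "aVR", "aVL", "aVF",
                                paste0("V", 1:6))) {
  rm <- sm <- matrix(0, nrow = n_beats, ncol = length(leads),
                     dimnames = list(NULL, leads))
  for (ld in names(r)) rm[, ld] <- r[[ld]]
  for (ld in names(s)) sm[, ld] <- s[[ld]]
  structure(list(r_amp_mv = rm, s_amp_mv = sm,
                 baseline_mv = matrix(0, n_beats, length(leads)),
                 qrs_duration_ms = rep(90, n_beats), lead_names = leads),
            class = "amplitude_matrix")
}

default_cohort <- function() cached("default200", {
  generate_cohort(cohort_spec(n_subjects = 200, seed = 101))
})

null_cohort <- function() cached("null200", {
  generate_cohort(cohort_spec(n_subjects = 200, voltage_effect = 0, seed = 202))
})

separated_cohort <- function() cached("sep200", {
  generate_cohort(cohort_spec(n_subjects = 200, voltage_effect = 0.02,
                              lvmi_lvh_sd = 5, lvmi_normal_sd = 5,
                              amplitude_noise_sd_mv = 0.05, seed = 303))
})

# per-subject WS MMCV through the full chain (detection -> measurement -> WS)
ws_mmcv_scores <- function(cohort, key = NULL) {
  compute <- function() vapply(cohort$subjects, function(s) {
    bs <- detect_beats(s$record)
    mmcv(ws_per_beat(measure_amplitudes(s$record, bs)))
  }, 0)
  if (is.null(key)) compute() else cached(key, compute())
}
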