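# Shared fixtures: all built in code at test time.

# a minimal valid recording with deterministic contents
make_test_recording <- function(duration_s = 10, person_id = "T",
                                eeg_fs = 207, acc_fs = 10,
                                eeg_fun = function(t) 50 * sin(2 * pi * 5 * t),
                                acc_xyz = c(0, 0, 1)) {
  t_eeg <- (seq_len(duration_s * eeg_fs) - 1) / eeg_fs
  n_acc <- duration_s * acc_fs
  recording(person_id, list(
    channel_signal("EEG_prox", "eeg", eeg_fs, eeg_fun(t_eeg)),
    channel_signal("EEG_dist", "eeg", eeg_fs, 0.5 * eeg_fun(t_eeg)),
    channel_signal("ACC_x", "acc", acc_fs, rep(acc_xyz[1], n_acc)),
    channel_signal("ACC_y", "acc", acc_fs, rep(acc_xyz[2], n_acc)),
    channel_signal("ACC_z", "acc", acc_fs, rep(acc_xyz[3], n_acc))))
}

# the study annotation table rebuilt from its published per-person counts
# (25/15/12/22 electrographic) plus four FBTCS split between two persons
table1_annotations <- function() {
  counts <- c(B = 25, E = 15, G = 12, I = 22)
  fbtcs <- c(B = 2, E = 2, G = 0, I = 0)
  rows <- lapply(names(counts), function(p) {
    n <- counts[[p]] + fbtcs[[p]]
    lab <- rep("electrographic", n)
    if (fbtcs[[p]] > 0) lab[seq_len(fbtcs[[p]])] <- "FBTCS"
    seizure_annotations(person_id = p,
                        seizure_id = sprintf("%s_s%02d", p, seq_len(n)),
                        onset_s = 400 + (seq_len(n) - 1) * 500,
                        duration_s = 30, label = lab)
  })
  do.call(rbind, rows)
}

# planted-family map for recovery checks: movement = any accelerometer
# feature (the planted movement signal is the x posture shift; the other acc
# features are deterministic transforms of the same axes); emg = the EMG
# estimate and the >20 Hz EEG band it is defined from; EEG bands by name.
feature_family <- function(f) {
  if (grepl("^acc_", f)) "movement"
  else if (grepl("^emg_|gamma", f)) "emg"
  else if (grepl("delta", f)) "delta"
  else if (grepl("low_theta", f)) "low_theta"
  else if (grepl("high_theta", f)) "high_theta"
  else "other"
}

planted_families <- c("movement", "emg", "delta", "low_theta", "high_theta")

n_planted_families <- function(selected) {
  length(intersect(unique(vapply(selected, feature_family, character(1))),
                   planted_families))
}

# small two-person cohort for fast pipeline tests (10 seizures each, the
# inclusion minimum)
small_cohort <- function(seed = 1) {
  cohort_spec(list(
    person_profile("P1", eeg_band_gain = c(low_theta = 3), n_seizures = 10,
                   seizure_duration_s = c(15, 40), seed = derive2(seed, 1)),
    person_profile("P2", acc_shift_g = 0.4, n_seizures = 10,
                   seizure_duration_s = c(15, 40), seed = derive2(seed, 2))))
}

derive2 <- function(seed, k) as.integer((seed * 1009 + k * 9973) %% 2147483647)

# one shared fit of the small cohort per test session (several files use it)
small_report <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(
        analyze_cohort(small_cohort(1), run_config(seed = 1)))
    cache
  }
})

expect_ip_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
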