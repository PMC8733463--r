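# Synthetic multimodal cohort generator.
#
# Stands in for the restricted clinical recordings: per person, 1/f-coloured
# background EEG on two bipolar channels, constant-gravity accelerometry with
# white noise, and planted ictal signatures — band-limited EEG power gains,
# >20 Hz broadband "EMG" bursts on the proximal channel, and a smoothed
# x-axis posture shift with optional tremor. Months-long home recordings are
# compressed to desk scale: the inter-seizure gap (minutes) stands in for the
# study's hours-long intervals, leaving every pre-ictal/baseline window
# intact.

#' Define a synthetic person profile
#'
#' Gains are amplitude multipliers relative to background: a band gain g
#' multiplies that band's ictal power by g^2 (an independent band-limited
#' component with variance (g^2-1) x background band variance is added), so
#' g = 1 plants nothing.
#'
#' @param person_id Person identifier.
#' @param eeg_band_gain Named amplitude gains for bands `delta`, `low_theta`,
#'   `high_theta`, `alpha`, `beta` (missing names default to 1). Applied to
#'   both EEG channels during ictal intervals.
#' @param emg_burst_gain Amplitude gain of >20 Hz broadband bursts added to
#'   `EEG_prox` during ictal intervals.
#' @param acc_shift_g Ictal mean shift of `ACC_x` in g (smoothed step).
#' @param acc_tremor_amp Ictal 4 Hz oscillation amplitude on `ACC_x` in g.
#' @param n_seizures Number of electrographic seizures (>= 10, the cohort
#'   inclusion minimum).
#' @param seizure_duration_s Duration range `c(min, max)` in seconds
#'   (min > 6 so trimmed ictal periods stay analyzable).
#' @param seed Integer seed for this person's generator.
#' @return List of class `person_profile`.
#' @export
person_profile <- function(person_id, eeg_band_gain = c(),
                           emg_burst_gain = 1, acc_shift_g = 0,
                           acc_tremor_amp = 0, n_seizures = 12,
                           seizure_duration_s = c(15, 60), seed = 1) {
  gains <- c(delta = 1, low_theta = 1, high_theta = 1, alpha = 1, beta = 1)
  if (length(eeg_band_gain)) {
    bad <- setdiff(names(eeg_band_gain), names(gains))
    if (length(bad))
      ip_stop(sprintf("unknown EEG band(s): %s", paste(bad, collapse = ", ")),
              "ip_config_error")
    gains[names(eeg_band_gain)] <- eeg_band_gain
  }
  if (any(c(gains, emg_burst_gain) < 0) || acc_tremor_amp < 0)
    ip_stop("gains must be non-negative", "ip_config_error")
  if (n_seizures < 10)
    ip_stop("n_seizures must be >= 10 (cohort inclusion minimum)",
            "ip_config_error")
  if (seizure_duration_s[1] <= 6)
    ip_stop("minimum seizure duration must exceed 6 s", "ip_config_error")
  structure(list(person_id = as.character(person_id), eeg_band_gain = gains,
                 emg_burst_gain = emg_burst_gain, acc_shift_g = acc_shift_g,
                 acc_tremor_amp = acc_tremor_amp,
                 n_seizures = as.integer(n_seizures),
                 seizure_duration_s = as.numeric(seizure_duration_s),
                 seed = as.integer(seed)),
            class = "person_profile")
}

#' Define a synthetic cohort
#'
#' @param profiles List of [person_profile()]s with distinct ids.
#' @param interictal_gap_s Gap range `c(min, max)` in seconds between a
#'   seizure's end and the next onset. The default minimum (420 s) keeps every
#'   baseline window (ending 300 s before onset) clear of the preceding
#'   seizure.
#' @param background_eeg List: `alpha` (central 1/f exponent), `sd`
#'   (background EEG standard deviation, microvolts), `alpha_spread`
#'   (the background crossfades between slopes `alpha - alpha_spread` and
#'   `alpha + alpha_spread` on the drift timescale, emulating
#'   vigilance-driven spectral-slope changes that make broadband shape
#'   summaries unreliable in chronic recordings), `amp_mod_sd` (log-sd of
#'   the slow per-channel amplitude drift; chronic subcutaneous recordings
#'   are not amplitude-stationary, which is what makes relative powers the
#'   robust features), `amp_mod_block_s` (drift timescale, seconds),
#'   `dist_gain` (fraction of planted band power reaching the distal
#'   channel; the focal field falls off with contact distance).
#' @param background_acc List: `gravity` (unit vector, g), `noise_sd`
#'   (white sensor noise, g), `posture_sd` (slow per-axis posture drift on
#'   the drift timescale, g — people do not hold one trunk orientation for
#'   hours).
#' @param fbtcs_extra Named integer vector: FBTCS-labelled seizures to inject
#'   per person id (they carry the same planted signature and are removed by
#'   the cohort filter).
#' @param eeg_fs,acc_fs Sampling rates (207 Hz; 10 or 20 Hz).
#' @param ictal_intensity_jitter Per-seizure intensity spread: each seizure
#'   scales its person's planted signature by a uniform factor in
#'   `1 +/- jitter` (seizures of one person share a fingerprint but differ
#'   in intensity).
#' @param max_duration_s Optional cap on recording length; a timeline that
#'   cannot host all seizures within it is a configuration error.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(profiles, interictal_gap_s = c(420, 540),
                        background_eeg = list(alpha = 1, sd = 20,
                                              alpha_spread = 0.4,
                                              amp_mod_sd = 0.5,
                                              amp_mod_block_s = 60,
                                              dist_gain = 0.02),
                        background_acc = list(gravity = c(0, 0, 1),
                                              noise_sd = 0.02,
                                              posture_sd = 0.1),
                        fbtcs_extra = NULL, eeg_fs = 207, acc_fs = 10,
                        ictal_intensity_jitter = 0.3,
                        max_duration_s = NULL) {
  ids <- vapply(profiles, function(p) p$person_id, character(1))
  if (anyDuplicated(ids))
    ip_stop("person ids must be distinct", "ip_config_error")
  structure(list(profiles = profiles, interictal_gap_s = interictal_gap_s,
                 background_eeg = background_eeg,
                 background_acc = background_acc,
                 fbtcs_extra = fbtcs_extra, eeg_fs = eeg_fs, acc_fs = acc_fs,
                 ictal_intensity_jitter = ictal_intensity_jitter,
                 max_duration_s = max_duration_s),
            class = "cohort_spec")
}

# -- coloured / band-limited noise by FFT shaping ---------------------------

# two-sided spectral amplitude profile for 1/f^alpha noise on m bins;
# frequencies below 0.1 Hz are clamped (AC-coupled recordings have no true DC)
colored_profile <- function(m, fs, alpha) {
  f <- (seq_len(m) - 1L) * fs / m
  f_eff <- pmin(f, fs - f)
  f_eff <- pmax(f_eff, 0.1)
  h <- f_eff^(-alpha / 2)
  h[1] <- 0
  h
}

colored_noise <- function(n, fs, alpha, sd_target) {
  m <- stats::nextn(n)
  h <- colored_profile(m, fs, alpha)
  x <- Re(stats::fft(stats::fft(stats::rnorm(m)) * h, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x * (sd_target / stats::sd(x))
}

# fraction of background variance inside [lo, hi] under the 1/f^alpha profile
band_var_fraction <- function(fs, alpha, lo, hi, m = 2^16) {
  h <- colored_profile(m, fs, alpha)
  f <- (seq_len(m) - 1L) * fs / m
  half <- f <= fs / 2
  inband <- half & f >= lo & f <= hi
  sum(h[inband]^2) / sum(h[half]^2)
}

# brickwall band-limited Gaussian noise, unit sd
band_noise <- function(n, fs, lo, hi) {
  m <- stats::nextn(max(n, as.integer(4 * fs)))
  f <- (seq_len(m) - 1L) * fs / m
  f_eff <- pmin(f, fs - f)
  keep <- f_eff >= lo & f_eff <= hi
  X <- stats::fft(stats::rnorm(m)) * keep
  x <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)] / m
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# piecewise-linear slow modulation: knot values drawn by rdraw every
# block_s seconds, linearly interpolated onto the sample grid
slow_modulation <- function(n, fs, total_s, block_s, rdraw) {
  n_knots <- ceiling(total_s / block_s) + 1L
  knots <- rdraw(n_knots)
  stats::approx(seq(0, by = block_s, length.out = n_knots), knots,
                xout = (seq_len(n) - 1L) / fs, rule = 2)$y
}

# narrow sub-band hosting a band's planted ictal rhythm: centred on the
# band midpoint, width the smaller of 1.5 Hz and half the band width
rhythm_band <- function(band, max_width = 1.5) {
  w <- min(max_width, diff(band) / 2)
  mid <- mean(band)
  c(mid - w / 2, mid + w / 2)
}

# raised-cosine on/off envelope with ramp_s second ramps
ictal_envelope <- function(n, fs, ramp_s = 2) {
  r <- min(as.integer(ramp_s * fs), n %/% 2L)
  env <- rep(1, n)
  if (r > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- ramp
    env[(n - r + 1L):n] <- rev(ramp)
  }
  env
}

#' Simulate one person's recording with planted ictal signatures
#'
#' Reproducible given the profile seed: the same profile and cohort always
#' yield sample-identical channels and identical annotations. Seizure onsets
#' are placed sequentially with uniform random gaps; the recording length is
#' sized to host them (plus a lead-in long enough for the first baseline
#' window) unless `max_duration_s` caps it.
#'
#' @param profile A [person_profile()] belonging to `cohort`.
#' @param cohort A [cohort_spec()].
#' @return List with `recording` and `annotations`.
#' @export
simulate_recording <- function(profile, cohort) {
  ids <- vapply(cohort$profiles, function(p) p$person_id, character(1))
  if (!profile$person_id %in% ids)
    ip_stop("profile is not part of the cohort", "ip_config_error")
  if (exists(".Random.seed", globalenv()))
    old_seed <- get(".Random.seed", globalenv()) else old_seed <- NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(profile$seed)

  n_fbtcs <- 0L
  if (!is.null(cohort$fbtcs_extra) &&
      profile$person_id %in% names(cohort$fbtcs_extra))
    n_fbtcs <- as.integer(cohort$fbtcs_extra[[profile$person_id]])
  n_total <- profile$n_seizures + n_fbtcs

  gaps <- stats::runif(n_total, cohort$interictal_gap_s[1],
                       cohort$interictal_gap_s[2])
  durs <- stats::runif(n_total, profile$seizure_duration_s[1],
                       profile$seizure_duration_s[2])
  onsets <- numeric(n_total)
  prev_end <- 0
  for (i in seq_len(n_total)) {
    onsets[i] <- prev_end + gaps[i]
    prev_end <- onsets[i] + durs[i]
  }
  total_s <- ceiling(prev_end + 60)
  if (!is.null(cohort$max_duration_s) && total_s > cohort$max_duration_s)
    ip_stop(sprintf(
      "timeline of %d s exceeds max_duration_s = %g; too short to host %d seizures with the configured gaps",
      total_s, cohort$max_duration_s, n_total), "ip_config_error")
  fbtcs_idx <- if (n_fbtcs > 0) sort(sample.int(n_total, n_fbtcs)) else integer()

  fs <- cohort$eeg_fs
  afs <- cohort$acc_fs
  alpha <- cohort$background_eeg$alpha
  bg_sd <- cohort$background_eeg$sd
  n_eeg <- as.integer(total_s * fs)
  n_acc <- as.integer(total_s * afs)

  spread <- cohort$background_eeg$alpha_spread %||% 0
  block <- cohort$background_eeg$amp_mod_block_s %||% 60
  make_background <- function() {
    if (spread > 0) {
      # crossfade between a shallow and a steep 1/f slope on the drift
      # timescale: broadband spectral shape is not stationary in chronic
      # recordings, only planted band contrasts are
      x1 <- colored_noise(n_eeg, fs, alpha - spread, 1)
      x2 <- colored_noise(n_eeg, fs, alpha + spread, 1)
      w <- slow_modulation(n_eeg, fs, total_s, block,
                           function(k) stats::runif(k))
      bg_sd * (sqrt(w) * x1 + sqrt(1 - w) * x2)
    } else {
      colored_noise(n_eeg, fs, alpha, bg_sd)
    }
  }
  eeg <- list(EEG_prox = make_background(), EEG_dist = make_background())
  g0 <- cohort$background_acc$gravity
  nsd <- cohort$background_acc$noise_sd
  psd_acc <- cohort$background_acc$posture_sd %||% 0
  make_axis <- function(gcomp) {
    drift <- if (psd_acc > 0)
      slow_modulation(n_acc, afs, total_s, block,
                      function(k) stats::rnorm(k, 0, psd_acc)) else 0
    gcomp + drift + stats::rnorm(n_acc, sd = nsd)
  }
  acc <- list(ACC_x = make_axis(g0[1]), ACC_y = make_axis(g0[2]),
              ACC_z = make_axis(g0[3]))

  band_sd <- function(lo, hi)
    bg_sd * sqrt(mean(c(band_var_fraction(fs, alpha - spread, lo, hi),
                        band_var_fraction(fs, alpha + spread, lo, hi))))
  emg_band <- c(20, fs / 2 - 3)

  # per-seizure intensity: seizures of one person share a signature but vary
  # in how strongly it expresses
  jit <- cohort$ictal_intensity_jitter %||% 0.3
  intensity <- stats::runif(n_total, 1 - jit, 1 + jit)
  for (i in seq_len(n_total)) {
    i0 <- floor(onsets[i] * fs) + 1L
    i1 <- min(floor((onsets[i] + durs[i]) * fs), n_eeg)
    L <- i1 - i0 + 1L
    env <- ictal_envelope(L, fs)
    u <- intensity[i]
    for (chan in names(eeg)) {
      reach <- if (chan == "EEG_dist")
        cohort$background_eeg$dist_gain %||% 0.02 else 1
      for (b in names(profile$eeg_band_gain)) {
        g <- 1 + (profile$eeg_band_gain[[b]] - 1) * u
        if (g == 1) next
        # ictal discharges are narrowband rhythms: plant in a sub-band
        # around the band centre rather than across the whole band
        bb <- rhythm_band(EEG_BANDS[[b]])
        amp <- sqrt(max(g^2 - 1, 0) * reach) * band_sd(bb[1], bb[2])
        eeg[[chan]][i0:i1] <- eeg[[chan]][i0:i1] +
          amp * band_noise(L, fs, bb[1], bb[2]) * env
      }
    }
    if (profile$emg_burst_gain != 1) {
      g <- 1 + (profile$emg_burst_gain - 1) * u
      amp <- sqrt(max(g^2 - 1, 0)) * band_sd(emg_band[1], emg_band[2])
      eeg$EEG_prox[i0:i1] <- eeg$EEG_prox[i0:i1] +
        amp * band_noise(L, fs, emg_band[1], emg_band[2]) * env
    }
    a0 <- floor(onsets[i] * afs) + 1L
    a1 <- min(floor((onsets[i] + durs[i]) * afs), n_acc)
    La <- a1 - a0 + 1L
    if (La > 0 && (profile$acc_shift_g != 0 || profile$acc_tremor_amp > 0)) {
      aenv <- ictal_envelope(La, afs)
      tt <- seq_len(La) / afs
      acc$ACC_x[a0:a1] <- acc$ACC_x[a0:a1] +
        profile$acc_shift_g * u * aenv +
        profile$acc_tremor_amp * u * sin(2 * pi * 4 * tt) * aenv
    }
  }

  # slow per-channel amplitude drift: chronic recordings are not
  # amplitude-stationary; planted components ride the same drift, so
  # relative (scale-invariant) features are unaffected
  mod_sd <- cohort$background_eeg$amp_mod_sd %||% 0
  if (mod_sd > 0) {
    block <- cohort$background_eeg$amp_mod_block_s %||% 60
    n_knots <- ceiling(total_s / block) + 1L
    for (chan in names(eeg)) {
      knots <- exp(stats::rnorm(n_knots, 0, mod_sd))
      envm <- stats::approx(seq(0, by = block, length.out = n_knots), knots,
                            xout = (seq_len(n_eeg) - 1L) / fs, rule = 2)$y
      eeg[[chan]] <- eeg[[chan]] * envm
    }
  }

  channels <- c(
    lapply(names(eeg), function(l)
      channel_signal(l, "eeg", fs, eeg[[l]], "uV")),
    lapply(names(acc), function(l)
      channel_signal(l, "acc", afs, acc[[l]], "g")))
  rec <- recording(profile$person_id, channels)

  labels <- rep("electrographic", n_total)
  labels[fbtcs_idx] <- "FBTCS"
  annos <- seizure_annotations(
    person_id = profile$person_id,
    seizure_id = sprintf("%s_s%02d", profile$person_id, seq_len(n_total)),
    onset_s = onsets, duration_s = durs, label = labels)
  list(recording = rec, annotations = annos)
}

#' Simulate a cohort to disk
#'
#' Writes one EDF per person, a combined annotation CSV and a JSON manifest
#' recording seeds and generator parameters. Identical specs and seeds give
#' byte-identical CSV/manifest and sample-identical EDFs.
#'
#' @param cohort A [cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly (list with `edf_paths`,
#'   `annotation_path`, `manifest_path`, `seeds`).
#' @export
simulate_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  edf_paths <- character(0)
  annos <- NULL
  for (p in cohort$profiles) {
    sim <- simulate_recording(p, cohort)
    path <- file.path(out_dir, sprintf("person_%s.edf", p$person_id))
    write_recording(sim$recording, path)
    edf_paths[p$person_id] <- path
    annos <- if (is.null(annos)) sim$annotations else
      rbind(annos, sim$annotations)
  }
  anno_path <- file.path(out_dir, "annotations.csv")
  write_annotations(annos, anno_path)
  manifest <- list(
    edf_paths = as.list(edf_paths),
    annotation_path = anno_path,
    seeds = stats::setNames(
      lapply(cohort$profiles, function(p) p$seed),
      vapply(cohort$profiles, function(p) p$person_id, character(1))),
    parameters = list(
      interictal_gap_s = cohort$interictal_gap_s,
      background_eeg = cohort$background_eeg,
      background_acc = cohort$background_acc,
      eeg_fs = cohort$eeg_fs, acc_fs = cohort$acc_fs))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest$manifest_path <- manifest_path
  invisible(manifest)
}

#' The default four-person archetype cohort
#'
#' Mirrors the study cohort structure: four persons with 25/15/12/22
#' electrographic seizures plus four FBTCS split between two of them, and the
#' four fingerprint archetypes — B theta-dominant, E mixed theta + movement,
#' G EMG-dominant, I movement-dominant with delta slowing. Dominant planted
#' gains are at least 3x background amplitude.
#'
#' @param seed Global seed; per-person seeds are derived from it.
#' @param n_seizures Named electrographic seizure counts.
#' @param signature_scale Scales every planted signature: amplitude gains
#'   become `1 + scale * (gain - 1)` and shifts `scale * shift`, so 0 gives a
#'   signature-free null cohort and 1 the full archetypes.
#' @param acc_fs Accelerometer rate (10 or 20 Hz).
#' @return A [cohort_spec()].
#' @export
archetype_cohort <- function(seed = 1,
                             n_seizures = c(B = 25, E = 15, G = 12, I = 22),
                             signature_scale = 1, acc_fs = 10) {
  s <- signature_scale
  gs <- function(g) 1 + s * (g - 1)
  profiles <- list(
    person_profile("B", eeg_band_gain = c(low_theta = gs(3)),
                   n_seizures = n_seizures[["B"]],
                   seed = derive_seed(seed, 1L)),
    person_profile("E", eeg_band_gain = c(high_theta = gs(3)),
                   acc_shift_g = s * 0.3,
                   n_seizures = n_seizures[["E"]],
                   seed = derive_seed(seed, 2L)),
    person_profile("G", emg_burst_gain = gs(3),
                   n_seizures = n_seizures[["G"]],
                   seed = derive_seed(seed, 3L)),
    person_profile("I", eeg_band_gain = c(delta = gs(3)),
                   acc_shift_g = s * 0.4,
                   n_seizures = n_seizures[["I"]],
                   seed = derive_seed(seed, 4L)))
  cohort_spec(profiles, fbtcs_extra = c(B = 2L, E = 2L), acc_fs = acc_fs)
}
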