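# The multimodal feature catalogue (~70 features over EEG, estimated EMG and
# trunk accelerometry) and its evaluation on analysis periods.
#
# The catalogue is a reconstruction spanning all three modalities and
# containing, verbatim-named, the five fingerprint features:
#   F1 acc_x_mean            x-axis acceleration component
#   F2 emg_power_prox        >20 Hz power at the proximal contact
#   F3 eeg_relpow_delta      EEG relative delta power (0.5-4 Hz)
#   F4 eeg_relpow_low_theta  EEG relative low-theta power (4-6 Hz)
#   F5 eeg_relpow_high_theta EEG relative high-theta power (6-8 Hz)
# Proximal-channel EEG/EMG features carry no suffix; distal ones end "_dist".

EEG_BANDS <- list(delta = c(0.5, 4), low_theta = c(4, 6), high_theta = c(6, 8),
                  alpha = c(8, 12), beta = c(12, 20), gamma = c(20, 48))
TOTAL_BAND <- c(0.5, 48)

#' The feature catalogue
#'
#' Enumerates the features computed per analysis period, as data: one row per
#' feature with its name, modality and source channel. The default catalogue
#' has 65 entries; the `"paper5"` preset is the five-feature fingerprint in
#' F1--F5 order.
#'
#' @param preset `"default"` or `"paper5"`.
#' @return Data frame (class `feature_catalog`) with columns `name`,
#'   `modality` (`eeg`, `emg`, `acc`), `channel`.
#' @export
feature_catalog <- function(preset = c("default", "paper5")) {
  preset <- match.arg(preset)
  eeg_one <- function(suffix, chan) {
    nm <- c(paste0("eeg_abspow_", names(EEG_BANDS)),
            paste0("eeg_relpow_", names(EEG_BANDS)),
            "eeg_totpow", "eeg_sef95", "eeg_peakfreq", "eeg_linelength",
            "eeg_hjorth_activity", "eeg_hjorth_mobility",
            "eeg_hjorth_complexity")
    data.frame(name = paste0(nm, suffix), modality = "eeg", channel = chan,
               stringsAsFactors = FALSE)
  }
  emg_one <- function(suffix, chan) {
    nm <- c("emg_power", "emg_relpow", "emg_rms_mean", "emg_rms_max",
            "emg_zcr")
    data.frame(name = paste0(nm, suffix), modality = "emg", channel = chan,
               stringsAsFactors = FALSE)
  }
  acc <- data.frame(
    name = c("acc_x_mean", "acc_y_mean", "acc_z_mean",
             "acc_x_sd", "acc_y_sd", "acc_z_sd",
             "acc_mag_mean", "acc_mag_sd", "acc_pitch", "acc_roll",
             "acc_sma", "acc_x_mad", "acc_y_mad", "acc_z_mad",
             "acc_mag_mad", "acc_mag_domfreq", "acc_move_frac"),
    modality = "acc", channel = "all", stringsAsFactors = FALSE)
  cat <- rbind(eeg_one("", "EEG_prox"), eeg_one("_dist", "EEG_dist"),
               emg_one("_prox", "EEG_prox"), emg_one("_dist", "EEG_dist"),
               acc)
  if (preset == "paper5")
    cat <- cat[match(c("acc_x_mean", "emg_power_prox", "eeg_relpow_delta",
                       "eeg_relpow_low_theta", "eeg_relpow_high_theta"),
                     cat$name), , drop = FALSE]
  rownames(cat) <- NULL
  class(cat) <- unique(c("feature_catalog", class(cat)))
  cat
}

#' Hjorth parameters
#'
#' Time-domain spectral descriptors: activity (variance), mobility
#' (RMS frequency proxy, from the variance ratio of the first difference) and
#' complexity (mobility of the first difference over mobility of the signal).
#' @param x Numeric vector.
#' @return Named vector `activity`, `mobility`, `complexity`.
#' @export
hjorth_params <- function(x) {
  v0 <- stats::var(x)
  d1 <- diff(x); v1 <- stats::var(d1)
  d2 <- diff(d1); v2 <- stats::var(d2)
  mob <- if (v0 > 0) sqrt(v1 / v0) else 0
  mob1 <- if (v1 > 0) sqrt(v2 / v1) else 0
  c(activity = v0, mobility = mob,
    complexity = if (mob > 0) mob1 / mob else 0)
}

#' Accelerometer feature set for one period
#'
#' Computed at the native accelerometer rate. Means/SDs per axis and for the
#' magnitude vector, pitch/roll from the mean gravity projection (degrees),
#' signal-magnitude area, mean absolute first difference per axis and for the
#' magnitude (scaled by `fs`, i.e. g/s), dominant frequency of the magnitude,
#' and the fraction of samples whose magnitude deviates from its mean by more
#' than `move_threshold`.
#'
#' @param ax,ay,az Axis sample vectors in g, equal lengths.
#' @param fs Sampling rate (10 or 20 Hz).
#' @param move_threshold Movement threshold in g (default 0.05).
#' @return Named numeric vector of 17 features.
#' @export
acc_features <- function(ax, ay, az, fs, move_threshold = 0.05) {
  n <- length(ax)
  if (length(ay) != n || length(az) != n)
    ip_stop("accelerometer axes have unequal lengths", "ip_argument_error")
  if (n < 2 * fs)
    ip_stop(sprintf("accelerometer period of %d samples < 2 s at %g Hz", n, fs),
            "ip_length_error")
  m <- sqrt(ax^2 + ay^2 + az^2)
  mx <- mean(ax); my <- mean(ay); mz <- mean(az)
  mad_fs <- function(v) mean(abs(diff(v))) * fs
  domfreq <- {
    psd <- estimate_psd(m, fs)
    peak_frequency(psd, band = c(0.3, fs / 2))
  }
  c(acc_x_mean = mx, acc_y_mean = my, acc_z_mean = mz,
    acc_x_sd = stats::sd(ax), acc_y_sd = stats::sd(ay),
    acc_z_sd = stats::sd(az),
    acc_mag_mean = mean(m), acc_mag_sd = stats::sd(m),
    acc_pitch = atan2(mx, sqrt(my^2 + mz^2)) * 180 / pi,
    acc_roll = atan2(my, sqrt(mx^2 + mz^2)) * 180 / pi,
    acc_sma = mean(abs(ax) + abs(ay) + abs(az)),
    acc_x_mad = mad_fs(ax), acc_y_mad = mad_fs(ay), acc_z_mad = mad_fs(az),
    acc_mag_mad = mad_fs(m),
    acc_mag_domfreq = domfreq,
    acc_move_frac = mean(abs(m - mean(m)) > move_threshold))
}

# EMG time-domain descriptors on one EEG channel: >20 Hz high-passed signal,
# windowed RMS (1 s) mean/max and zero-crossing rate per second.
emg_time_features <- function(x, fs, lo = 20) {
  bf <- signal::butter(4, lo / (fs / 2), type = "high")
  xf <- signal::filtfilt(bf, x - mean(x))
  L <- as.integer(fs)
  nwin <- length(xf) %/% L
  rms <- vapply(seq_len(nwin), function(k)
    sqrt(mean(xf[((k - 1L) * L + 1L):(k * L)]^2)), numeric(1))
  zc <- sum(diff(sign(xf)) != 0) / (length(xf) / fs)
  c(rms_mean = mean(rms), rms_max = max(rms), zcr = zc)
}

# All 65 default features for one period of a recording. Returns a named
# numeric vector in catalogue order.
period_features <- function(rec, start_s, end_s, move_threshold = 0.05,
                            window_s = 2) {
  out <- c()
  for (spec in list(c("", "EEG_prox"), c("_dist", "EEG_dist"))) {
    ch <- get_channel(rec, spec[2])
    x <- slice_channel(ch, start_s, end_s)
    psd <- estimate_psd(x, ch$fs, window_s = window_s)
    tot <- band_power(psd, TOTAL_BAND[1], TOTAL_BAND[2])
    abs_p <- vapply(EEG_BANDS, function(b) band_power(psd, b[1], b[2]),
                    numeric(1))
    rel_p <- if (tot > 0) abs_p / tot else abs_p * 0
    hj <- hjorth_params(x)
    eeg <- c(stats::setNames(abs_p, paste0("eeg_abspow_", names(EEG_BANDS))),
             stats::setNames(rel_p, paste0("eeg_relpow_", names(EEG_BANDS))),
             eeg_totpow = tot,
             eeg_sef95 = spectral_edge(psd, 0.95, TOTAL_BAND),
             eeg_peakfreq = peak_frequency(psd, TOTAL_BAND),
             eeg_linelength = mean(abs(diff(x))) * ch$fs,
             eeg_hjorth_activity = unname(hj["activity"]),
             eeg_hjorth_mobility = unname(hj["mobility"]),
             eeg_hjorth_complexity = unname(hj["complexity"]))
    ep <- band_power(psd, 20, ch$fs / 2 - 3)
    etot <- band_power(psd, 0.5, ch$fs / 2 - 3)
    tf <- emg_time_features(x, ch$fs)
    emg <- c(emg_power = ep,
             emg_relpow = if (etot > 0) ep / etot else 0,
             emg_rms_mean = unname(tf["rms_mean"]),
             emg_rms_max = unname(tf["rms_max"]),
             emg_zcr = unname(tf["zcr"]))
    suf <- if (spec[1] == "") c("", "_prox") else c("_dist", "_dist")
    names(eeg) <- paste0(names(eeg), suf[1])
    names(emg) <- paste0(names(emg), suf[2])
    out <- c(out, eeg, emg)
  }
  axch <- get_channel(rec, "ACC_x")
  acc <- acc_features(slice_channel(axch, start_s, end_s),
                      slice_channel(get_channel(rec, "ACC_y"), start_s, end_s),
                      slice_channel(get_channel(rec, "ACC_z"), start_s, end_s),
                      axch$fs, move_threshold = move_threshold)
  # interleave EEG/EMG blocks back into catalogue order
  full <- c(out, acc)
  cat_names <- feature_catalog("default")$name
  full[cat_names]
}

#' Compute the feature table for a set of analysis periods
#'
#' One row per period, one column per catalogue feature, preceded by the
#' metadata columns `person_id`, `seizure_id`, `kind`. A period on which any
#' feature fails (e.g. too short for the spectral estimator) is dropped and
#' the reason logged in the `drop_log` attribute; emitted rows have no
#' missing values.
#'
#' @param rec A [recording()].
#' @param periods An `analysis_periods` data frame from [extract_periods()].
#' @param catalog A [feature_catalog()] (default full catalogue).
#' @param move_threshold Movement threshold in g for `acc_move_frac`.
#' @return Data frame of class `feature_table`.
#' @export
compute_feature_table <- function(rec, periods,
                                  catalog = feature_catalog("default"),
                                  move_threshold = 0.05) {
  if (nrow(periods) && any(periods$person_id != rec$person_id))
    ip_stop("periods refer to a different person than the recording",
            "ip_validation_error")
  rows <- vector("list", nrow(periods))
  drops <- list()
  for (i in seq_len(nrow(periods))) {
    p <- periods[i, ]
    vals <- tryCatch(
      period_features(rec, p$start_s, p$end_s,
                      move_threshold = move_threshold)[catalog$name],
      ictalprint_error = function(e) {
        if (inherits(e, "ip_bounds_error")) stop(e)  # outside the recording
        e
      })
    if (inherits(vals, "error")) {
      drops[[length(drops) + 1L]] <-
        data.frame(person_id = p$person_id, seizure_id = p$seizure_id,
                   kind = p$kind, reason = conditionMessage(vals),
                   stringsAsFactors = FALSE)
      next
    }
    if (anyNA(vals)) {
      drops[[length(drops) + 1L]] <-
        data.frame(person_id = p$person_id, seizure_id = p$seizure_id,
                   kind = p$kind,
                   reason = paste("missing feature value(s):",
                                  paste(catalog$name[is.na(vals)], collapse = ", ")),
                   stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- cbind(
      data.frame(person_id = p$person_id, seizure_id = p$seizure_id,
                 kind = p$kind, stringsAsFactors = FALSE),
      as.data.frame(as.list(vals)))
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(
      cbind(data.frame(person_id = character(), seizure_id = character(),
                       kind = character(), stringsAsFactors = FALSE),
            as.data.frame(matrix(numeric(), 0, nrow(catalog)))),
      c("person_id", "seizure_id", "kind", catalog$name))
  rownames(tab) <- NULL
  attr(tab, "drop_log") <- if (length(drops)) do.call(rbind, drops) else NULL
  class(tab) <- unique(c("feature_table", class(tab)))
  tab
}

#' Names of the metadata columns of a feature table
#' @return Character vector.
#' @export
feature_meta_cols <- function() c("person_id", "seizure_id", "kind")

# numeric feature matrix of a feature_table (rows x features)
feature_matrix <- function(table, features = NULL) {
  feats <- features %||% setdiff(names(table), feature_meta_cols())
  as.matrix(table[, feats, drop = FALSE])
}
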