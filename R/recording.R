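#' Construct a channel signal
#'
#' A single uniformly sampled channel of a multimodal recording. EEG channels
#' are bipolar subcutaneous EEG in microvolts sampled at 207 Hz; accelerometer
#' channels are trunk acceleration in g sampled at 10 or 20 Hz.
#'
#' @param label Channel label, one of `"EEG_prox"`, `"EEG_dist"`, `"ACC_x"`,
#'   `"ACC_y"`, `"ACC_z"` (aliases can be mapped at read time).
#' @param role `"eeg"` or `"acc"`.
#' @param fs Sampling rate in samples/second (EEG 207 unless overridden;
#'   accelerometer 10 or 20).
#' @param samples Numeric vector of samples.
#' @param units Physical units string (`"uV"` for EEG, `"g"` for acceleration).
#' @return An object of class `channel_signal`.
#' @export
channel_signal <- function(label, role = c("eeg", "acc"), fs, samples,
                           units = if (role == "eeg") "uV" else "g") {
  role <- match.arg(role)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    ip_stop("fs must be a single positive number", "ip_validation_error")
  structure(
    list(label = as.character(label), role = role, fs = as.numeric(fs),
         samples = as.numeric(samples), units = as.character(units)),
    class = "channel_signal"
  )
}

#' Construct a multimodal recording
#'
#' One person's recording: exactly two bipolar subcutaneous EEG channels
#' (`EEG_prox`, `EEG_dist`) and three accelerometer axes (`ACC_x`, `ACC_y`,
#' `ACC_z`), each at its own sampling rate, sharing a common start time.
#'
#' @param person_id Person identifier.
#' @param channels List of [channel_signal()] objects.
#' @param start_time Recording start in seconds (absolute clock time is
#'   carried but unused by the analysis; all onsets are relative).
#' @param allow_eeg_fs If `TRUE`, EEG channels may have a sampling rate other
#'   than 207 Hz.
#' @return An object of class `recording`.
#' @export
recording <- function(person_id, channels, start_time = 0,
                      allow_eeg_fs = FALSE) {
  rec <- structure(
    list(person_id = as.character(person_id), channels = channels,
         start_time = as.numeric(start_time)),
    class = "recording"
  )
  validate_recording(rec, allow_eeg_fs = allow_eeg_fs)
  rec
}

required_channel_labels <- function() {
  c("EEG_prox", "EEG_dist", "ACC_x", "ACC_y", "ACC_z")
}

#' Validate a recording against the channel-set invariants
#'
#' Checks the 2 EEG + 3 accelerometer channel set, sampling rates (EEG 207 Hz,
#' accelerometer 10 or 20 Hz) and that channel durations agree to within one
#' sample period of the slowest channel.
#'
#' @param rec A [recording()].
#' @param allow_eeg_fs Allow non-207 Hz EEG.
#' @return `rec`, invisibly.
#' @export
validate_recording <- function(rec, allow_eeg_fs = FALSE) {
  labs <- vapply(rec$channels, function(ch) ch$label, character(1))
  req <- required_channel_labels()
  missing <- setdiff(req, labs)
  if (length(missing) || length(labs) != 5L || anyDuplicated(labs))
    ip_stop(sprintf(
      "recording must contain exactly the channels %s; missing or extra: %s",
      paste(req, collapse = ", "),
      paste(c(missing, setdiff(labs, req), labs[duplicated(labs)]),
            collapse = ", ")), "ip_format_error")
  for (ch in rec$channels) {
    expected_role <- if (grepl("^EEG", ch$label)) "eeg" else "acc"
    if (ch$role != expected_role)
      ip_stop(sprintf("channel %s has role %s, expected %s",
                      ch$label, ch$role, expected_role), "ip_format_error")
    if (ch$role == "eeg" && !allow_eeg_fs && ch$fs != 207)
      ip_stop(sprintf("EEG channel %s sampled at %g Hz; 207 Hz required",
                      ch$label, ch$fs), "ip_validation_error")
    if (ch$role == "acc" && !ch$fs %in% c(10, 20))
      ip_stop(sprintf("accelerometer channel %s sampled at %g Hz; 10 or 20 Hz required",
                      ch$label, ch$fs), "ip_validation_error")
  }
  durs <- vapply(rec$channels, function(ch) length(ch$samples) / ch$fs,
                 numeric(1))
  slowest <- min(vapply(rec$channels, function(ch) ch$fs, numeric(1)))
  if (diff(range(durs)) >= 1 / slowest)
    ip_stop(sprintf(
      "channel durations differ by %.3f s (>= one sample period of the slowest channel)",
      diff(range(durs))), "ip_validation_error")
  invisible(rec)
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> person %s, %.1f s\n", x$person_id,
              recording_duration(x)))
  for (ch in x$channels)
    cat(sprintf("  %-8s %-3s %6g Hz  %8d samples [%s]\n",
                ch$label, ch$role, ch$fs, length(ch$samples), ch$units))
  invisible(x)
}

#' Recording duration in seconds
#'
#' Duration of the shortest channel (channels may differ by less than one
#' sample period of the slowest channel).
#' @param rec A [recording()].
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) {
  min(vapply(rec$channels, function(ch) length(ch$samples) / ch$fs, numeric(1)))
}

#' Fetch a channel by label
#' @param rec A [recording()].
#' @param label Channel label.
#' @return The matching [channel_signal()].
#' @export
get_channel <- function(rec, label) {
  for (ch in rec$channels) if (ch$label == label) return(ch)
  ip_stop(sprintf("no channel labelled %s", label), "ip_format_error")
}

#' Slice one channel over a time window
#'
#' Half-open window `[start_s, end_s)` converted to sample indices with
#' `floor(t * fs)` (zero-based), the convention used throughout the package.
#' @param ch A [channel_signal()].
#' @param start_s,end_s Window bounds in seconds from recording start.
#' @return Numeric vector of samples.
#' @export
slice_channel <- function(ch, start_s, end_s) {
  if (end_s <= start_s)
    ip_stop("end_s must exceed start_s", "ip_validation_error")
  i0 <- floor(start_s * ch$fs)
  i1 <- floor(end_s * ch$fs)
  if (i0 < 0 || i1 > length(ch$samples))
    ip_stop(sprintf("window [%g, %g) s outside channel %s (%.1f s)",
                    start_s, end_s, ch$label, length(ch$samples) / ch$fs),
            "ip_bounds_error")
  ch$samples[(i0 + 1L):i1]
}
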