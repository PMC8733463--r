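# Minimal EDF (European Data Format) I/O.
#
# EDF stores 16-bit samples in fixed-duration data records with a per-signal
# number of samples per record, which is what lets one file carry 207 Hz EEG
# next to 10/20 Hz accelerometry. Records are 1 s long here, so recordings
# must span a whole number of seconds. Seizure labels are NOT embedded as
# EDF+ annotations; they live in a sidecar CSV (see read_annotations()).

EDF_DIG_MIN <- -32768L
EDF_DIG_MAX <- 32767L

#' Default physical ranges per channel role
#'
#' EDF quantizes each signal onto 16 bits over a fixed physical range.
#' Defaults: EEG \eqn{\pm}1000 microvolts, accelerometer \eqn{\pm}4 g.
#' @return Named list with elements `eeg` and `acc`, each `c(min, max)`.
#' @export
default_physical_range <- function() {
  list(eeg = c(-1000, 1000), acc = c(-4, 4))
}

#' Write a recording to an EDF file
#'
#' One EDF signal per channel, 1-second data records, per-signal sampling
#' rates preserved. Samples outside the configured physical range raise a
#' range error — there is no silent clipping.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @param physical_range Named list of `c(min, max)` per role, as
#'   [default_physical_range()].
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, physical_range = default_physical_range()) {
  validate_recording(rec, allow_eeg_fs = TRUE)
  ns <- length(rec$channels)
  spr <- vapply(rec$channels, function(ch) {
    if (ch$fs != round(ch$fs))
      ip_stop(sprintf("channel %s: non-integer samples per 1 s record (fs=%g)",
                      ch$label, ch$fs), "ip_format_error")
    as.integer(round(ch$fs))
  }, integer(1))
  nrec <- unique(vapply(rec$channels, function(ch) {
    n <- length(ch$samples) / ch$fs
    if (abs(n - round(n)) > 1e-9)
      ip_stop(sprintf("channel %s: duration %.4f s is not a whole number of seconds",
                      ch$label, n), "ip_format_error")
    as.integer(round(n))
  }, integer(1)))
  if (length(nrec) != 1L)
    ip_stop("all channels must span the same whole number of seconds",
            "ip_format_error")

  dig <- vector("list", ns)
  pmin <- pmax <- numeric(ns)
  for (i in seq_len(ns)) {
    ch <- rec$channels[[i]]
    pr <- physical_range[[ch$role]]
    if (is.null(pr)) ip_stop(sprintf("no physical range for role %s", ch$role),
                             "ip_config_error")
    if (any(ch$samples < pr[1]) || any(ch$samples > pr[2]))
      ip_stop(sprintf(
        "channel %s has samples outside physical range [%g, %g] %s (peak %g); not clipping",
        ch$label, pr[1], pr[2], ch$units, max(abs(ch$samples))),
        "ip_range_error")
    pmin[i] <- pr[1]; pmax[i] <- pr[2]
    dig[[i]] <- as.integer(round(
      (ch$samples - pr[1]) / (pr[2] - pr[1]) *
        (EDF_DIG_MAX - EDF_DIG_MIN) + EDF_DIG_MIN))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field(rec$person_id, 80),
    pad_field("ictalprint recording", 80),
    pad_field("01.01.00", 8),
    pad_field("00.00.00", 8),
    pad_field(256L + ns * 256L, 8),
    pad_field(sprintf("t0=%.6f", rec$start_time), 44),
    pad_field(nrec, 8),
    pad_field(1L, 8),
    pad_field(ns, 4)
  )
  fld <- function(f, w) paste0(vapply(rec$channels, function(ch)
    pad_field(f(ch), w), character(1)), collapse = "")
  sig_hdr <- paste0(
    fld(function(ch) ch$label, 16),
    fld(function(ch) "", 80),
    fld(function(ch) ch$units, 8),
    paste0(vapply(pmin, pad_field, character(1), width = 8), collapse = ""),
    paste0(vapply(pmax, pad_field, character(1), width = 8), collapse = ""),
    fld(function(ch) EDF_DIG_MIN, 8),
    fld(function(ch) EDF_DIG_MAX, 8),
    fld(function(ch) "", 80),
    paste0(vapply(spr, pad_field, character(1), width = 8), collapse = ""),
    fld(function(ch) "", 32)
  )
  writeChar(paste0(hdr, sig_hdr), con, eos = NULL, useBytes = TRUE)

  # record-major interleave: each record holds spr[i] samples of signal i
  mats <- lapply(seq_len(ns), function(i) matrix(dig[[i]], nrow = spr[i]))
  out <- as.vector(do.call(rbind, mats))
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' Expects the package's channel-naming convention (`EEG_prox`, `EEG_dist`,
#' `ACC_x`, `ACC_y`, `ACC_z`); `channel_map` maps device-specific aliases
#' onto those names. Units are parsed from the EDF physical-dimension field
#' and each signal keeps its native sampling rate.
#'
#' @param path EDF file path.
#' @param channel_map Optional named character vector `c(alias = canonical)`.
#' @param allow_eeg_fs Allow non-207 Hz EEG.
#' @return A [recording()].
#' @export
read_recording <- function(path, channel_map = NULL, allow_eeg_fs = FALSE) {
  if (!file.exists(path))
    ip_stop(sprintf("cannot read EDF file: %s", path), "ip_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) readChar(con, w, useBytes = TRUE)
  version <- trim_ws(rd(8))
  if (!identical(version, "0"))
    ip_stop(sprintf("not an EDF file (version field '%s'): %s", version, path),
            "ip_format_error")
  person_id <- trim_ws(rd(80))
  rd(80); rd(8); rd(8); rd(8)
  reserved <- trim_ws(rd(44))
  start_time <- if (grepl("^t0=", reserved))
    as.numeric(sub("^t0=", "", reserved)) else 0
  nrec <- as.integer(trim_ws(rd(8)))
  rec_dur <- as.numeric(trim_ws(rd(8)))
  ns <- as.integer(trim_ws(rd(4)))
  labels <- trim_ws(vapply(seq_len(ns), function(i) rd(16), character(1)))
  rd(80 * ns)
  units <- trim_ws(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(32 * ns)

  if (!is.null(channel_map)) {
    hit <- labels %in% names(channel_map)
    labels[hit] <- unname(channel_map[labels[hit]])
  }
  req <- required_channel_labels()
  missing <- setdiff(req, labels)
  if (length(missing))
    ip_stop(sprintf("EDF lacks required channel label(s) %s; required: %s",
                    paste(missing, collapse = ", "),
                    paste(req, collapse = ", ")), "ip_format_error")

  raw <- readBin(con, "integer", n = sum(spr) * nrec, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) != sum(spr) * nrec)
    ip_stop(sprintf("truncated EDF data section in %s", path), "ip_io_error")
  m <- matrix(raw, nrow = sum(spr), ncol = nrec)
  row_end <- cumsum(spr)
  row_start <- row_end - spr + 1L

  channels <- vector("list", 5L)
  for (k in seq_along(req)) {
    i <- match(req[k], labels)
    d <- as.vector(m[row_start[i]:row_end[i], , drop = FALSE])
    x <- (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
    channels[[k]] <- channel_signal(
      label = req[k], role = if (grepl("^EEG", req[k])) "eeg" else "acc",
      fs = spr[i] / rec_dur, samples = x, units = units[i])
  }
  recording(person_id, channels, start_time = start_time,
            allow_eeg_fs = allow_eeg_fs)
}
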