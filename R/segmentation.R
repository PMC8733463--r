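# Cohort filtering and segmentation into analysis periods.
#
# Each retained seizure contributes up to three periods:
#   ictal     [onset + 2, onset + duration - 2]   (2 s trimmed at both ends)
#   pre-ictal [onset - 60, onset - 2]             (the minute before onset,
#                                                  last 2 s trimmed)
#   baseline  [onset - 360, onset - 300]          (1 min ending 5 min before
#                                                  onset)
# Trimming avoids transition phenomena at seizure boundaries.

#' Apply the cohort inclusion rules
#'
#' Removes all FBTCS-labelled seizures first, then removes every person with
#' fewer than `min_seizures` remaining electrographic seizures. Each exclusion
#' is logged with its reason.
#'
#' @param annos A `seizure_annotations` data frame.
#' @param min_seizures Minimum electrographic seizures per person (default 10).
#' @return List with `kept` (retained annotations) and `log` (data frame of
#'   person_id, seizure_id, reason).
#' @export
filter_cohort <- function(annos, min_seizures = 10) {
  log <- data.frame(person_id = character(), seizure_id = character(),
                    reason = character(), stringsAsFactors = FALSE)
  if (!nrow(annos)) {
    ip_warn("empty annotation table: nothing to filter")
    return(list(kept = annos, log = log))
  }
  annos <- validate_annotations(annos)

  is_fbtcs <- annos$label == "FBTCS"
  if (any(is_fbtcs))
    log <- rbind(log, data.frame(person_id = annos$person_id[is_fbtcs],
                                 seizure_id = annos$seizure_id[is_fbtcs],
                                 reason = "FBTCS excluded",
                                 stringsAsFactors = FALSE))
  kept <- annos[!is_fbtcs, , drop = FALSE]

  counts <- table(kept$person_id)
  low <- names(counts)[counts < min_seizures]
  if (length(low)) {
    drop <- kept$person_id %in% low
    log <- rbind(log, data.frame(person_id = kept$person_id[drop],
                                 seizure_id = kept$seizure_id[drop],
                                 reason = "below minimum",
                                 stringsAsFactors = FALSE))
    kept <- kept[!drop, , drop = FALSE]
  }
  list(kept = kept, log = log)
}

#' Closed-form analysis-period bounds for one seizure
#'
#' Pure arithmetic, independent of any recording: ictal trimmed 2 s at each
#' end, pre-ictal `[onset - 60, onset - 2]`, baseline
#' `[onset - 360, onset - 300]`.
#'
#' @param onset_s,duration_s Seizure onset and duration in seconds.
#' @return Data frame with columns `kind`, `start_s`, `end_s` (three rows).
#' @export
period_bounds <- function(onset_s, duration_s) {
  data.frame(
    kind = c("ictal", "preictal", "baseline"),
    start_s = c(onset_s + 2, onset_s - 60, onset_s - 360),
    end_s = c(onset_s + duration_s - 2, onset_s - 2, onset_s - 300),
    stringsAsFactors = FALSE
  )
}

#' Extract trimmed analysis periods from an annotated recording
#'
#' Emits up to three periods per seizure. A seizure's ictal period is skipped
#' when, after the 2 s trims, it is shorter than `min_ictal_len`. Pre-ictal
#' and baseline windows are skipped when they would start before the
#' recording or overlap the (untrimmed) ictal interval of another seizure of
#' the same person. Skips are logged, never raised.
#'
#' @param rec A [recording()] (supplies person id and duration).
#' @param annos Retained annotations for that person.
#' @param min_ictal_len Minimum analyzable ictal length after trimming, in
#'   seconds (default 2, the shortest window the spectral estimator accepts).
#' @return Data frame (class `analysis_periods`) with columns `person_id`,
#'   `seizure_id`, `kind`, `start_s`, `end_s`, and a `skip_log` attribute.
#' @export
extract_periods <- function(rec, annos, min_ictal_len = 2) {
  annos <- validate_annotations(annos, rec_duration = recording_duration(rec))
  if (any(annos$person_id != rec$person_id))
    ip_stop("annotations refer to a different person than the recording",
            "ip_validation_error")
  annos <- annos[order(annos$onset_s), , drop = FALSE]

  out <- list()
  skips <- list()
  skip <- function(sid, kind, reason)
    data.frame(person_id = rec$person_id, seizure_id = sid, kind = kind,
               reason = reason, stringsAsFactors = FALSE)
  n <- nrow(annos)
  for (i in seq_len(n)) {
    o <- annos$onset_s[i]; d <- annos$duration_s[i]
    sid <- annos$seizure_id[i]
    pb <- period_bounds(o, d)
    others <- annos[-i, , drop = FALSE]
    overlaps_ictal <- function(s, e)
      any(s < others$onset_s + others$duration_s & e > others$onset_s)

    ictal <- pb[pb$kind == "ictal", ]
    if (ictal$end_s - ictal$start_s < min_ictal_len) {
      skips[[length(skips) + 1L]] <-
        skip(sid, "ictal", sprintf("trimmed ictal period %.1f s < minimum %g s",
                                   ictal$end_s - ictal$start_s, min_ictal_len))
    } else {
      out[[length(out) + 1L]] <- cbind(
        data.frame(person_id = rec$person_id, seizure_id = sid,
                   stringsAsFactors = FALSE), ictal)
    }
    for (kind in c("preictal", "baseline")) {
      w <- pb[pb$kind == kind, ]
      if (w$start_s < 0) {
        skips[[length(skips) + 1L]] <-
          skip(sid, kind, sprintf("window starts at %.1f s, before recording start",
                                  w$start_s))
      } else if (overlaps_ictal(w$start_s, w$end_s)) {
        skips[[length(skips) + 1L]] <-
          skip(sid, kind, "window overlaps another seizure's ictal interval")
      } else {
        out[[length(out) + 1L]] <- cbind(
          data.frame(person_id = rec$person_id, seizure_id = sid,
                     stringsAsFactors = FALSE), w)
      }
    }
  }
  periods <- if (length(out)) do.call(rbind, out) else
    data.frame(person_id = character(), seizure_id = character(),
               kind = character(), start_s = numeric(), end_s = numeric(),
               stringsAsFactors = FALSE)
  rownames(periods) <- NULL
  attr(periods, "skip_log") <- if (length(skips)) do.call(rbind, skips) else
    data.frame(person_id = character(), seizure_id = character(),
               kind = character(), reason = character(),
               stringsAsFactors = FALSE)
  class(periods) <- unique(c("analysis_periods", class(periods)))
  periods
}
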