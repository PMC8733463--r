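# Seizure annotation tables: a sidecar CSV with one row per labelled seizure.
# Labels are restricted to "electrographic" (focal seizures with an EEG
# correlate; the analysis population) and "FBTCS" (focal to bilateral
# tonic-clonic seizures, excluded by the cohort filter).

ANNOTATION_LABELS <- c("electrographic", "FBTCS")
ANNOTATION_COLS <- c("person_id", "seizure_id", "onset_s", "duration_s", "label")

#' Build a seizure annotation table
#'
#' @param person_id,seizure_id Character vectors.
#' @param onset_s Seizure onsets in seconds from recording start.
#' @param duration_s Seizure durations in seconds.
#' @param label `"electrographic"` or `"FBTCS"`.
#' @return A `data.frame` of class `seizure_annotations` with the columns
#'   above.
#' @export
seizure_annotations <- function(person_id, seizure_id, onset_s, duration_s,
                                label = "electrographic") {
  df <- data.frame(person_id = as.character(person_id),
                   seizure_id = as.character(seizure_id),
                   onset_s = as.numeric(onset_s),
                   duration_s = as.numeric(duration_s),
                   label = as.character(label),
                   stringsAsFactors = FALSE)
  validate_annotations(df)
}

#' Validate a seizure annotation table
#'
#' Enforces non-negative onsets, positive durations, the label vocabulary and
#' per-person uniqueness of seizure ids. When a recording (or its duration) is
#' supplied, seizures must also fit the recording timeline.
#'
#' @param annos Annotation `data.frame`.
#' @param rec_duration Optional recording duration in seconds.
#' @return The validated table, classed `seizure_annotations`.
#' @export
validate_annotations <- function(annos, rec_duration = NULL) {
  miss <- setdiff(ANNOTATION_COLS, names(annos))
  if (length(miss))
    ip_stop(sprintf("annotation table lacks column(s): %s",
                    paste(miss, collapse = ", ")), "ip_validation_error")
  annos$onset_s <- as.numeric(annos$onset_s)
  annos$duration_s <- as.numeric(annos$duration_s)
  bad <- setdiff(unique(annos$label), ANNOTATION_LABELS)
  if (length(bad))
    ip_stop(sprintf("unknown seizure label(s) %s; allowed: %s",
                    paste(bad, collapse = ", "),
                    paste(ANNOTATION_LABELS, collapse = ", ")),
            "ip_validation_error")
  if (any(annos$onset_s < 0))
    ip_stop("negative seizure onset", "ip_validation_error")
  if (any(annos$duration_s <= 0))
    ip_stop("non-positive seizure duration", "ip_validation_error")
  if (!is.null(rec_duration) &&
      any(annos$onset_s + annos$duration_s > rec_duration + 1e-9))
    ip_stop("seizure extends beyond recording end", "ip_validation_error")
  dup <- duplicated(annos[, c("person_id", "seizure_id")])
  if (any(dup))
    ip_stop(sprintf("duplicate seizure id(s) within person: %s",
                    paste(unique(annos$seizure_id[dup]), collapse = ", ")),
            "ip_validation_error")
  class(annos) <- unique(c("seizure_annotations", class(annos)))
  annos
}

#' Read seizure annotations from CSV
#'
#' Expects header `person_id,seizure_id,onset_s,duration_s,label`.
#' @param path CSV path.
#' @return A validated `seizure_annotations` data frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path))
    ip_stop(sprintf("cannot read annotation CSV: %s", path), "ip_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(person_id = "character",
                                       seizure_id = "character"))
  validate_annotations(df)
}

#' Write seizure annotations to CSV
#'
#' Rows are written in deterministic `(person_id, onset_s)` order so repeated
#' runs produce byte-identical files.
#' @param annos A `seizure_annotations` data frame (may be empty).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annos, path) {
  if (nrow(annos)) {
    annos <- validate_annotations(annos)
    annos <- annos[order(annos$person_id, annos$onset_s), , drop = FALSE]
  }
  utils::write.csv(annos[, ANNOTATION_COLS, drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
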