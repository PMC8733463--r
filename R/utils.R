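# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signal a classed error
#'
#' All package errors carry a subclass so callers and tests can distinguish
#' format, validation, range and configuration failures.
#' @noRd
ip_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "ictalprint_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ip_warn <- function(msg) warning(msg, call. = FALSE)

#' Derive a stage seed from a global seed
#'
#' One global seed is fanned out deterministically to per-stage / per-person
#' seeds so stages can be re-run in isolation. Kept within 32-bit range.
#' @noRd
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(offset) * 104729) %%
               2147483647)
}

# Fixed-width helpers for the EDF header (ASCII, space padded)
pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

trim_ws <- function(x) sub("\\s+$", "", sub("^\\s+", "", x))
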