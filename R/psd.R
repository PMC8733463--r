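# Welch power spectral density and band-power primitives.
#
# All band powers in the feature catalogue derive from one estimator:
# Welch's method with 2 s Hamming windows, 50 % overlap and per-window mean
# detrend. The one-sided density is normalized so that its integral over
# [0, fs/2] equals the detrended signal variance (Parseval), which makes
# band powers read directly in signal units squared.

#' Welch power spectral density
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate (samples/second).
#' @param window_s Window length in seconds (default 2).
#' @param overlap Fractional window overlap (default 0.5).
#' @return List of class `ip_psd` with `freq` (Hz), `density`
#'   (units^2 per Hz, one-sided), `fs`, `n_windows`.
#' @export
estimate_psd <- function(x, fs, window_s = 2, overlap = 0.5) {
  L <- as.integer(round(window_s * fs))
  if (length(x) < L)
    ip_stop(sprintf(
      "signal of %d samples is too short for spectral estimation; %d samples (%g s at %g Hz) required",
      length(x), L, window_s, fs), "ip_length_error")
  w <- signal::hamming(L)
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq.int(1L, length(x) - L + 1L, by = step)
  nfreq <- L %/% 2L + 1L
  acc <- numeric(nfreq)
  scale <- fs * sum(w^2)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)
    p <- (Mod(X[seq_len(nfreq)])^2) / scale
    # one-sided: double everything except DC and (L even) Nyquist
    dbl <- 2:(nfreq - if (L %% 2L == 0L) 1L else 0L)
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  structure(list(freq = (seq_len(nfreq) - 1L) * fs / L,
                 density = acc / length(starts),
                 fs = fs, n_windows = length(starts)),
            class = "ip_psd")
}

#' Absolute band power
#'
#' Trapezoidal integral of the spectral density over `[lo, hi]`, with linear
#' interpolation of the density at the band edges so that powers over a
#' partition of contiguous bands add exactly to the power of their union.
#'
#' @param psd An `ip_psd` from [estimate_psd()].
#' @param lo,hi Band edges in Hz, `0 <= lo < hi <= fs/2`.
#' @return Power in signal units squared.
#' @export
band_power <- function(psd, lo, hi) {
  if (!(lo >= 0 && lo < hi && hi <= psd$fs / 2 + 1e-9))
    ip_stop(sprintf("invalid band [%g, %g] Hz for fs = %g", lo, hi, psd$fs),
            "ip_argument_error")
  f <- psd$freq; d <- psd$density
  inner <- f > lo & f < hi
  fi <- c(lo, f[inner], hi)
  di <- c(stats::approx(f, d, xout = lo, rule = 2)$y,
          d[inner],
          stats::approx(f, d, xout = hi, rule = 2)$y)
  pracma::trapz(fi, di)
}

#' Relative band power
#'
#' `band_power(lo, hi)` divided by the power in `total_band` (default
#' 0.5--48 Hz, below mains frequency and within Nyquist at 207 Hz). Returns 0
#' when the denominator is 0.
#'
#' @inheritParams band_power
#' @param total_band Reference band `c(lo, hi)` in Hz.
#' @return Fraction in `[0, 1]`.
#' @export
relative_band_power <- function(psd, lo, hi, total_band = c(0.5, 48)) {
  if (lo < total_band[1] - 1e-9 || hi > total_band[2] + 1e-9)
    ip_stop(sprintf("band [%g, %g] lies outside the total band [%g, %g]",
                    lo, hi, total_band[1], total_band[2]), "ip_argument_error")
  tot <- band_power(psd, total_band[1], total_band[2])
  if (tot <= 0) return(0)
  band_power(psd, lo, hi) / tot
}

#' Surface-EMG power estimate from an EEG channel
#'
#' The subcutaneous electrodes span the temporalis muscle, so EEG frequency
#' content above 20 Hz is dominated by muscle activity. The EMG estimate is
#' the band power over `[20, fs/2 - guard]` Hz (default 20--100 Hz at
#' 207 Hz, with a 3 Hz anti-alias guard below Nyquist).
#'
#' @param x EEG channel samples (microvolts).
#' @param fs Sampling rate.
#' @param lo Lower band edge in Hz (default 20).
#' @param guard Anti-alias margin below Nyquist in Hz (default 3).
#' @param window_s Welch window length in seconds.
#' @return Power above 20 Hz in signal units squared.
#' @export
emg_power <- function(x, fs, lo = 20, guard = 3, window_s = 2) {
  psd <- estimate_psd(x, fs, window_s = window_s)
  band_power(psd, lo, fs / 2 - guard)
}

#' Frequency below which a fraction of band power lies
#'
#' Spectral edge frequency: the smallest frequency f such that the power in
#' `[band[1], f]` reaches `q` times the power in `band`.
#' @param psd An `ip_psd`.
#' @param q Fraction (default 0.95).
#' @param band Reference band in Hz.
#' @return Frequency in Hz.
#' @export
spectral_edge <- function(psd, q = 0.95, band = c(0.5, 48)) {
  f <- psd$freq; d <- psd$density
  keep <- f >= band[1] & f <= band[2]
  fk <- f[keep]; dk <- d[keep]
  if (length(fk) < 2L) return(band[1])
  cum <- pracma::cumtrapz(fk, dk)
  tot <- cum[length(cum)]
  if (tot <= 0) return(band[1])
  idx <- which(cum >= q * tot)[1]
  fk[idx]
}

#' Frequency of the spectral peak within a band
#' @inheritParams spectral_edge
#' @return Frequency in Hz of the maximum density in `band`.
#' @export
peak_frequency <- function(psd, band = c(0.5, 48)) {
  keep <- psd$freq >= band[1] & psd$freq <= band[2]
  psd$freq[keep][which.max(psd$density[keep])]
}
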