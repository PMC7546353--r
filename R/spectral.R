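#' Periodogram of a temporal mode with zero-padding
#'
#' Rectangular-window periodogram on a zero-padded FFT grid. 100-sample
#' modes at 1 kHz have a 10 Hz raw resolution; padding to `nfft` points
#' (default 1024) resolves dominant frequencies finer than the band edges
#' of interest. No demeaning is applied, so a constant trace is dominated
#' by the DC bin at 0 Hz.
#'
#' @param mode_trace Numeric trace (length >= 8).
#' @param sample_rate Sampling rate in Hz.
#' @param nfft FFT length after zero-padding (>= trace length).
#' @param window `"rectangular"` (default) or `"hann"` taper applied
#'   before the FFT.
#' @param mode_index Optional index stored in the result.
#' @return An object of class `mode_spectrum` with `frequencies` (Hz, up
#'   to Nyquist), `psd`, `dominant_freq` and `mode_index`.
#' @export
mode_spectrum <- function(mode_trace, sample_rate, nfft = 1024,
                          window = c("rectangular", "hann"),
                          mode_index = NA_integer_) {
  window <- match.arg(window)
  x <- as.numeric(mode_trace)
  m <- length(x)
  if (m < 8L) stop("trace too short for spectral analysis (need >= 8 samples)")
  if (max(abs(x)) == 0) stop("undefined dominant frequency: trace is identically zero")
  if (window == "hann") {
    x <- x * (0.5 - 0.5 * cos(2 * pi * seq(0, m - 1) / (m - 1)))
  }
  if (nfft < m) nfft <- m
  X <- stats::fft(c(x, rep(0, nfft - m)))
  n_keep <- floor(nfft / 2) + 1L
  psd <- abs(X[seq_len(n_keep)])^2 / (sample_rate * m)
  freqs <- (seq_len(n_keep) - 1L) * sample_rate / nfft
  structure(list(mode_index = mode_index, frequencies = freqs, psd = psd,
                 dominant_freq = freqs[which.max(psd)]),
            class = "mode_spectrum")
}

#' Dominant frequency of a temporal mode
#'
#' The grid frequency at the maximum of the zero-padded periodogram; see
#' [mode_spectrum()]. Invariant to sign flips and amplitude scaling of the
#' mode.
#'
#' @inheritParams mode_spectrum
#' @return Dominant frequency in Hz.
#' @export
#' @examples
#' dominant_frequency(sin(2 * pi * 40 * (0:99) / 1000), 1000)
dominant_frequency <- function(mode_trace, sample_rate, nfft = 1024) {
  mode_spectrum(mode_trace, sample_rate, nfft)$dominant_freq
}

#' Singular-value-weighted modal contribution of a frequency band
#'
#' Sums the singular values of all modes whose dominant frequency lies in
#' `[f_lo, f_hi)` and divides by the sum over all modes - the same
#' first-power weighting as the reduction criterion. The band is half-open
#' ("under 40 Hz" is `[0, 40)`), except that a band ending exactly at
#' Nyquist also includes Nyquist so that a disjoint partition of
#' `[0, Nyquist]` sums to 1.
#'
#' @param basis A [pca_decompose()] result carrying a sample rate.
#' @param f_lo,f_hi Band edges in Hz, `0 <= f_lo < f_hi <= Nyquist`.
#' @param nfft Periodogram padding (default 1024).
#' @return Fraction in `[0, 1]`.
#' @export
band_contribution <- function(basis, f_lo, f_hi, nfft = 1024) {
  stopifnot(inherits(basis, "pca_basis"))
  fs <- basis$sample_rate
  if (is.na(fs)) stop("basis carries no sample rate")
  nyq <- fs / 2
  if (f_lo < 0 || f_hi <= f_lo || f_hi > nyq + 1e-9) {
    stop("invalid band: need 0 <= f_lo < f_hi <= Nyquist")
  }
  doms <- vapply(seq_len(basis$r), function(i) {
    dominant_frequency(basis$U[, i], fs, nfft)
  }, numeric(1))
  in_band <- doms >= f_lo & (doms < f_hi | (abs(f_hi - nyq) < 1e-9 & doms == nyq))
  sum(basis$sigma[in_band]) / sum(basis$sigma)
}
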