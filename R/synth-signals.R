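#' Generate a 1/f aperiodic EEG background signal
#'
#' Synthesizes a zero-mean signal whose power spectral density follows a
#' power law \eqn{P(f) \propto f^{-\beta}} over the analysis range, emulating
#' the aperiodic (scale-free) background of resting EEG. Shaping is done in
#' the frequency domain: Gaussian white noise is Fourier transformed, its
#' amplitude spectrum multiplied by \eqn{f^{-\beta/2}} and transformed back.
#' Frequencies below 0.5 Hz are clamped to the 0.5 Hz gain to keep the
#' lowest bins from dominating the variance.
#'
#' @param duration_s duration in seconds (> 0).
#' @param fs sampling rate in Hz (> 0).
#' @param slope aperiodic exponent \eqn{\beta} (>= 0); the fitted log-log PSD
#'   slope over 1-40 Hz is approximately \eqn{-\beta}. `slope = 0` gives white
#'   noise.
#' @param seed optional RNG seed for reproducibility.
#'
#' @return Numeric vector of `round(duration_s * fs)` samples, zero mean,
#'   unit standard deviation.
#' @export
#' @examples
#' x <- gen_background(10, 250, slope = 1, seed = 1)
#' sd(x)
gen_background <- function(duration_s, fs, slope = 1, seed = NULL) {
  assert_scalar_pos(duration_s, "duration_s")
  assert_scalar_pos(fs, "fs")
  stopifnot(is.numeric(slope), length(slope) == 1L, slope >= 0)
  n <- round(duration_s * fs)
  local_seed(seed, {
    w <- rnorm(n)
    x <- fft(w)
    freqs <- seq(0, n - 1) * fs / n
    # fold to two-sided physical frequency
    freqs <- pmin(freqs, fs - freqs)
    gain <- pmax(freqs, 0.5)^(-slope / 2)
    gain[1] <- 0 # remove DC
    x <- Re(fft(x * gain, inverse = TRUE)) / n
    x <- x - mean(x)
    x / sd(x)
  })
}

#' Generate a narrowband oscillation
#'
#' Produces a sinusoid at `freq_hz` with a per-sample amplitude envelope, the
#' building block for band-limited EEG rhythms such as the 8-12 Hz alpha
#' oscillation.
#'
#' @param freq_hz oscillation frequency, 0 < freq_hz < fs/2.
#' @param envelope numeric vector of per-sample amplitudes; its length sets
#'   the signal length.
#' @param fs sampling rate in Hz.
#' @param phase initial phase in radians.
#'
#' @return Numeric vector `envelope * sin(2 pi f t + phase)`.
#' @export
#' @examples
#' x <- gen_oscillation(10, rep(1, 2500), fs = 250)
gen_oscillation <- function(freq_hz, envelope, fs, phase = 0) {
  assert_scalar_pos(fs, "fs")
  if (!is.numeric(freq_hz) || length(freq_hz) != 1L ||
      freq_hz <= 0 || freq_hz >= fs / 2) {
    stop("`freq_hz` must satisfy 0 < freq_hz < fs/2 (Nyquist)", call. = FALSE)
  }
  stopifnot(is.numeric(envelope), length(envelope) >= 1L)
  t <- (seq_along(envelope) - 1) / fs
  envelope * sin(2 * pi * freq_hz * t + phase)
}
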