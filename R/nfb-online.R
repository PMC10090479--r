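#' Online alpha amplitude extraction
#'
#' Emulates the real-time feedback estimator: the raw feedback-channel
#' stream is band-pass filtered with a causal IIR filter (Butterworth order
#' 4, default 8-12 Hz training band), then the RMS amplitude is computed
#' over sliding epochs of `epoch_s` seconds advancing by `epoch_s -
#' overlap_s` (defaults 0.5 s epochs, 0.1 s overlap, i.e. a 0.4 s hop). The
#' number of epochs is `floor(n_samples / hop_samples)`; the final window is
#' truncated to the available samples, so a 20-minute stream yields exactly
#' 1200 / 0.4 = 3000 feedback epochs.
#'
#' @param stream numeric vector, single-channel EEG in uV.
#' @param fs sampling rate in Hz.
#' @param band training band c(lo, hi) in Hz, inside the Nyquist range.
#' @param epoch_s epoch length in seconds.
#' @param overlap_s overlap between consecutive epochs in seconds
#'   (`overlap_s < epoch_s`).
#' @param order Butterworth order of the causal filter.
#' @return Numeric vector of per-epoch RMS amplitudes (uV).
#' @export
#' @examples
#' x <- gen_oscillation(10, rep(5, 250 * 10), 250)
#' a <- online_alpha_amplitude(x, 250)
#' mean(a[10:25]) # ~ 5 / sqrt(2)
online_alpha_amplitude <- function(stream, fs, band = c(8, 12),
                                   epoch_s = 0.5, overlap_s = 0.1,
                                   order = 4) {
  assert_scalar_pos(fs, "fs")
  stopifnot(is.numeric(stream), length(band) == 2L)
  if (band[1] <= 0 || band[2] >= fs / 2 || band[1] >= band[2]) {
    stop("training band must lie strictly inside (0, fs/2)", call. = FALSE)
  }
  stopifnot(overlap_s >= 0, overlap_s < epoch_s)
  spe <- round(epoch_s * fs)
  hop <- round((epoch_s - overlap_s) * fs)
  n <- length(stream)
  if (n < spe) stop("stream shorter than one epoch", call. = FALSE)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  filt <- as.numeric(signal::filter(bf, stream)) # causal
  n_ep <- n %/% hop
  vapply(seq_len(n_ep), function(i) {
    s <- (i - 1L) * hop + 1L
    e <- min(s + spe - 1L, n)
    rms(filt[s:e])
  }, numeric(1))
}

#' Calibrate the reward threshold from rest amplitudes
#'
#' Down-training rewards epochs whose alpha amplitude falls below the
#' threshold, so setting the threshold at the `target_reward` empirical
#' quantile of the pre-session rest amplitudes gives a stationary reward
#' rate of approximately `target_reward` (the protocol's ~65% positive /
#' ~35% negative feedback split).
#'
#' @param rest_amps per-epoch amplitudes from the three-minute rest baseline
#'   (>= 10 epochs).
#' @param target_reward target reward fraction (default 0.65).
#' @return Threshold amplitude (uV).
#' @export
calibrate_threshold <- function(rest_amps, target_reward = 0.65) {
  if (length(rest_amps) < 10L) {
    stop("need >= 10 rest epochs to calibrate", call. = FALSE)
  }
  stopifnot(target_reward > 0, target_reward <= 1)
  unname(quantile(rest_amps, target_reward, names = FALSE))
}

#' Adapt the reward threshold at a training-period boundary
#'
#' Applied only at the start of a training period, based on the preceding
#' 30 s of feedback epochs: if the reward fraction under the current
#' threshold exceeded `hi` (default 90%) or fell below `lo` (default 50%),
#' the threshold is re-calibrated to the `target` quantile of that window's
#' amplitudes; otherwise it is left unchanged.
#'
#' @param window_amps amplitudes of the trailing 30 s window (>= 1 epoch).
#' @param current_threshold threshold in force during the window.
#' @param target target reward fraction for re-calibration.
#' @param hi,lo reward-fraction bounds that trigger re-calibration.
#' @return The (possibly updated) threshold.
#' @export
adapt_threshold <- function(window_amps, current_threshold, target = 0.65,
                            hi = 0.90, lo = 0.50) {
  if (length(window_amps) < 1L) {
    stop("adaptation window is empty", call. = FALSE)
  }
  frac <- mean(window_amps < current_threshold)
  if (frac > hi || frac < lo) {
    unname(quantile(window_amps, target, names = FALSE))
  } else {
    current_threshold
  }
}
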