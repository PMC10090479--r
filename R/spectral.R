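#' EEG frequency band definition
#'
#' @param name band name.
#' @param lo_hz,hi_hz band edges in Hz, `0 < lo_hz < hi_hz`.
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(name, lo_hz, hi_hz) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(lo_hz > 0 && hi_hz > lo_hz)) {
    stop("band edges must satisfy 0 < lo_hz < hi_hz", call. = FALSE)
  }
  structure(list(name = name, lo_hz = lo_hz, hi_hz = hi_hz),
            class = "band_definition")
}

#' Canonical analysis bands
#'
#' The four offline analysis bands (delta 1-4, theta 4-8, alpha 8-13, beta
#' 14-30 Hz; note the deliberate 13-14 Hz gap between alpha and beta) plus
#' the 1-40 Hz broadband used as the denominator of relative power. The
#' online training band is narrower (8-12 Hz, see [online_alpha_amplitude()]).
#'
#' @format A named list of [band_definition()] objects.
#' @export
eeg_bands <- list(
  delta = band_definition("delta", 1, 4),
  theta = band_definition("theta", 4, 8),
  alpha = band_definition("alpha", 8, 13),
  beta = band_definition("beta", 14, 30),
  broadband = band_definition("broadband", 1, 40)
)

# periodic Hann window (matches the convention of common Welch
# implementations, e.g. scipy)
.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' Welch power spectral density estimate
#'
#' Mean modified periodogram over overlapping Hann-tapered segments with
#' per-segment mean removal; the estimator behind every band-power quantity
#' in the package. The default 2-s window at 250 Hz yields a 0.5 Hz grid.
#'
#' @param x numeric vector (single channel) or channels x samples matrix.
#' @param fs sampling rate in Hz.
#' @param win_s segment length in seconds (default 2).
#' @param overlap fractional segment overlap in \[0, 1) (default 0.5).
#' @return An object of class `psd`: list with `freqs` (one-sided Hz grid),
#'   `power` (matrix n_freqs x n_channels, uV^2/Hz) and `params`.
#' @export
#' @examples
#' x <- gen_oscillation(10, rep(1, 5000), 250)
#' p <- welch_psd(x, 250)
#' p$freqs[which.max(p$power)]
welch_psd <- function(x, fs, win_s = 2.0, overlap = 0.5) {
  assert_scalar_pos(fs, "fs")
  assert_scalar_pos(win_s, "win_s")
  stopifnot(overlap >= 0, overlap < 1)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  nper <- round(win_s * fs)
  n <- ncol(x)
  if (n < nper) stop("signal shorter than one Welch segment", call. = FALSE)
  step <- max(1L, nper - floor(nper * overlap))
  starts <- seq(1L, n - nper + 1L, by = step)
  w <- .hann(nper)
  scale <- 1 / (fs * sum(w^2))
  n_keep <- nper %/% 2 + 1L
  freqs <- (seq_len(n_keep) - 1) * fs / nper
  pow <- matrix(0, n_keep, nrow(x))
  for (s in starts) {
    seg <- x[, s:(s + nper - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    seg <- sweep(seg, 2, w, "*")
    sp <- stats::mvfft(t(seg))
    p <- (Mod(sp[seq_len(n_keep), , drop = FALSE])^2) * scale
    # one-sided: double everything except DC (and Nyquist when nper even)
    dbl <- rep(2, n_keep); dbl[1] <- 1
    if (nper %% 2 == 0) dbl[n_keep] <- 1
    pow <- pow + p * dbl
  }
  pow <- pow / length(starts)
  structure(
    list(freqs = freqs, power = pow,
         params = list(fs = fs, win_s = win_s, overlap = overlap,
                       taper = "hann", n_segments = length(starts))),
    class = "psd")
}

#' @export
print.psd <- function(x, ...) {
  cat(sprintf("<psd> %d freqs (0-%g Hz, df = %g) x %d channels, %d segments\n",
              length(x$freqs), max(x$freqs), diff(x$freqs[1:2]),
              ncol(x$power), x$params$n_segments))
  invisible(x)
}

#' Absolute band power from a PSD
#'
#' Integrates the PSD over `[lo_hz, hi_hz)` as a Riemann sum `df *
#' sum(power)` with half-open bin ownership, so that adjacent bands sharing
#' an edge (4 Hz, 8 Hz) partition the spectrum without double counting.
#'
#' @param psd a [welch_psd()] result.
#' @param band a [band_definition()].
#' @return Numeric vector of band power per channel (uV^2).
#' @export
band_power <- function(psd, band) {
  stopifnot(inherits(psd, "psd"), inherits(band, "band_definition"))
  if (band$lo_hz < min(psd$freqs) || band$hi_hz > max(psd$freqs) +
      diff(psd$freqs[1:2])) {
    stop("band lies outside the PSD frequency grid", call. = FALSE)
  }
  df <- diff(psd$freqs[1:2])
  sel <- psd$freqs >= band$lo_hz & psd$freqs < band$hi_hz
  colSums(psd$power[sel, , drop = FALSE]) * df
}

#' Relative band power
#'
#' Ratio of band power to broadband (default 1-40 Hz) power, the
#' scale-invariant spectral fraction used for all group comparisons.
#'
#' @param psd a [welch_psd()] result.
#' @param band a [band_definition()].
#' @param broadband broadband [band_definition()] covering `band`.
#' @return Numeric vector in \[0, 1\], per channel.
#' @export
relative_power <- function(psd, band, broadband = eeg_bands$broadband) {
  stopifnot(inherits(band, "band_definition"),
            inherits(broadband, "band_definition"))
  if (band$lo_hz < broadband$lo_hz || band$hi_hz > broadband$hi_hz) {
    stop("broadband must cover the requested band", call. = FALSE)
  }
  bp <- band_power(psd, band)
  bb <- band_power(psd, broadband)
  if (any(bb == 0)) stop("zero broadband power", call. = FALSE)
  bp / bb
}

#' Alpha amplitude from band power
#'
#' Offline amplitude of a band, defined as the square root of its absolute
#' band power; used for session-level summaries when the online estimator is
#' not in play.
#'
#' @inheritParams band_power
#' @return Numeric vector, uV, per channel.
#' @export
band_amplitude <- function(psd, band) sqrt(band_power(psd, band))
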