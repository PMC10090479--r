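#' Re-reference a recording to the common average
#'
#' Subtracts, at every sample, the mean across channels, so that the channel
#' mean is zero throughout. Idempotent.
#'
#' @param rec a [recording()] with at least 2 channels.
#' @return The re-referenced [recording()] with `reference =
#'   "common_average"`.
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (nrow(rec$data) < 2L) {
    stop("common average reference needs >= 2 channels", call. = FALSE)
  }
  rec$data <- sweep(rec$data, 2, colMeans(rec$data), "-")
  rec$reference <- "common_average"
  rec
}

#' Zero-phase band-pass filter a recording
#'
#' Offline filtering as used before spectral analysis: a Butterworth filter
#' (order 4) applied forward and backward (`signal::filtfilt`) for zero phase
#' distortion. `lo_hz = 0` degenerates to a low-pass filter.
#'
#' @param rec a [recording()].
#' @param lo_hz,hi_hz band edges in Hz, `0 <= lo_hz < hi_hz < fs/2`.
#' @param order Butterworth order (default 4).
#' @return The filtered [recording()].
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(2 * 2500), 2), 250)
#' filt <- bandpass(rec, 0.5, 40)
bandpass <- function(rec, lo_hz, hi_hz, order = 4) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (!is.numeric(lo_hz) || !is.numeric(hi_hz) || lo_hz < 0 ||
      lo_hz >= hi_hz || hi_hz >= fs / 2) {
    stop("band edges must satisfy 0 <= lo_hz < hi_hz < fs/2", call. = FALSE)
  }
  bf <- if (lo_hz == 0) {
    signal::butter(order, hi_hz / (fs / 2), type = "low")
  } else {
    signal::butter(order, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  }
  rec$data <- t(apply(rec$data, 1, function(ch) signal::filtfilt(bf, ch)))
  rec
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' @param rec a [recording()] at least one epoch long.
#' @param epoch_len_s epoch length in seconds (default 1 s, the segment
#'   length used by the artifact rejection step).
#' @return An [epoch_set()] with `floor(n_samples / samples_per_epoch)`
#'   epochs; any trailing remainder is dropped.
#' @export
segment_epochs <- function(rec, epoch_len_s = 1.0) {
  stopifnot(inherits(rec, "recording"))
  assert_scalar_pos(epoch_len_s, "epoch_len_s")
  spe <- round(epoch_len_s * rec$fs)
  n <- ncol(rec$data)
  if (n < spe) stop("recording is shorter than one epoch", call. = FALSE)
  n_ep <- n %/% spe
  n_ch <- nrow(rec$data)
  ep <- array(0, c(n_ep, n_ch, spe))
  for (i in seq_len(n_ep)) {
    ep[i, , ] <- rec$data[, ((i - 1) * spe + 1):(i * spe), drop = FALSE]
  }
  epoch_set(ep, epoch_len_s, rec$fs, channel_labels = rec$channel_labels)
}

#' Statistical epoch rejection on amplitude and variance deviations
#'
#' Implements the z-score based epoch rejection used in the offline chain:
#' for every epoch, the channel-averaged mean absolute amplitude and the
#' channel-averaged variance are computed, each metric is z-scored across
#' epochs, and an epoch is rejected when |z| > `z_thresh` on either metric.
#' The decision is scale-invariant: rescaling the whole dataset leaves the
#' rejection set unchanged.
#'
#' @param eps an [epoch_set()] with >= 3 epochs.
#' @param z_thresh rejection threshold in SD units (default 2).
#' @return The [epoch_set()] with its `keep_mask` updated (an epoch already
#'   masked out stays out).
#' @export
faster_reject <- function(eps, z_thresh = 2.0) {
  stopifnot(inherits(eps, "epoch_set"))
  n_ep <- dim(eps$epochs)[1]
  if (n_ep < 3L) {
    stop("z-scores across epochs are undefined for fewer than 3 epochs",
         call. = FALSE)
  }
  amp <- apply(eps$epochs, 1, function(e) mean(abs(e)))
  vr <- apply(eps$epochs, 1, function(e) mean(apply(e, 1, var)))
  zs <- function(x) {
    s <- sd(x)
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  bad <- abs(zs(amp)) > z_thresh | abs(zs(vr)) > z_thresh
  eps$keep_mask <- eps$keep_mask & !bad
  eps
}

#' Concatenate the kept epochs of an epoch set back into a recording
#'
#' @param eps an [epoch_set()].
#' @param reference reference flag carried into the output recording.
#' @return A [recording()] made of the kept epochs in order.
#' @export
kept_recording <- function(eps, reference = "common_average") {
  stopifnot(inherits(eps, "epoch_set"))
  keep <- which(eps$keep_mask)
  if (length(keep) == 0L) stop("no epochs kept", call. = FALSE)
  n_ch <- dim(eps$epochs)[2]
  dat <- do.call(cbind, lapply(keep, function(i) {
    matrix(eps$epochs[i, , ], nrow = n_ch)
  }))
  recording(dat, eps$fs,
            channel_labels = eps$channel_labels %||%
              paste0("ch", seq_len(n_ch)),
            reference = reference)
}
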