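#' Multichannel EEG recording container
#'
#' A lightweight container for a channels-by-samples EEG data matrix with its
#' sampling rate, 10-20 montage labels and reference state. All preprocessing
#' and spectral functions in the package accept and return this class.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of montage labels, one per row of
#'   `data`.
#' @param reference reference state, `"linked_ear"` or `"common_average"`.
#'
#' @return An object of class `recording`: a list with elements `data`, `fs`,
#'   `channel_labels`, `reference`.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(2 * 500), 2), fs = 250,
#'                  channel_labels = c("Fz", "Pz"))
#' rec
recording <- function(data, fs, channel_labels = NULL,
                      reference = c("linked_ear", "common_average")) {
  if (is.vector(data)) data <- matrix(data, nrow = 1L)
  stopifnot(is.matrix(data), is.numeric(data))
  assert_scalar_pos(fs, "fs")
  reference <- match.arg(reference)
  if (is.null(channel_labels)) {
    channel_labels <- paste0("ch", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("`channel_labels` must have one entry per data row", call. = FALSE)
  }
  structure(
    list(data = data, fs = fs,
         channel_labels = as.character(channel_labels),
         reference = reference),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.1f s), ref: %s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$reference))
  cat("channels:", paste(x$channel_labels, collapse = " "), "\n")
  invisible(x)
}

#' Fixed-length epoch container
#'
#' Holds non-overlapping fixed-length epochs cut from a [recording()], with a
#' per-epoch keep mask maintained by [faster_reject()].
#'
#' @param epochs numeric array, n_epochs x channels x samples_per_epoch.
#' @param epoch_len_s epoch length in seconds.
#' @param fs sampling rate in Hz.
#' @param keep_mask logical vector, one flag per epoch; defaults to all `TRUE`.
#' @param channel_labels optional channel labels.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, epoch_len_s, fs, keep_mask = NULL,
                      channel_labels = NULL) {
  stopifnot(is.array(epochs), length(dim(epochs)) == 3L)
  assert_scalar_pos(fs, "fs")
  assert_scalar_pos(epoch_len_s, "epoch_len_s")
  spe <- round(epoch_len_s * fs)
  if (dim(epochs)[3] != spe) {
    stop("third dimension of `epochs` must equal round(epoch_len_s * fs)",
         call. = FALSE)
  }
  keep_mask <- keep_mask %||% rep(TRUE, dim(epochs)[1])
  if (length(keep_mask) != dim(epochs)[1]) {
    stop("`keep_mask` must have one flag per epoch", call. = FALSE)
  }
  structure(
    list(epochs = epochs, epoch_len_s = epoch_len_s, fs = fs,
         keep_mask = as.logical(keep_mask),
         channel_labels = channel_labels),
    class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d kept) x %d channels x %g s @ %g Hz\n",
              dim(x$epochs)[1], sum(x$keep_mask), dim(x$epochs)[2],
              x$epoch_len_s, x$fs))
  invisible(x)
}
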