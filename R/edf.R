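# Minimal European Data Format (EDF) reader/writer: ASCII fixed-width
# header plus 16-bit little-endian samples. Covers continuous
# equal-rate multichannel recordings, which is all this package produces.

.edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16-bit integers over the physical range
#' (default +/- 500 uV), with one data record per second; a trailing
#' fraction of a second is dropped with a warning. Values outside the
#' physical range are clipped.
#'
#' @param rec a [recording()]; `fs` must be a whole number.
#' @param path output path ending in `.edf`.
#' @param phys_range physical range c(min, max) in uV.
#' @return `path`, invisibly.
#' @export
#' @examples
#' rec <- recording(matrix(rnorm(2 * 500), 2), 250, c("Fz", "Pz"))
#' f <- tempfile(fileext = ".edf")
#' write_edf(rec, f)
#' rec2 <- read_edf(f)
write_edf <- function(rec, path, phys_range = c(-500, 500)) {
  stopifnot(inherits(rec, "recording"))
  if (!grepl("\\.edf$", path, ignore.case = TRUE)) {
    stop("EDF output path must end in .edf", call. = FALSE)
  }
  if (abs(rec$fs - round(rec$fs)) > 1e-9) {
    stop("EDF export requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(rec$fs))
  n_ch <- nrow(rec$data)
  n <- ncol(rec$data)
  n_rec <- n %/% fs
  if (n_rec < 1L) stop("recording shorter than one EDF record", call. = FALSE)
  if (n_rec * fs < n) {
    warning(sprintf("dropping trailing %d samples (< 1 s record)",
                    n - n_rec * fs))
  }
  pmin_ <- phys_range[1]; pmax_ <- phys_range[2]
  dmin <- -32768L; dmax <- 32767L
  x <- pmin(pmax(rec$data[, seq_len(n_rec * fs), drop = FALSE], pmin_),
            pmax_)
  dig <- round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * n_ch
  put <- function(s, w) writeChar(.edf_pad(s, w), con, nchars = w,
                                  eos = NULL)
  put("0", 8); put("X X X X", 80); put("Startdate 01-JAN-2000 X X X", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(hdr_bytes, 8); put("", 44); put(n_rec, 8); put("1", 8); put(n_ch, 4)
  for (lab in rec$channel_labels) put(paste("EEG", lab), 16)
  for (i in seq_len(n_ch)) put("AgAgCl electrode", 80)
  for (i in seq_len(n_ch)) put("uV", 8)
  for (i in seq_len(n_ch)) put(pmin_, 8)
  for (i in seq_len(n_ch)) put(pmax_, 8)
  for (i in seq_len(n_ch)) put(dmin, 8)
  for (i in seq_len(n_ch)) put(dmax, 8)
  for (i in seq_len(n_ch)) put("HP:0.5Hz LP:40Hz", 80)
  for (i in seq_len(n_ch)) put(fs, 8)
  for (i in seq_len(n_ch)) put("", 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(t(dig[, idx, drop = FALSE])), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path path to a `.edf` file.
#' @param reference reference state to record on the result (EDF does not
#'   encode it).
#' @return A [recording()].
#' @export
read_edf <- function(path, reference = "linked_ear") {
  if (!grepl("\\.edf$", path, ignore.case = TRUE)) {
    stop("expected a .edf file", call. = FALSE)
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- get(8)
  if (version != "0") stop("malformed EDF header (version)", call. = FALSE)
  get(80); get(80); get(8); get(8)
  hdr_bytes <- as.integer(get(8))
  get(44)
  n_rec <- as.integer(get(8))
  rec_dur <- as.numeric(get(8))
  n_ch <- as.integer(get(4))
  if (is.na(n_ch) || n_ch < 1L || is.na(n_rec) ||
      hdr_bytes != 256L + 256L * n_ch) {
    stop("malformed EDF header", call. = FALSE)
  }
  labs <- vapply(seq_len(n_ch), function(i) get(16), "")
  for (i in seq_len(n_ch)) get(80)
  for (i in seq_len(n_ch)) get(8)
  pmin_ <- as.numeric(vapply(seq_len(n_ch), function(i) get(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(n_ch), function(i) get(8), ""))
  dmin <- as.numeric(vapply(seq_len(n_ch), function(i) get(8), ""))
  dmax <- as.numeric(vapply(seq_len(n_ch), function(i) get(8), ""))
  for (i in seq_len(n_ch)) get(80)
  spr <- as.integer(vapply(seq_len(n_ch), function(i) get(8), ""))
  for (i in seq_len(n_ch)) get(32)
  if (length(unique(spr)) != 1L) {
    stop("mixed per-channel sampling rates are not supported", call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  dat <- matrix(0, n_ch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = n_ch * spr[1], size = 2L,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = n_ch)
    dat[, ((r - 1L) * spr[1] + 1L):(r * spr[1])] <- t(block)
  }
  for (i in seq_len(n_ch)) {
    dat[i, ] <- (dat[i, ] - dmin[i]) * (pmax_[i] - pmin_[i]) /
      (dmax[i] - dmin[i]) + pmin_[i]
  }
  labs <- sub("^EEG ", "", labs)
  recording(dat, fs, channel_labels = labs, reference = reference)
}
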