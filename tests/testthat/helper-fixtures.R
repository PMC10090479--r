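# Shared fixtures. Everything is generated in code; leadfields are cached
# per size/seed because their construction is deterministic.

.lf_cache <- new.env(parent = emptyenv())

fixture_leadfield <- function(n_sources = 24, seed = 101) {
  key <- paste0("lf_", n_sources, "_", seed)
  if (is.null(.lf_cache[[key]])) {
    .lf_cache[[key]] <- make_toy_leadfield(n_sources, seed = seed)
  }
  .lf_cache[[key]]
}

# log-log PSD slope over 1-40 Hz, the oracle used for the 1/f generator
fit_psd_slope <- function(x, fs) {
  p <- welch_psd(x, fs)
  sel <- p$freqs >= 1 & p$freqs <= 40
  unname(coef(lm(log10(p$power[sel, 1]) ~ log10(p$freqs[sel])))[2])
}

# anterior-channel mean relative alpha straight from scalp data
scalp_anterior_rel_alpha <- function(rec) {
  ant <- c("Fp1", "Fp2", "F3", "Fz", "F4")
  idx <- match(ant, rec$channel_labels)
  p <- welch_psd(rec$data[idx, , drop = FALSE], rec$fs)
  mean(relative_power(p, eeg_bands$alpha))
}

# independent step-up BH implementation used as the FDR oracle
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  pass <- ps <= seq_len(m) * q / m
  k <- if (any(pass)) max(which(pass)) else 0L
  mask <- logical(m)
  if (k > 0) mask[o[seq_len(k)]] <- TRUE
  mask
}
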