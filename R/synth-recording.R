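#' Subject profile for synthetic EEG generation
#'
#' Describes the generative parameters of one simulated participant. The key
#' parameter is `alpha_deficit`, the fractional attenuation of anterior-source
#' alpha amplitude: patients show reduced relative alpha power over anterior
#' midline cortex at baseline, and `alpha_deficit > 0` reproduces that
#' contrast in the synthetic cohort.
#'
#' @param group one of `"ptsd_experimental"`, `"ptsd_sham"`,
#'   `"healthy_control"`.
#' @param alpha_deficit fraction in \[0, 1\] applied to anterior-source alpha
#'   amplitude (0 = no deficit).
#' @param aperiodic_slope 1/f exponent of the background activity.
#' @param artifact_rate expected transient artifacts per minute (>= 0).
#' @param trait_sd between-subject log-scale SD of regional alpha amplitude
#'   (default 0.25, i.e. ~25% individual variability, in line with the
#'   large inter-individual spread of resting alpha power).
#' @param seed RNG seed for this subject.
#'
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(group = c("healthy_control", "ptsd_experimental",
                                      "ptsd_sham"),
                            alpha_deficit = 0, aperiodic_slope = 1,
                            artifact_rate = 0, trait_sd = 0.25,
                            seed = NULL) {
  group <- match.arg(group)
  stopifnot(is.numeric(alpha_deficit), length(alpha_deficit) == 1L,
            alpha_deficit >= 0, alpha_deficit <= 1)
  stopifnot(is.numeric(artifact_rate), length(artifact_rate) == 1L,
            artifact_rate >= 0)
  stopifnot(is.numeric(trait_sd), length(trait_sd) == 1L, trait_sd >= 0)
  structure(
    list(group = group, alpha_deficit = alpha_deficit,
         aperiodic_slope = aperiodic_slope, artifact_rate = artifact_rate,
         trait_sd = trait_sd, seed = seed),
    class = "subject_profile")
}

# Region-specific alpha envelope amplitudes (arbitrary source units).
# Posterior alpha dominates in eyes-closed rest; anterior alpha carries the
# group deficit.
.alpha_amp_for_region <- function(region, deficit) {
  base <- switch(region,
                 anterior_medial  = 1.8,
                 anterior_lateral = 1.4,
                 posterior        = 2.4,
                 central          = 0.8,
                 0.8)
  if (startsWith(region, "anterior")) base * (1 - deficit) else base
}

#' Generate a synthetic resting-state EEG recording for one subject
#'
#' Simulates source activity on the toy source grid (1/f aperiodic background
#' plus an alpha-band oscillator per source, with anterior alpha scaled by
#' `1 - alpha_deficit`), projects it to the 19-channel scalp montage through
#' the leadfield, and adds sensor noise and (optionally) transient artifacts
#' with a step-plus-decay shape that the amplitude/variance rejection step is
#' designed to catch.
#'
#' @param profile a [subject_profile()].
#' @param leadfield a [make_toy_leadfield()] object; its channel count must
#'   match the 19-channel montage.
#' @param duration_s recording duration in seconds (default 180 s, the
#'   three-minute resting protocol).
#' @param fs sampling rate in Hz (default 250).
#'
#' @return A [recording()] with `length(leadfield$channel_labels)` channels,
#'   reference `"linked_ear"`, scaled to a realistic ~10 uV RMS.
#' @export
#' @examples
#' lf <- make_toy_leadfield(12, seed = 1)
#' rec <- gen_subject_recording(subject_profile(seed = 2), lf, duration_s = 4)
gen_subject_recording <- function(profile, leadfield, duration_s = 180,
                                  fs = 250) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(leadfield, "leadfield"))
  assert_scalar_pos(duration_s, "duration_s")
  n_ch <- dim(leadfield$gain)[3]
  if (n_ch != length(leadfield$channel_labels)) {
    stop("leadfield channel count does not match its montage labels",
         call. = FALSE)
  }
  n_src <- dim(leadfield$gain)[1]
  n <- round(duration_s * fs)

  local_seed(profile$seed, {
    # effective per-source scalp pattern for the stored dipole orientation
    geff <- vapply(seq_len(n_src), function(j) {
      drop(leadfield$orientations[j, ] %*% leadfield$gain[j, , ])
    }, numeric(n_ch)) # n_ch x n_src

    # per-subject regional alpha "trait": individuals differ substantially
    # in resting alpha amplitude; drawn before the per-source loop so that
    # changing alpha_deficit alone never alters the RNG stream
    regions <- unique(leadfield$region_labels)
    trait <- setNames(exp(rnorm(length(regions), 0, profile$trait_sd)),
                      regions)

    src <- matrix(0, n_src, n)
    for (j in seq_len(n_src)) {
      bg <- gen_background(duration_s, fs, profile$aperiodic_slope)
      a <- trait[[leadfield$region_labels[j]]] *
        .alpha_amp_for_region(leadfield$region_labels[j],
                              profile$alpha_deficit)
      f_alpha <- runif(1, 9.2, 10.8)
      # slow waxing-waning envelope, strictly positive
      env_mod <- gen_background(duration_s, fs, 2)
      env <- a * pmax(1 + 0.3 * env_mod, 0.05)
      src[j, ] <- bg + gen_oscillation(f_alpha, env, fs,
                                       phase = runif(1, 0, 2 * pi))
    }
    dat <- geff %*% src
    dat <- dat + matrix(rnorm(length(dat), sd = 0.05 * sd(dat)), nrow = n_ch)

    n_art <- rpois(1, profile$artifact_rate * duration_s / 60)
    if (n_art > 0) {
      art_len <- round(0.8 * fs)
      shape <- exp(-(seq_len(art_len) - 1) / (0.25 * fs))
      for (k in seq_len(n_art)) {
        t0 <- sample.int(max(n - art_len, 1L), 1L)
        amp <- 8 * sd(dat) * sample(c(-1, 1), 1)
        w <- runif(n_ch, 0.3, 1) # artifact topography
        idx <- t0:(t0 + art_len - 1L)
        dat[, idx] <- dat[, idx] + amp * (w %o% shape)
      }
    }
    dat <- dat * 10 / rms(dat)
    recording(dat, fs = fs, channel_labels = leadfield$channel_labels,
              reference = "linked_ear")
  })
}
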