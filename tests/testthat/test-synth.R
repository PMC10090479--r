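test_that("aperiodic background has the requested spectral slope", {
  # white-noise limit
  expect_lt(abs(fit_psd_slope(gen_background(60, 250, 0, seed = 1), 250)),
            0.1)
  # pink-noise case, Welch log-log regression oracle
  expect_lt(abs(fit_psd_slope(gen_background(60, 250, 1, seed = 2), 250) -
                  (-1)), 0.15)
  # determinism and moments
  x1 <- gen_background(5, 250, 1, seed = 9)
  x2 <- gen_background(5, 250, 1, seed = 9)
  expect_identical(x1, x2)
  expect_lt(abs(mean(x1)), 1e-12)
  expect_error(gen_background(-1, 250), "positive")
  expect_error(gen_background(10, 0), "positive")
})

test_that("narrowband oscillator peaks at its frequency and scales as power", {
  x <- gen_oscillation(10, rep(1, 5000), 250)
  p <- welch_psd(x, 250)
  expect_equal(p$freqs[which.max(p$power)], 10)
  expect_identical(gen_oscillation(10, rep(0, 100), 250), rep(0, 100))
  # doubling the envelope quadruples band power
  p2 <- welch_psd(gen_oscillation(10, rep(2, 5000), 250), 250)
  ratio <- band_power(p2, eeg_bands$alpha) / band_power(p, eeg_bands$alpha)
  expect_lt(abs(ratio - 4), 4 * 0.05)
  expect_error(gen_oscillation(130, rep(1, 100), 250), "Nyquist")
})

test_that("synthetic recordings express the anterior alpha deficit", {
  lf <- fixture_leadfield()
  rec0 <- gen_subject_recording(
    subject_profile("healthy_control", alpha_deficit = 0, seed = 31), lf,
    duration_s = 20)
  rec5 <- gen_subject_recording(
    subject_profile("ptsd_sham", alpha_deficit = 0.5, seed = 31), lf,
    duration_s = 20)
  expect_lt(scalp_anterior_rel_alpha(rec5), scalp_anterior_rel_alpha(rec0))

  # monotone in the deficit over a grid at fixed seed
  vals <- vapply(c(0, 0.3, 0.6, 0.9), function(d) {
    rec <- gen_subject_recording(
      subject_profile("ptsd_sham", alpha_deficit = d, seed = 77), lf,
      duration_s = 15)
    scalp_anterior_rel_alpha(rec)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("recording geometry, determinism and artifact-free rejection rate", {
  lf <- fixture_leadfield()
  prof <- subject_profile(seed = 5)
  rec <- gen_subject_recording(prof, lf, duration_s = 180)
  expect_equal(ncol(rec$data), 45000)
  expect_equal(nrow(rec$data), 19)
  expect_identical(rec$channel_labels, montage_1020_labels())

  rec2 <- gen_subject_recording(prof, lf, duration_s = 180)
  expect_identical(rec$data, rec2$data)

  # with no injected artifacts the 2-SD rule rejects at most chance level
  eps <- faster_reject(segment_epochs(rec, 1.0))
  expect_lte(mean(!eps$keep_mask), 0.091)
})

test_that("plant relaxes to its setpoint and is stable without homeostasis", {
  st <- plant_state(alpha_setpoint = 10, alpha_current = 16,
                    relax_rate = 6, noise_sd = 0)
  for (i in 1:2000) st <- plant_step(st, 0, 0.4)
  expect_lt(abs(st$alpha_current - 10), 1e-6)

  st <- plant_state(10, homeostatic_gain = 0, suppression_gain = 4,
                    noise_sd = 0)
  sp0 <- st$alpha_setpoint
  for (i in 1:500) st <- plant_step(st, runif(1), 0.4)
  expect_identical(st$alpha_setpoint, sp0)
  expect_error(plant_step(st, 0.5, -1), "positive")
})

test_that("sustained suppression with homeostatic gain produces alpha rebound", {
  # probe the mechanism at a clear operating point: strong drift, and the
  # post-training rest is measured after a 60-s wash-in so the suppressed
  # amplitude has relaxed back to its (raised) setpoint
  rebound_sign <- vapply(1:100, function(s) {
    set.seed(s)
    st <- plant_state(10, homeostatic_gain = 0.3, suppression_gain = 4,
                      relax_rate = 2, noise_sd = 0.6)
    pre <- numeric(450)
    for (i in seq_along(pre)) {
      st <- plant_step(st, 0, 0.4); pre[i] <- st$alpha_current
    }
    for (i in 1:3000) st <- plant_step(st, 0.65, 0.4) # 20 min training
    for (i in 1:150) st <- plant_step(st, 0, 0.4) # 60 s wash-in
    post <- numeric(450)
    for (i in seq_along(post)) {
      st <- plant_step(st, 0, 0.4); post[i] <- st$alpha_current
    }
    mean(post) > mean(pre)
  }, logical(1))
  expect_gte(mean(rebound_sign), 0.95)
})

test_that("clinical cohort reproduces requested moments and paired effect size", {
  # law-of-large-numbers check at n = 1e4: moments within 2%
  tab <- gen_clinical_cohort(10000, 2, seed = 41)
  e <- tab[tab$group == "ptsd_experimental", ]
  expect_lt(abs(mean(e$caps_pre) - 36.52) / 36.52, 0.02)
  expect_lt(abs(mean(e$caps_post) - 23.19) / 23.19, 0.02)
  expect_lt(abs(sd(e$caps_pre) - 9.71) / 9.71, 0.02)
  expect_lt(abs(sd(e$caps_post) - 15.37) / 15.37, 0.02)

  # correlation chosen so that the analytic dz equals the trial's reported
  # pre-to-post effect size of 0.77
  sd_diff <- (36.52 - 23.19) / 0.77
  rho <- (9.71^2 + 15.37^2 - sd_diff^2) / (2 * 9.71 * 15.37)
  tab <- gen_clinical_cohort(10000, 2, rho_prepost = rho, seed = 42)
  e <- tab[tab$group == "ptsd_experimental", ]
  d <- e$caps_pre - e$caps_post
  expect_lt(abs(mean(d) / sd(d) - 0.77), 0.02)

  # degenerate and deterministic behaviour
  tab0 <- gen_clinical_cohort(5, 5, sds = list(exp = c(0, 0, 0),
                                               sham = c(0, 0, 0)),
                              seed = 1)
  expect_true(all(tab0$caps_pre[tab0$group == "ptsd_experimental"] == 36.52))
  expect_identical(gen_clinical_cohort(8, 8, seed = 3),
                   gen_clinical_cohort(8, 8, seed = 3))
  expect_error(gen_clinical_cohort(5, 5, rho_prepost = 1.2), "rho")
  expect_true(all(tab$caps_post >= 0 & tab$caps_post <= caps_max["caps5"]))
})
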