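test_that("toy leadfield is deterministic with sensible geometry", {
  lf1 <- make_toy_leadfield(16, seed = 2)
  lf2 <- make_toy_leadfield(16, seed = 2)
  expect_identical(lf1$gain, lf2$gain)
  expect_true(all(is.finite(lf1$gain)))
  expect_true(all(apply(lf1$gain, 1, function(g) sum(g^2)) > 0))

  # the source closest to electrode Fz couples more strongly to Fz than O2
  lf <- fixture_leadfield(40, seed = 7)
  fz <- lf$electrode_positions["Fz", ]
  d_fz <- sqrt(colSums((t(lf$source_positions) - fz)^2))
  j <- which.min(d_fz)
  gnorm <- function(ch) sqrt(sum(lf$gain[j, , ch]^2))
  expect_gt(gnorm(which(lf$channel_labels == "Fz")),
            gnorm(which(lf$channel_labels == "O2")))

  # generic positions give full column/row rank
  K5 <- alphanfb:::.lf_matrix(make_toy_leadfield(5, seed = 3))
  expect_equal(qr(K5)$rank, 15) # min(3*5, 19)
  K10 <- alphanfb:::.lf_matrix(make_toy_leadfield(10, seed = 3))
  expect_equal(qr(K10)$rank, 19)
  expect_error(make_toy_leadfield(1), "n_sources")
})

test_that("sLORETA matches the explicit textbook operator on a tiny system", {
  lf <- make_toy_leadfield(2, seed = 5)
  set.seed(6)
  y <- matrix(rnorm(19 * 7), 19, 7)
  lambda <- 0.1
  stc <- sloreta_inverse(lf, y, lambda = lambda)

  # hand-coded oracle: T = K'(KK' + lambda*tr(KK')/n * I)^-1, standardized
  # per source by the inverse matrix square root of the resolution block
  K <- cbind(t(lf$gain[1, , ]), t(lf$gain[2, , ]))
  H <- K %*% t(K)
  H <- H + lambda * (sum(diag(H)) / 19) * diag(19)
  Tm <- t(K) %*% solve(H)
  for (j in 1:2) {
    idx <- (3 * j - 2):(3 * j)
    S <- Tm[idx, ] %*% K[, idx]
    es <- eigen((S + t(S)) / 2, symmetric = TRUE)
    Sinv2 <- es$vectors %*% diag(1 / sqrt(es$values)) %*% t(es$vectors)
    expect_equal(stc$tc[j, , ], Sinv2 %*% Tm[idx, ] %*% y,
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("sLORETA inverse is linear and vanishes on zero data", {
  lf <- fixture_leadfield()
  set.seed(11)
  X <- matrix(rnorm(19 * 40), 19)
  Y <- matrix(rnorm(19 * 40), 19)
  sx <- sloreta_inverse(lf, X)$tc
  sy <- sloreta_inverse(lf, Y)$tc
  sxy <- sloreta_inverse(lf, 2 * X - 3 * Y)$tc
  expect_equal(sxy, 2 * sx - 3 * sy, tolerance = 1e-10)
  expect_true(all(sloreta_inverse(lf, matrix(0, 19, 5))$tc == 0))
  expect_error(sloreta_inverse(lf, matrix(0, 5, 5)), "channel")
})

test_that("single noiseless sources are localized without error", {
  lf <- fixture_leadfield(30, seed = 13)
  set.seed(14)
  hits <- vapply(1:50, function(i) {
    j <- sample(30, 1)
    ori <- rnorm(3); ori <- ori / sqrt(sum(ori^2))
    s <- sin(seq(0, 30, length.out = 150))
    y <- t(lf$gain[j, , ]) %*% (ori %o% s)
    which.max(source_power(sloreta_inverse(lf, y))) == j
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("standardized power is ~1 per orientation for model white noise", {
  lf <- fixture_leadfield(12, seed = 21)
  K <- alphanfb:::.lf_matrix(lf)
  lam_eff <- 0.1 * sum(diag(K %*% t(K))) / 19
  set.seed(22)
  n_t <- 4000
  y <- K %*% matrix(rnorm(36 * n_t), 36) +
    sqrt(lam_eff) * matrix(rnorm(19 * n_t), 19)
  pw <- source_power(sloreta_inverse(lf, y, lambda = 0.1)) / 3
  expect_true(all(abs(pw - 1) < 0.15))
})

test_that("source relative power maps recover the simulated contrast", {
  lf <- fixture_leadfield()
  ant <- grepl("^anterior", lf$region_labels)
  prof <- subject_profile("ptsd_experimental", alpha_deficit = 0.6,
                          seed = 33)
  rec <- common_average_reference(
    gen_subject_recording(prof, lf, duration_s = 20))
  m <- source_relative_power(lf, rec)
  expect_lt(mean(m$values[ant]), mean(m$values[!ant]))

  # band = broadband gives a map of ones; global gain cancels
  m1 <- source_relative_power(lf, rec, eeg_bands$broadband,
                              eeg_bands$broadband)
  expect_equal(m1$values, rep(1, length(m1$values)))
  rec2 <- rec
  rec2$data <- rec2$data * 4.2
  m2 <- source_relative_power(lf, rec2)
  expect_equal(m2$values, m$values, tolerance = 1e-10)

  df <- as.data.frame(m)
  expect_equal(nrow(df), 24)
  expect_true(all(c("region", "value") %in% names(df)))
})
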