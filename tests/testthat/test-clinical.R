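# split-plot ANOVA oracle: classical sums of squares for a balanced
# two-group design, computed longhand from group/time/subject means
balanced_splitplot_oracle <- function(Y, grp) {
  k <- ncol(Y); N <- nrow(Y)
  grand <- mean(Y)
  m_subj <- rowMeans(Y)
  m_time <- colMeans(Y)
  groups <- unique(grp)
  m_grp <- vapply(groups, function(g) mean(Y[grp == g, ]), numeric(1))
  n_g <- vapply(groups, function(g) sum(grp == g), numeric(1))
  m_gt <- t(vapply(groups, function(g) colMeans(Y[grp == g, , drop = FALSE]),
                   numeric(k)))
  ss_time <- N * sum((m_time - grand)^2)
  ss_gxt <- sum(n_g * (m_gt - outer(m_grp, m_time, "+") + grand)^2)
  fit <- m_gt[match(grp, groups), ] + (m_subj - m_grp[match(grp, groups)])
  ss_err_w <- sum((Y - fit)^2)
  S <- matrix(0, k, k)
  for (g in groups) {
    Yg <- Y[grp == g, , drop = FALSE]
    S <- S + crossprod(sweep(Yg, 2, colMeans(Yg), "-"))
  }
  S <- S / (N - length(groups))
  Sc <- sweep(sweep(S, 1, rowMeans(S), "-"), 2, colMeans(S), "-") + mean(S)
  list(F_time = (ss_time / (k - 1)) /
         (ss_err_w / ((N - length(groups)) * (k - 1))),
       F_gxt = (ss_gxt / ((length(groups) - 1) * (k - 1))) /
         (ss_err_w / ((N - length(groups)) * (k - 1))),
       eps = sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2)))
}

test_that("split-plot ANOVA matches the hand-computed balanced oracle", {
  tab <- gen_clinical_cohort(14, 14, seed = 31)
  fit <- split_plot_rm_anova(clinical_long(tab))
  Y <- cbind(tab$caps_pre, tab$caps_post, tab$caps_fu)
  orc <- balanced_splitplot_oracle(Y, tab$group)
  expect_equal(fit$time$F, orc$F_time, tolerance = 1e-6)
  expect_equal(fit$group_time$F, orc$F_gxt, tolerance = 1e-6)
  expect_equal(fit$epsilon, orc$eps, tolerance = 1e-6)

  # degenerate all-equal data: F = 0 by convention
  flat <- data.frame(subject = rep(sprintf("s%d", 1:6), 3),
                     group = rep(rep(c("a", "b"), each = 3), 3),
                     time = rep(c("pre", "post", "fu"), each = 6),
                     score = 7)
  f0 <- split_plot_rm_anova(flat)
  expect_equal(f0$time$F, 0)
  expect_equal(f0$group_time$F, 0)
  expect_error(split_plot_rm_anova(flat[-1, ]), "missing cells")
})

test_that("split-plot ANOVA reproduces the Type III reference (car) for
           unbalanced groups", {
  tab <- gen_clinical_cohort(20, 18, seed = 32)
  fit <- split_plot_rm_anova(clinical_long(tab))
  wide <- cbind(tab$caps_pre, tab$caps_post, tab$caps_fu)
  g <- factor(tab$group)
  mod <- lm(wide ~ g, contrasts = list(g = "contr.sum"))
  av <- car::Anova(mod, idata = data.frame(time = factor(1:3)),
                   idesign = ~time, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))
  ut <- s$univariate.tests
  expect_equal(fit$time$F, unname(ut["time", "F value"]),
               tolerance = 1e-10)
  expect_equal(fit$group_time$F, unname(ut["g:time", "F value"]),
               tolerance = 1e-10)
  expect_equal(fit$group$F, unname(ut["g", "F value"]), tolerance = 1e-10)
  expect_equal(fit$epsilon,
               unname(s$pval.adjustments["time", "GG eps"]),
               tolerance = 1e-10)
  expect_equal(fit$time$p_gg,
               unname(s$pval.adjustments["time", "Pr(>F[GG])"]),
               tolerance = 1e-10)
})

test_that("simulated trial-scale cohort shows a time effect with sane epsilon", {
  tab <- gen_clinical_cohort(2000, 2000, seed = 33)
  fit <- split_plot_rm_anova(clinical_long(tab))
  expect_lt(fit$time$p_gg, 1e-6)
  expect_gt(fit$epsilon, 0.5)
  expect_lte(fit$epsilon, 1)
})

test_that("paired effect size obeys dz = t / sqrt(n)", {
  set.seed(34)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    pre <- rnorm(n, 30, 8)
    post <- pre - rnorm(n, 2, 4)
    r <- paired_t_and_dz(pre, post)
    expect_equal(r$dz, r$t / sqrt(r$n), tolerance = 1e-12)
    expect_equal(r$df, n - 1)
  }
  # no true change: dz shrinks to zero at large n
  pre <- rnorm(10000)
  r0 <- paired_t_and_dz(pre, pre + rnorm(10000, 0, 1))
  expect_lt(abs(r0$dz), 0.03)
  expect_error(paired_t_and_dz(1:5, 1:5 - 2), "zero-variance")
})

test_that("CAPS normalization maps instrument ranges onto each other", {
  expect_equal(caps_normalize(57, "caps5"), 57)
  expect_equal(caps_normalize(0, "caps4"), 0)
  expect_equal(caps_normalize(caps_max[["caps4"]], "caps4"),
               caps_max[["caps5"]])
  expect_equal(caps_normalize(68, "caps4"), 40)
  expect_error(caps_normalize(90, "caps5"), "range")
})

test_that("percent reduction and remission arithmetic", {
  expect_equal(percent_reduction(36.52, 23.19), 36.5)
  expect_equal(percent_reduction(50, 50), 0)
  expect_error(percent_reduction(0, 10), "positive")

  expect_true(remission_classify(100, 69))
  expect_false(remission_classify(100, 70)) # exactly 30% is not remission
  expect_false(remission_classify(100, 100))
  expect_error(remission_classify(0, 0), "positive")
})

test_that("per-source clinical regression recovers a planted slope and stays
           specific under the null", {
  set.seed(35)
  n <- 50; m <- 30
  caps <- rnorm(n, 0, 10)
  maps <- matrix(rnorm(n * m, sd = 0.05), n)
  beta <- 0.004
  maps[, 1] <- maps[, 1] + beta * caps
  sm <- regress_caps_on_alpha_change(caps, maps)
  se1 <- abs(sm$slopes[1] / sm$t_values[1])
  expect_lt(abs(sm$slopes[1] - beta), 2 * se1)
  expect_true(sm$sig_mask[1])

  # constant clinical change is flagged, not fitted
  expect_warning(sm0 <- regress_caps_on_alpha_change(rep(2, n), maps),
                 "constant")
  expect_true(all(sm0$p_values == 1))

  # null specificity at the trial's sample size
  empty <- vapply(1:20, function(s) {
    set.seed(600 + s)
    sum(regress_caps_on_alpha_change(rnorm(38),
                                     matrix(rnorm(38 * 50), 38))$sig_mask)
  }, numeric(1))
  expect_gte(mean(empty == 0), 0.95)
})
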