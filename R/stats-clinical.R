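#' Split-plot repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Mixed ANOVA for the trial's primary clinical analysis: between-subjects
#' factor group (2 levels) and within-subjects factor time (k assessments).
#' Returns the within-subject F tests (main effect of time and the Group x
#' Time interaction) with partial eta squared and Greenhouse-Geisser
#' epsilon-adjusted degrees of freedom and p-values. Epsilon follows Box's
#' definition, computed from the pooled within-group covariance of the
#' repeated measures.
#'
#' @param table_long data frame with columns `subject`, `group`, `time`,
#'   `score`; complete cases (every subject observed at every time).
#' @return List of class `clinical_anova`: per effect (`time`,
#'   `group_time`), `F`, `df` (unadjusted), `df_adjusted`
#'   (Greenhouse-Geisser), `p_gg`, `eta_p_sq`; plus `epsilon` and the sums
#'   of squares table.
#' @export
#' @examples
#' tab <- gen_clinical_cohort(10, 10, seed = 1)
#' long <- clinical_long(tab)
#' fit <- split_plot_rm_anova(long)
#' fit$time$F
split_plot_rm_anova <- function(table_long) {
  need <- c("subject", "group", "time", "score")
  if (!all(need %in% names(table_long))) {
    stop("`table_long` needs columns subject, group, time, score",
         call. = FALSE)
  }
  table_long$subject <- as.character(table_long$subject)
  table_long$group <- as.character(table_long$group)
  times <- unique(table_long$time)
  k <- length(times)
  wide <- tapply(table_long$score,
                 list(table_long$subject, factor(table_long$time,
                                                 levels = times)),
                 identity)
  if (anyNA(wide)) {
    stop("missing cells: every subject must be observed at every time",
         call. = FALSE)
  }
  Y <- matrix(as.numeric(wide), nrow(wide), k,
              dimnames = dimnames(wide))
  grp <- table_long$group[match(rownames(Y), table_long$subject)]
  groups <- unique(grp)
  G <- length(groups)
  N <- nrow(Y)

  # Type III (sum-to-zero) tests via orthonormal within-subject contrasts,
  # the convention of standard statistical GUIs for split-plot designs.
  gf <- factor(grp)
  Xb <- cbind(1, stats::contr.sum(G)[as.integer(gf), , drop = FALSE])
  C <- stats::contr.poly(k) # orthonormal columns
  M <- Y %*% C # N x (k-1) contrast scores
  XtXi <- solve(crossprod(Xb))
  B <- XtXi %*% crossprod(Xb, M)
  SSP_err <- crossprod(M) - t(B) %*% crossprod(Xb) %*% B

  hyp_ssp <- function(rows) {
    L <- diag(ncol(Xb))[rows, , drop = FALSE]
    LB <- L %*% B
    t(LB) %*% solve(L %*% XtXi %*% t(L)) %*% LB
  }
  SSP_time <- hyp_ssp(1L)
  SSP_gxt <- hyp_ssp(1L + seq_len(G - 1))

  ss_time <- sum(diag(SSP_time))
  ss_gxt <- sum(diag(SSP_gxt))
  ss_err_within <- sum(diag(SSP_err))

  df_time <- k - 1
  df_gxt <- (G - 1) * (k - 1)
  df_err_w <- (N - G) * (k - 1)
  df_err_b <- N - G

  # Box / Greenhouse-Geisser epsilon from the pooled within-group
  # covariance of the contrast scores; degenerate (zero-variance) data get
  # epsilon 1 by convention
  Sc <- SSP_err / (N - G)
  eps <- if (sum(Sc^2) == 0) 1 else {
    (sum(diag(Sc)))^2 / ((k - 1) * sum(Sc^2))
  }

  # between-subjects (group) test on the subject means
  ym <- rowMeans(Y)
  bm <- XtXi %*% crossprod(Xb, ym)
  ss_err_b <- sum((ym - Xb %*% bm)^2) * k
  Lg <- diag(ncol(Xb))[1L + seq_len(G - 1), , drop = FALSE]
  Lb <- Lg %*% bm
  ss_group <- drop(t(Lb) %*% solve(Lg %*% XtXi %*% t(Lg)) %*% Lb) * k

  fratio <- function(ss_eff, df_eff, ss_err, df_err) {
    if (ss_err == 0) return(if (ss_eff <= 1e-12) 0 else Inf)
    (ss_eff / df_eff) / (ss_err / df_err)
  }
  F_time <- fratio(ss_time, df_time, ss_err_within, df_err_w)
  F_gxt <- fratio(ss_gxt, df_gxt, ss_err_within, df_err_w)
  F_group <- fratio(ss_group, G - 1, ss_err_b, df_err_b)
  ss_err_between <- ss_err_b

  eta <- function(ss_eff, ss_err) {
    if (ss_eff + ss_err == 0) 0 else ss_eff / (ss_eff + ss_err)
  }
  res <- list(
    time = list(
      F = F_time, df = c(df_time, df_err_w),
      df_adjusted = eps * c(df_time, df_err_w),
      p_gg = stats::pf(F_time, eps * df_time, eps * df_err_w,
                       lower.tail = FALSE),
      eta_p_sq = eta(ss_time, ss_err_within)),
    group_time = list(
      F = F_gxt, df = c(df_gxt, df_err_w),
      df_adjusted = eps * c(df_gxt, df_err_w),
      p_gg = stats::pf(F_gxt, eps * df_gxt, eps * df_err_w,
                       lower.tail = FALSE),
      eta_p_sq = eta(ss_gxt, ss_err_within)),
    group = list(
      F = F_group, df = c(G - 1, df_err_b),
      p = stats::pf(F_group, G - 1, df_err_b, lower.tail = FALSE),
      eta_p_sq = eta(ss_group, ss_err_between)),
    epsilon = eps,
    ss = c(time = ss_time, group_time = ss_gxt,
           error_within = ss_err_within, group = ss_group,
           error_between = ss_err_between))
  class(res) <- "clinical_anova"
  res
}

#' @export
print.clinical_anova <- function(x, ...) {
  cat(sprintf(
    "time:        F(%.2f, %.2f) = %.3f, p = %.4g, eta_p^2 = %.3f\n",
    x$time$df_adjusted[1], x$time$df_adjusted[2], x$time$F, x$time$p_gg,
    x$time$eta_p_sq))
  cat(sprintf(
    "group x time: F(%.2f, %.2f) = %.3f, p = %.4g, eta_p^2 = %.3f\n",
    x$group_time$df_adjusted[1], x$group_time$df_adjusted[2],
    x$group_time$F, x$group_time$p_gg, x$group_time$eta_p_sq))
  cat(sprintf("Greenhouse-Geisser epsilon = %.3f\n", x$epsilon))
  invisible(x)
}

#' Reshape a clinical table to long format
#'
#' @param tab a [gen_clinical_cohort()] table (or any data frame with
#'   `subject_id`, `group` and `caps_pre`/`caps_post`/`caps_fu` columns).
#' @return Long data frame with columns `subject`, `group`, `time`
#'   (`pre`/`post`/`fu`), `score`.
#' @export
clinical_long <- function(tab) {
  data.frame(
    subject = rep(tab$subject_id, 3),
    group = rep(tab$group, 3),
    time = rep(c("pre", "post", "fu"), each = nrow(tab)),
    score = c(tab$caps_pre, tab$caps_post, tab$caps_fu),
    stringsAsFactors = FALSE)
}

#' Paired t-test with the paired effect size dz
#'
#' Within-group change test used for the pre/post and pre/follow-up CAPS
#' comparisons, with Cohen's \eqn{d_z = \bar d / s_d = t / \sqrt{n}}.
#'
#' @param pre,post matched score vectors (n >= 2); the test is on `pre -
#'   post`, so a positive `t` means a reduction.
#' @return List with `t`, `df`, `p` (two-sided), `dz`, `n`.
#' @export
#' @examples
#' r <- paired_t_and_dz(c(30, 40, 35, 42), c(22, 31, 30, 33))
#' r$dz - r$t / sqrt(r$n) # 0
paired_t_and_dz <- function(pre, post) {
  stopifnot(length(pre) == length(post), length(pre) >= 2L)
  d <- pre - post
  if (sd(d) == 0) {
    stop("zero-variance differences: dz undefined", call. = FALSE)
  }
  n <- length(d)
  tt <- t.test(pre, post, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, dz = mean(d) / sd(d), n = n)
}

#' Normalize a CAPS score to the CAPS-5 scale
#'
#' CAPS-IV totals are mapped onto the CAPS-5 range by dividing by the
#' CAPS-IV maximum and multiplying by the CAPS-5 maximum; CAPS-5 scores are
#' returned unchanged. Instrument maxima are the [caps_max] configuration
#' constants.
#'
#' @param score numeric score(s) within the instrument range.
#' @param instrument `"caps4"` or `"caps5"`.
#' @return Score(s) on the CAPS-5 scale.
#' @export
#' @examples
#' caps_normalize(136, "caps4") # 80
caps_normalize <- function(score, instrument = c("caps5", "caps4")) {
  instrument <- match.arg(instrument)
  if (any(score < 0 | score > caps_max[[instrument]])) {
    stop(sprintf("score outside the %s range [0, %d]", instrument,
                 caps_max[[instrument]]), call. = FALSE)
  }
  if (instrument == "caps4") {
    score / caps_max[["caps4"]] * caps_max[["caps5"]]
  } else {
    score
  }
}

#' Percent reduction of a group mean score
#'
#' @param pre_mean baseline mean (> 0).
#' @param later_mean mean at the later assessment.
#' @param digits decimal places to report (default 1, as in the trial's
#'   outcome table).
#' @return `100 * (pre_mean - later_mean) / pre_mean`, rounded.
#' @export
#' @examples
#' percent_reduction(36.52, 23.19) # 36.5
percent_reduction <- function(pre_mean, later_mean, digits = 1) {
  if (!is.numeric(pre_mean) || any(pre_mean <= 0)) {
    stop("`pre_mean` must be positive", call. = FALSE)
  }
  round(100 * (pre_mean - later_mean) / pre_mean, digits)
}

#' Clinically significant change classification
#'
#' A participant is classified as showing clinically significant improvement
#' (used for remission counting) when their severity reduction strictly
#' exceeds `threshold_pct` percent of the baseline score.
#'
#' @param pre,later individual scores, `pre > 0`.
#' @param threshold_pct reduction threshold in percent (default 30).
#' @return Logical vector.
#' @export
#' @examples
#' remission_classify(100, 69) # TRUE (31% > 30%)
#' remission_classify(100, 70) # FALSE (exactly 30%)
remission_classify <- function(pre, later, threshold_pct = 30) {
  if (any(pre <= 0)) stop("`pre` must be positive", call. = FALSE)
  100 * (pre - later) / pre > threshold_pct
}
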