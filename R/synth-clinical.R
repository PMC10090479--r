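#' CAPS instrument score ranges
#'
#' Maximum total severity scores used for instrument normalization and for
#' bounding simulated scores. These are configuration constants of the
#' package, taken from the instrument manuals (CAPS-IV total 0-136, CAPS-5
#' total 0-80), not estimated quantities.
#'
#' @format Named numeric vector with entries `caps4` and `caps5`.
#' @export
caps_max <- c(caps4 = 136, caps5 = 80)

# Mean and sd of a normal(mu, sigma) truncated to [a, b].
.truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  Z <- pnorm(be) - pnorm(al)
  d <- (dnorm(al) - dnorm(be)) / Z
  m <- mu + sigma * d
  v <- sigma^2 * (1 + (al * dnorm(al) - be * dnorm(be)) / Z - d^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# probabilists' Gauss-Hermite rule (Golub-Welsch), weights summing to 1
.gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  es <- eigen(J, symmetric = TRUE)
  list(x = sqrt(2) * es$values, w = es$vectors[1, ]^2)
}

# Latent Gaussian-copula correlation delivering a requested linear
# correlation between two (monotone-transformed) margins g1, g2 with known
# target moments. Solved by quadrature + root finding; the transform
# attenuates correlation, so the latent value is slightly larger in
# magnitude.
.copula_rho_solve <- function(target_rho, g1, g2, m1, s1, m2, s2,
                              n_nodes = 40) {
  if (target_rho == 0) return(0)
  gh <- .gauss_hermite(n_nodes)
  gv1 <- g1(gh$x)
  lin_corr <- function(r) {
    e12 <- sum(vapply(seq_along(gh$x), function(i) {
      z2 <- r * gh$x[i] + sqrt(1 - r^2) * gh$x
      gh$w[i] * sum(gh$w * g2(z2))
    }, numeric(1)) * gv1)
    (e12 - m1 * m2) / (s1 * s2)
  }
  f <- function(r) lin_corr(r) - target_rho
  loh <- sort(c(target_rho, sign(target_rho) * 0.999))
  if (f(loh[1]) * f(loh[2]) > 0) return(target_rho) # already attainable
  stats::uniroot(f, loh, tol = 1e-6)$root
}

# Latent (mu, sigma) such that the [a,b]-truncated normal has the requested
# mean and sd. Identity when truncation is negligible.
.truncnorm_match <- function(target_mean, target_sd, a, b) {
  mom <- .truncnorm_moments(target_mean, target_sd, a, b)
  if (abs(mom["mean"] - target_mean) < 1e-9 * max(1, target_sd) &&
      abs(mom["sd"] - target_sd) < 1e-9 * max(1, target_sd)) {
    return(c(mu = target_mean, sigma = target_sd))
  }
  obj <- function(par) {
    m <- .truncnorm_moments(par[1], exp(par[2]), a, b)
    (m["mean"] - target_mean)^2 + (m["sd"] - target_sd)^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Generate a synthetic clinical cohort of CAPS severity scores
#'
#' Draws per-subject CAPS total severity at three assessments (pre-treatment,
#' post-treatment, three-month follow-up) for the experimental and
#' sham-control arms with the requested group means, SDs and a common
#' pre/post/follow-up correlation, bounded to the instrument range
#' \[0, max\]. Scores are built from a Gaussian copula with truncated-normal
#' margins whose latent parameters are moment-matched, so the bounded scores
#' carry the requested means and SDs exactly in population; the paired
#' effect size between two time points is then approximately the analytic
#' \eqn{d_z = (\mu_1 - \mu_2) / \sqrt{\sigma_1^2 + \sigma_2^2 -
#' 2\rho\sigma_1\sigma_2}}.
#'
#' @param n_exp,n_sham subjects per arm (>= 2).
#' @param means,sds lists with numeric length-3 elements `exp` and `sham`
#'   giving (pre, post, follow-up) moments; defaults are the trial's reported
#'   group values.
#' @param rho_prepost common correlation between assessments, |rho| < 1 (and
#'   > -0.5 for a valid exchangeable structure).
#' @param instrument `"caps5"` (default) or `"caps4"`; sets the truncation
#'   bound.
#' @param seed RNG seed.
#'
#' @return A `data.frame` (class `clinical_table`) with columns `subject_id`,
#'   `group`, `instrument`, `caps_pre`, `caps_post`, `caps_fu`.
#' @export
#' @examples
#' tab <- gen_clinical_cohort(20, 18, seed = 1)
#' aggregate(caps_pre ~ group, tab, mean)
gen_clinical_cohort <- function(n_exp = 20, n_sham = 18,
                                means = list(exp = c(36.52, 23.19, 23.65),
                                             sham = c(39.94, 32.78, 31.78)),
                                sds = list(exp = c(9.71, 15.37, 13.71),
                                           sham = c(7.83, 12.27, 12.89)),
                                rho_prepost = 0.2,
                                instrument = c("caps5", "caps4"),
                                seed = NULL) {
  instrument <- match.arg(instrument)
  stopifnot(n_exp >= 2, n_sham >= 2)
  if (!is.numeric(rho_prepost) || abs(rho_prepost) >= 1 ||
      rho_prepost <= -0.5) {
    stop("`rho_prepost` must lie in (-0.5, 1) for a valid correlation matrix",
         call. = FALSE)
  }
  for (g in c("exp", "sham")) {
    if (length(means[[g]]) != 3L || length(sds[[g]]) != 3L ||
        any(sds[[g]] < 0)) {
      stop("`means` and `sds` need length-3 non-negative entries per group",
           call. = FALSE)
    }
  }
  bound <- caps_max[[instrument]]

  draw_group <- function(n, m, s) {
    if (all(s == 0)) {
      return(matrix(rep(m, each = n), nrow = n))
    }
    # margin transforms: standard normal -> moment-matched truncated normal
    gs <- lapply(1:3, function(j) {
      if (s[j] == 0) return(function(z) rep(m[j], length(z)))
      lat <- .truncnorm_match(m[j], s[j], 0, bound)
      al <- pnorm((0 - lat[["mu"]]) / lat[["sigma"]])
      be <- pnorm((bound - lat[["mu"]]) / lat[["sigma"]])
      function(z) lat[["mu"]] +
        lat[["sigma"]] * qnorm(al + pnorm(z) * (be - al))
    })
    R <- diag(3)
    for (j in 1:2) for (l in (j + 1):3) {
      R[j, l] <- R[l, j] <- if (s[j] == 0 || s[l] == 0) 0 else {
        .copula_rho_solve(rho_prepost, gs[[j]], gs[[l]],
                          m[j], s[j], m[l], s[l])
      }
    }
    ev <- eigen(R, symmetric = TRUE)
    if (min(ev$values) < 1e-8) { # guard: clip to nearest valid correlation
      V <- ev$vectors %*% diag(pmax(ev$values, 1e-8)) %*% t(ev$vectors)
      R <- stats::cov2cor(V)
    }
    z <- matrix(MASS::mvrnorm(n, mu = rep(0, 3), Sigma = R), ncol = 3)
    out <- matrix(0, n, 3)
    for (j in 1:3) out[, j] <- gs[[j]](z[, j])
    out
  }

  local_seed(seed, {
    xe <- draw_group(n_exp, means$exp, sds$exp)
    xs <- draw_group(n_sham, means$sham, sds$sham)
    tab <- data.frame(
      subject_id = sprintf("S%03d", seq_len(n_exp + n_sham)),
      group = rep(c("ptsd_experimental", "ptsd_sham"), c(n_exp, n_sham)),
      instrument = instrument,
      caps_pre = c(xe[, 1], xs[, 1]),
      caps_post = c(xe[, 2], xs[, 2]),
      caps_fu = c(xe[, 3], xs[, 3]),
      stringsAsFactors = FALSE)
    class(tab) <- c("clinical_table", "data.frame")
    tab
  })
}
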