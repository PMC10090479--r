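#' EM imputation of missing sessions
#'
#' Replaces missing cells of a subjects x sessions matrix (e.g. session-mean
#' alpha % change) under a multivariate-normal model across sessions with
#' subjects as i.i.d. rows, using the expectation-maximization algorithm.
#' Missing entries are set to their conditional means given the observed
#' sessions at the converged (mu, Sigma); the E-step adds the conditional
#' covariance to the scatter so that Sigma is the proper EM estimate, and
#' convergence is declared when the observed-data log-likelihood changes by
#' less than `tol`.
#'
#' @param x numeric matrix, subjects x sessions, `NA` for missing; at most
#'   50% missing per subject.
#' @param max_iter maximum EM iterations.
#' @param tol log-likelihood convergence tolerance (default 1e-6).
#' @return List with `matrix` (imputed), `mu`, `sigma`, `iterations`,
#'   `loglik`. Stops with an error if EM fails to converge.
#' @export
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' x[1, 2] <- NA
#' out <- impute_missing_sessions(x)
impute_missing_sessions <- function(x, max_iter = 500, tol = 1e-6) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (!anyNA(x)) {
    return(list(matrix = x, mu = colMeans(x), sigma = stats::cov(x),
                iterations = 0L, loglik = NA_real_))
  }
  miss_frac <- rowMeans(is.na(x))
  if (any(miss_frac > 0.5)) {
    stop("subjects with more than 50% missing sessions are not imputable",
         call. = FALSE)
  }
  n <- nrow(x); k <- ncol(x)
  mu <- colMeans(x, na.rm = TRUE)
  v <- apply(x, 2, var, na.rm = TRUE)
  v[!is.finite(v) | v == 0] <- 1
  sigma <- diag(v, k)
  obs <- !is.na(x)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    sum_x <- matrix(0, n, k)
    scatter_fix <- matrix(0, k, k)
    ll <- 0
    for (i in seq_len(n)) {
      o <- obs[i, ]
      xi <- x[i, ]
      if (all(o)) {
        sum_x[i, ] <- xi
      } else {
        m <- !o
        Soo <- sigma[o, o, drop = FALSE]
        Smo <- sigma[m, o, drop = FALSE]
        B <- Smo %*% solve(Soo)
        xi[m] <- mu[m] + drop(B %*% (xi[o] - mu[o]))
        sum_x[i, ] <- xi
        Cm <- sigma[m, m, drop = FALSE] - B %*% t(Smo)
        scatter_fix[m, m] <- scatter_fix[m, m] + Cm
      }
      # observed-data log-likelihood contribution
      Soo <- sigma[o, o, drop = FALSE]
      d <- x[i, o] - mu[o]
      ll <- ll - 0.5 * (sum(o) * log(2 * pi) +
                          determinant(Soo)$modulus +
                          drop(t(d) %*% solve(Soo, d)))
    }
    mu_new <- colMeans(sum_x)
    ctr <- sweep(sum_x, 2, mu_new, "-")
    sigma_new <- (crossprod(ctr) + scatter_fix) / n
    mu <- mu_new
    sigma <- (sigma_new + t(sigma_new)) / 2
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      imputed <- x
      imputed[!obs] <- sum_x[!obs]
      return(list(matrix = imputed, mu = mu, sigma = sigma,
                  iterations = it, loglik = as.numeric(ll)))
    }
    ll_old <- ll
  }
  stop("EM imputation did not converge within `max_iter` iterations",
       call. = FALSE)
}

#' Within-subject imputation of missing training periods
#'
#' For within-session (period-wise) statistics, a missing (subject, session,
#' period) cell is replaced by that subject's mean over the sessions where
#' the same period was observed.
#'
#' @param x numeric array, subjects x sessions x periods, `NA` for missing.
#' @return The array with missing cells imputed. Errors if a subject has a
#'   period that was never observed in any session.
#' @export
impute_missing_periods <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  for (i in seq_len(dim(x)[1])) {
    for (p in seq_len(dim(x)[3])) {
      v <- x[i, , p]
      if (all(is.na(v))) {
        stop(sprintf(
          "subject %d has no observed session for period %d", i, p),
          call. = FALSE)
      }
      v[is.na(v)] <- mean(v, na.rm = TRUE)
      x[i, , p] <- v
    }
  }
  x
}
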