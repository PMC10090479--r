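#' Statistical map container
#'
#' @param t_values per-source test statistics.
#' @param p_values per-source p-values in \[0, 1\].
#' @param sig_mask logical significance mask (after any correction).
#' @param contrast_id label of the contrast.
#' @param band optional [band_definition()].
#' @param n_perm number of permutations (0 for parametric tests).
#' @param alpha_level significance / FDR level used for the mask.
#' @return An object of class `stat_map`.
#' @export
stat_map <- function(t_values, p_values, sig_mask = NULL,
                     contrast_id = "", band = NULL, n_perm = 0L,
                     alpha_level = 0.05) {
  stopifnot(length(t_values) == length(p_values),
            all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  sig_mask <- sig_mask %||% rep(FALSE, length(p_values))
  structure(
    list(t_values = as.numeric(t_values), p_values = as.numeric(p_values),
         sig_mask = as.logical(sig_mask), contrast_id = contrast_id,
         band = band, n_perm = as.integer(n_perm),
         alpha_level = alpha_level),
    class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf(
    "<stat_map> %s: %d sources, %d significant (n_perm = %d, level = %g)\n",
    x$contrast_id, length(x$t_values), sum(x$sig_mask), x$n_perm,
    x$alpha_level))
  invisible(x)
}

# paired t statistics per column given a subjects x sources matrix of
# differences; sign-flip invariant sum of squares is precomputed
.paired_t <- function(D) {
  n <- nrow(D)
  m <- colMeans(D)
  ss <- colSums(D^2)
  s2 <- (ss - n * m^2) / (n - 1)
  m / sqrt(s2 / n)
}

# pooled two-sample t per column for rows idx_a vs the rest
.pooled_t <- function(X, in_a, X2 = X^2) {
  n1 <- sum(in_a); n2 <- nrow(X) - n1
  s1 <- colSums(X[in_a, , drop = FALSE])
  s2 <- colSums(X[!in_a, , drop = FALSE])
  q1 <- colSums(X2[in_a, , drop = FALSE])
  q2 <- colSums(X2[!in_a, , drop = FALSE])
  m1 <- s1 / n1; m2 <- s2 / n2
  sp2 <- pmax((q1 - n1 * m1^2 + q2 - n2 * m2^2) / (n1 + n2 - 2), 1e-300)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Monte-Carlo permutation test on source maps
#'
#' Voxel-wise nonparametric inference for two conditions across subjects.
#' The observed statistic is the per-source two-sample pooled-variance t
#' (unpaired) or paired t. The null distribution is built by random label
#' permutation: group-label shuffles for the unpaired design, and
#' within-subject condition swaps -- equivalently random sign flips of the
#' per-subject differences -- for the paired design. Two-tailed p-values use
#' the add-one estimator `p = (1 + #{|T_perm| >= |T_obs|}) / (1 + n_perm)`,
#' which cannot return an exact zero. Sources with zero variance under the
#' statistic are flagged with `p = 1` and a warning.
#'
#' @param maps_a,maps_b numeric matrices, subjects x sources, condition A
#'   and B values (rows matched across conditions when `paired = TRUE`).
#' @param paired logical; paired (within-subject) or unpaired design.
#' @param n_perm number of Monte-Carlo permutations (default 10000).
#' @param seed RNG seed.
#' @return A [stat_map()] with unthresholded p-values (apply
#'   [fdr_correct()] for the corrected mask).
#' @export
#' @examples
#' a <- matrix(rnorm(50), 10)
#' b <- matrix(rnorm(50), 10)
#' pm <- permutation_test(a, b, paired = TRUE, n_perm = 500, seed = 1)
permutation_test <- function(maps_a, maps_b, paired = FALSE,
                             n_perm = 10000, seed = NULL) {
  maps_a <- as.matrix(maps_a); maps_b <- as.matrix(maps_b)
  if (ncol(maps_a) != ncol(maps_b)) {
    stop("condition maps must share the source space", call. = FALSE)
  }
  if (paired && nrow(maps_a) != nrow(maps_b)) {
    stop("paired design requires matched subject rows", call. = FALSE)
  }
  if (min(nrow(maps_a), nrow(maps_b)) < 3L) {
    stop("need at least 3 subjects per condition", call. = FALSE)
  }
  m <- ncol(maps_a)
  local_seed(seed, {
    if (paired) {
      D <- maps_a - maps_b
      n <- nrow(D)
      ss <- colSums(D^2)
      s2 <- (ss - n * colMeans(D)^2) / (n - 1)
      s2_zero <- s2 <= 1e-12 * pmax(ss / (n - 1), 1e-300)
      t_obs <- .paired_t(D)
      t_obs[s2_zero] <- 0
      # tie-tolerant threshold: permutations that reproduce |T_obs| exactly
      # (e.g. the identity and global-flip patterns) must count even when
      # the vectorized path rounds differently
      t_thr <- abs(t_obs) - 1e-8 * (1 + abs(t_obs))
      exceed <- numeric(m)
      # sign-flip null: colSums(D^2) is flip-invariant, so each
      # permutation only needs the flipped column means
      chunk <- max(1L, min(n_perm, floor(2e6 / m)))
      done <- 0L
      while (done < n_perm) {
        b <- min(chunk, n_perm - done)
        S <- matrix(sample(c(-1, 1), b * n, replace = TRUE), b, n)
        Mp <- (S %*% D) / n # b x m
        s2p <- pmax(sweep(-n * Mp^2, 2, ss, "+") / (n - 1), 1e-300)
        Tp <- Mp / sqrt(s2p / n)
        exceed <- exceed +
          colSums(abs(Tp) >= matrix(t_thr, b, m, byrow = TRUE))
        done <- done + b
      }
    } else {
      X <- rbind(maps_a, maps_b)
      n <- nrow(X)
      in_a <- rep(c(TRUE, FALSE), c(nrow(maps_a), nrow(maps_b)))
      X2 <- X^2
      vv <- apply(X, 2, var)
      s2_zero <- vv <= 1e-12 * pmax(colMeans(X2), 1e-300)
      t_obs <- .pooled_t(X, in_a, X2)
      t_obs[s2_zero] <- 0
      t_thr <- abs(t_obs) - 1e-8 * (1 + abs(t_obs))
      exceed <- numeric(m)
      for (b in seq_len(n_perm)) {
        Tp <- .pooled_t(X, sample(in_a), X2)
        exceed <- exceed + (abs(Tp) >= t_thr)
      }
    }
    p <- (1 + exceed) / (1 + n_perm)
    if (any(s2_zero)) {
      warning(sprintf("%d zero-variance source(s); p set to 1",
                      sum(s2_zero)))
      t_obs[s2_zero] <- 0
      p[s2_zero] <- 1
    }
    stat_map(t_obs, pmin(p, 1),
             contrast_id = if (paired) "paired" else "unpaired",
             n_perm = n_perm)
  })
}

#' Benjamini-Hochberg FDR mask
#'
#' Step-up false discovery rate control over the submitted collection of
#' p-values (typically sources x bands jointly). A p-value passes when its
#' BH-adjusted value is at most `q`, equivalent to the classic step-up rule
#' with thresholds `i * q / m`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param q target FDR level (default 0.05).
#' @return Logical mask of discoveries.
#' @export
#' @examples
#' fdr_correct(c(0.001, 0.01, 0.2, 0.8))
fdr_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) stop("empty p-value vector", call. = FALSE)
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH") <= q
}

#' Conjunction (logical AND) of significance masks
#'
#' Formal conjunction inference: a source survives only if it is
#' individually significant in every contributing contrast. Accepts logical
#' masks or `stat_map` objects.
#'
#' @param mask_a,mask_b logical masks or [stat_map()]s over the same source
#'   space.
#' @return Logical conjunction mask.
#' @export
conjunction <- function(mask_a, mask_b) {
  if (inherits(mask_a, "stat_map")) mask_a <- mask_a$sig_mask
  if (inherits(mask_b, "stat_map")) mask_b <- mask_b$sig_mask
  if (length(mask_a) != length(mask_b)) {
    stop("masks are defined over different source spaces", call. = FALSE)
  }
  as.logical(mask_a) & as.logical(mask_b)
}
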