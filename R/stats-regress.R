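#' Per-source regression of alpha-power change on clinical change
#'
#' Tests, source by source, the linear association between each subject's
#' change in relative alpha power (post minus pre, one map per subject) and
#' their change in CAPS severity. For source `j` the model is `delta_map[,
#' j] ~ delta_caps` by ordinary least squares; the returned map carries the
#' slope t-statistics, two-sided p-values, and a Benjamini-Hochberg FDR
#' mask. A zero-variance predictor is flagged and all p-values set to 1.
#'
#' @param delta_caps numeric vector, per-subject CAPS change (post - pre).
#' @param delta_alpha_maps numeric matrix, subjects x sources, per-subject
#'   alpha relative-power change maps.
#' @param q FDR level for the mask.
#' @return A [stat_map()] with an extra `slopes` element.
#' @export
#' @examples
#' maps <- matrix(rnorm(40), 10)
#' caps <- rnorm(10)
#' sm <- regress_caps_on_alpha_change(caps, maps)
regress_caps_on_alpha_change <- function(delta_caps, delta_alpha_maps,
                                         q = 0.05) {
  delta_alpha_maps <- as.matrix(delta_alpha_maps)
  n <- length(delta_caps)
  if (nrow(delta_alpha_maps) != n) {
    stop("one map row per subject is required", call. = FALSE)
  }
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  m <- ncol(delta_alpha_maps)
  x <- delta_caps - mean(delta_caps)
  sxx <- sum(x^2)
  if (sxx == 0) {
    warning("constant clinical change: association undefined, p = 1")
    sm <- stat_map(rep(0, m), rep(1, m), contrast_id = "caps_alpha_regression",
                   alpha_level = q)
    sm$slopes <- rep(NA_real_, m)
    return(sm)
  }
  Yc <- sweep(delta_alpha_maps, 2, colMeans(delta_alpha_maps), "-")
  beta <- drop(crossprod(x, Yc)) / sxx
  res <- Yc - x %o% beta
  s2 <- colSums(res^2) / (n - 2)
  se <- sqrt(s2 / sxx)
  tv <- ifelse(se > 0, beta / se, 0)
  p <- 2 * pt(abs(tv), df = n - 2, lower.tail = FALSE)
  p[se == 0] <- 1
  sm <- stat_map(tv, p, sig_mask = fdr_correct(p, q),
                 contrast_id = "caps_alpha_regression", alpha_level = q)
  sm$slopes <- beta
  sm
}
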