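# Approximate unit-sphere positions of the 19 electrodes of the 10-20
# montage (x = right, y = front, z = up), parameterized by inclination from
# the vertex and azimuth.
.montage_1020 <- local({
  ang <- rbind(
    Fp1 = c(90, 108), Fp2 = c(90, 72),
    F7 = c(90, 144), F3 = c(60, 120), Fz = c(45, 90),
    F4 = c(60, 60), F8 = c(90, 36),
    T3 = c(90, 180), C3 = c(45, 180), Cz = c(0, 0),
    C4 = c(45, 0), T4 = c(90, 0),
    T5 = c(90, 216), P3 = c(60, 240), Pz = c(45, 270),
    P4 = c(60, 300), T6 = c(90, 324),
    O1 = c(90, 252), O2 = c(90, 288))
  th <- ang[, 1] * pi / 180
  ph <- ang[, 2] * pi / 180
  pos <- cbind(x = sin(th) * cos(ph), y = sin(th) * sin(ph), z = cos(th))
  rownames(pos) <- rownames(ang)
  pos
})

#' Standard 19-channel 10-20 montage labels
#' @return Character vector of the 19 electrode labels in montage order.
#' @export
montage_1020_labels <- function() rownames(.montage_1020)

.region_of <- function(p) {
  if (p[2] > 0.25) {
    if (abs(p[1]) < 0.35) "anterior_medial" else "anterior_lateral"
  } else if (p[2] < -0.25) "posterior" else "central"
}

#' Build a toy spherical-head leadfield for the 19-channel 10-20 montage
#'
#' Places `n_sources` dipolar sources inside a unit-sphere head (sources
#' stratified over anterior-medial, anterior-lateral, posterior and central
#' compartments so every region is represented) and computes, for each of
#' three orthogonal dipole orientations, quasi-static potential gains at the
#' 19 scalp electrodes of the 10-20 system. The gain of orientation `o` of
#' source `j` at electrode `c` is \eqn{e_o \cdot (r_c - r_j) / |r_c -
#' r_j|^3}. Region labels take the place of anatomical structures: the
#' anterior-medial compartment stands in for the medial frontal cortex where
#' the baseline alpha deficit and the post-treatment rebound are expressed,
#' the posterior compartment for occipital/cuneus cortex.
#'
#' @param n_sources number of sources (>= 2).
#' @param seed RNG seed; the leadfield is deterministic given the seed.
#' @param depth maximum source eccentricity as a fraction of head radius.
#' @param regions compartment labels cycled over the sources; the default
#'   alternates anterior-medial, posterior and anterior-lateral sources,
#'   leaving a gap (|y| <= 0.25) between the anterior and posterior
#'   compartments so the two contrast regions are spatially separated.
#' @return An object of class `leadfield`: `gain` (n_sources x 3 x 19),
#'   `source_positions` (n_sources x 3), `region_labels`, `orientations`
#'   (per-source default dipole orientation used by the simulator),
#'   `channel_labels`, `electrode_positions`, `space_id`.
#' @export
#' @examples
#' lf <- make_toy_leadfield(24, seed = 1)
#' table(lf$region_labels)
make_toy_leadfield <- function(n_sources, seed = NULL, depth = 0.8,
                               regions = c("anterior_medial", "posterior",
                                           "anterior_lateral")) {
  stopifnot(is.numeric(n_sources), n_sources >= 2)
  n_sources <- as.integer(n_sources)
  epos <- .montage_1020
  n_ch <- nrow(epos)
  regions <- rep(regions, length.out = n_sources)
  local_seed(seed, {
    pos <- matrix(NA_real_, n_sources, 3,
                  dimnames = list(NULL, c("x", "y", "z")))
    for (j in seq_len(n_sources)) {
      repeat {
        p <- runif(3, -depth, depth)
        if (sum(p^2) > depth^2 || p[3] < -0.2) next
        if (.region_of(p) == regions[j]) break
      }
      pos[j, ] <- p
    }
    gain <- array(0, c(n_sources, 3, n_ch))
    for (j in seq_len(n_sources)) {
      d <- sweep(epos, 2, pos[j, ], "-") # n_ch x 3
      r3 <- rowSums(d^2)^(3 / 2)
      for (o in 1:3) gain[j, o, ] <- d[, o] / r3
    }
    ori <- matrix(rnorm(3 * n_sources), n_sources, 3)
    ori <- ori / sqrt(rowSums(ori^2))
    structure(
      list(gain = gain, source_positions = pos, region_labels = regions,
           orientations = ori, channel_labels = rownames(epos),
           electrode_positions = epos,
           space_id = sprintf("toy_sphere_n%d_seed%s", n_sources,
                              seed %||% "none")),
      class = "leadfield")
  })
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d sources x 3 orientations x %d channels (%s)\n",
              dim(x$gain)[1], dim(x$gain)[3], x$space_id))
  print(table(x$region_labels))
  invisible(x)
}

# leadfield gain rearranged as channels x (3 * n_sources), orientation
# fastest
.lf_matrix <- function(lf) {
  n_src <- dim(lf$gain)[1]
  n_ch <- dim(lf$gain)[3]
  K <- matrix(0, n_ch, 3 * n_src)
  for (j in seq_len(n_src)) {
    K[, (3 * j - 2):(3 * j)] <- t(lf$gain[j, , ])
  }
  K
}
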