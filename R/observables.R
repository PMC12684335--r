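#' Lipari-Szabo order parameter from a bond-vector series
#'
#' \deqn{S^2 = \tfrac{3}{2}\sum_{a,b\in\{x,y,z\}} \langle e_a e_b\rangle^2
#'   - \tfrac{1}{2}} over unit vectors. Vectors are assumed expressed in a
#' molecule-fixed frame (overall tumbling removed, e.g. after superposition
#' with [superpose()]); they are normalised internally.
#'
#' @param vectors numeric matrix, one frame per row, columns x, y, z.
#' @return S2 in `[0, 1]` (up to sampling noise).
#' @export
s2_order_parameter <- function(vectors) {
  v <- as.matrix(vectors)
  stopifnot(ncol(v) == 3)
  if (nrow(v) < 2) stop("need at least 2 frames")
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm == 0)) stop("zero-length vector in series")
  e <- v / nrm
  acc <- 0
  for (a in 1:3) for (b in 1:3) acc <- acc + mean(e[, a] * e[, b])^2
  1.5 * acc - 0.5
}

#' r^-6-averaged distance
#'
#' The NOE-relevant ensemble average \eqn{\langle r^{-6}\rangle^{-1/6}},
#' which is dominated by the closest-approach frames.
#'
#' @param r per-frame distances, Angstrom (all > 0).
#' @return averaged distance, Angstrom.
#' @export
r6_mean_distance <- function(r) {
  r <- as.numeric(r)
  if (length(r) == 0) stop("empty distance series")
  if (any(r <= 0)) stop("distances must be positive")
  mean(r^-6)^(-1 / 6)
}

#' Normalised distance histogram
#'
#' @param r per-frame distances, Angstrom.
#' @param edges bin edges, Angstrom (default: 60 bins over the data range).
#' @return list of class `distance_histogram`: `edges`, `density`
#'   (integrates to 1), `counts`.
#' @export
distance_histogram <- function(r, edges = NULL) {
  r <- as.numeric(r)
  if (is.null(edges))
    edges <- seq(min(r) - 1e-9, max(r) + 1e-9, length.out = 61)
  h <- graphics::hist(r, breaks = edges, plot = FALSE)
  structure(list(edges = h$breaks, density = h$density, counts = h$counts),
            class = "distance_histogram")
}

#' Modes of a distance histogram
#'
#' Local maxima of the binned density (after light 3-bin smoothing),
#' reported as bin midpoints; used to verify bimodal open/closed sampling.
#'
#' @param h a `distance_histogram`.
#' @param min_frac ignore modes below this fraction of the global maximum.
#' @return numeric vector of mode positions, Angstrom.
#' @export
histogram_modes <- function(h, min_frac = 0.05) {
  d <- as.numeric(stats::filter(h$density, rep(1 / 3, 3), sides = 2))
  d[is.na(d)] <- h$density[is.na(d)]
  mids <- (h$edges[-1] + h$edges[-length(h$edges)]) / 2
  n <- length(d)
  is_peak <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) d[i - 1] else -Inf
    r <- if (i < n) d[i + 1] else -Inf
    d[i] >= l && d[i] >= r && d[i] > 0
  }, logical(1))
  keep <- is_peak & d >= min_frac * max(d)
  # merge adjacent flagged bins into single modes
  runs <- rle(keep)
  pos <- cumsum(runs$lengths)
  out <- numeric(0)
  start <- c(1, utils::head(pos, -1) + 1)
  for (j in seq_along(runs$values)) if (runs$values[j]) {
    seg <- start[j]:pos[j]
    out <- c(out, mids[seg][which.max(d[seg])])
  }
  out
}

#' Distance from one atom to the centre of a pair, per frame
#'
#' E.g. Ile97 Cd1 to the geometric centre of Val84 Cg1/Cg2 across a
#' trajectory.
#'
#' @param xyz_a frames x 3 matrix, coordinates of the single atom.
#' @param xyz_b1,xyz_b2 frames x 3 matrices, coordinates of the pair.
#' @return per-frame distances, Angstrom.
#' @export
methyl_center_distance <- function(xyz_a, xyz_b1, xyz_b2) {
  a <- as.matrix(xyz_a); b1 <- as.matrix(xyz_b1); b2 <- as.matrix(xyz_b2)
  stopifnot(ncol(a) == 3, all(dim(a) == dim(b1)), all(dim(a) == dim(b2)))
  mid <- (b1 + b2) / 2
  sqrt(rowSums((a - mid)^2))
}

#' NOE visibility call from an r^-6-averaged distance
#'
#' Methyl-methyl NOEs are typically observable up to about 10 Angstrom;
#' the cutoff is inclusive.
#'
#' @param r6_distance r^-6-averaged distance, Angstrom.
#' @param cutoff visibility cutoff, Angstrom (default 10).
#' @return logical: visible?
#' @export
noe_visibility <- function(r6_distance, cutoff = 10) {
  r6_distance <= cutoff
}
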