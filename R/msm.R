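#' Transition count matrix from discrete trajectories
#'
#' Sliding-window counts at the given lag, summed over trajectories.
#' State space is `0 .. max(label)` unless `n_states` is given; counts are
#' indexed 1-based (state `i` label = `i - 1`).
#'
#' @param dtrajs a list of integer vectors (labels >= 0), or one vector.
#' @param lag lag time in frames (>= 1, shorter than every trajectory).
#' @param n_states optional number of states.
#' @return n x n count matrix.
#' @export
count_matrix <- function(dtrajs, lag = 1L, n_states = NULL) {
  if (!is.list(dtrajs)) dtrajs <- list(dtrajs)
  stopifnot(lag >= 1)
  lab <- unlist(dtrajs)
  if (any(lab < 0)) stop("labels must be >= 0")
  n <- n_states %||% (max(lab) + 1L)
  C <- matrix(0, n, n)
  for (d in dtrajs) {
    if (length(d) <= lag)
      stop("lag must be shorter than every trajectory")
    from <- d[seq_len(length(d) - lag)] + 1L
    to   <- d[seq_len(length(d) - lag) + lag] + 1L
    tab <- table(factor(from, levels = 1:n), factor(to, levels = 1:n))
    C <- C + unclass(tab)
  }
  dimnames(C) <- NULL
  C
}

#' Maximum-likelihood Markov state model from counts
#'
#' Reversible estimation solves the detailed-balance-constrained likelihood
#' by the standard iterative fixed-point on the unnormalised flux variables
#' `x_ij`, giving a transition matrix satisfying `pi_i T_ij = pi_j T_ji`
#' essentially to machine precision. Non-reversible mode row-normalises the
#' counts. In reversible mode the estimate is restricted to the largest
#' strongly connected set of states; dropped states are reported.
#'
#' @param counts count matrix from [count_matrix()].
#' @param lag lag time used, in frames (carried as metadata).
#' @param dt frame interval in seconds (metadata; default 1).
#' @param reversible enforce detailed balance (default TRUE).
#' @param tol convergence tolerance on the transition matrix.
#' @param max_iter iteration cap.
#' @return object of class `msm`: `T` (row-stochastic), `pi`, `active`
#'   (original 0-based labels of retained states), `dropped`, `lag`, `dt`,
#'   `reversible`.
#' @export
estimate_msm <- function(counts, lag = 1L, dt = 1, reversible = TRUE,
                         tol = 1e-14, max_iter = 10000L) {
  counts <- as.matrix(counts)
  n0 <- nrow(counts)
  active <- seq_len(n0)
  dropped <- integer(0)
  if (reversible) {
    g <- igraph::graph_from_adjacency_matrix(counts > 0, mode = "directed")
    comp <- igraph::components(g, mode = "strong")
    sizes <- tapply(rowSums(counts) + colSums(counts), comp$membership, sum)
    keep <- comp$membership == as.integer(names(which.max(sizes)))
    if (!all(keep)) {
      dropped <- which(!keep)
      message("estimate_msm: dropping ", length(dropped),
              " state(s) outside the largest connected set: ",
              paste(dropped - 1L, collapse = ", "))
      counts <- counts[keep, keep, drop = FALSE]
      active <- which(keep)
    }
  }
  n <- nrow(counts)
  ci <- rowSums(counts)
  if (any(ci == 0)) stop("state(s) with no outgoing counts")
  if (reversible) {
    Csym <- counts + t(counts)
    x <- Csym / sum(counts)        # init
    Tm_old <- x / rowSums(x)
    for (it in seq_len(max_iter)) {
      xi <- rowSums(x)
      denom <- outer(ci / xi, ci / xi, "+")
      x <- Csym / denom
      Tm <- x / rowSums(x)
      if (max(abs(Tm - Tm_old)) < tol) break
      Tm_old <- Tm
    }
    pi <- rowSums(x) / sum(x)
  } else {
    Tm <- counts / ci
    pi <- stationary_distribution(Tm)
  }
  structure(list(T = Tm, pi = as.numeric(pi),
                 active = active - 1L, dropped = dropped - 1L,
                 lag = lag, dt = dt, reversible = reversible),
            class = "msm")
}

#' @export
print.msm <- function(x, ...) {
  cat(sprintf("<msm> %d states, lag %d frame(s) (%.3g s), %s\n",
              nrow(x$T), x$lag, x$lag * x$dt,
              if (x$reversible) "reversible" else "non-reversible"))
  cat("  pi:", paste(sprintf("%.4f", x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Stationary distribution of a row-stochastic matrix
#' @param T row-stochastic transition matrix.
#' @return stationary probability vector.
#' @export
stationary_distribution <- function(T) {
  ev <- eigen(t(T))
  i <- which.min(abs(ev$values - 1))
  v <- Re(ev$vectors[, i])
  v <- v * sign(sum(v))
  v / sum(v)
}

#' Implied relaxation timescales of an MSM
#'
#' `t_i = -tau / log(lambda_i)` for eigenvalues below 1, sorted descending.
#' Non-positive eigenvalues have no defined timescale and are returned as
#' `NA` (flagged); a unit eigenvalue beyond the first (reducible chain)
#' yields `Inf`.
#'
#' @param msm an `msm` object (or a row-stochastic matrix).
#' @param tau lag time in physical units; defaults to `lag * dt` of the
#'   model, or 1 for a raw matrix.
#' @return numeric vector of timescales (same units as `tau`).
#' @export
implied_timescales <- function(msm, tau = NULL) {
  T <- if (inherits(msm, "msm")) msm$T else as.matrix(msm)
  if (is.null(tau))
    tau <- if (inherits(msm, "msm")) msm$lag * msm$dt else 1
  lam <- eigen(T, only.values = TRUE)$values
  lam <- Re(lam[order(-Mod(lam))])[-1]   # drop the unit eigenvalue
  ts <- ifelse(lam <= 0, NA_real_,
               ifelse(lam >= 1, Inf, -tau / log(lam)))
  sort(ts, decreasing = TRUE, na.last = TRUE)
}

#' PCCA-like coarse-graining into metastable macrostates
#'
#' Spectral assignment of microstates to `n_macro` metastable sets: the
#' microstates are embedded in the space of the `n_macro - 1` slowest right
#' eigenvectors, vertices of the resulting simplex are located by
#' furthest-point search, and fuzzy memberships are the barycentric
#' coordinates (clipped to `[0, 1]` and renormalised). Crisp assignments
#' (argmax) are used for population and rate reporting.
#'
#' @param msm an `msm` object.
#' @param n_macro number of macrostates.
#' @param gap_tol warn when the spectral gap at the cut is below this.
#' @return object of class `coarse_model`: `membership` (micro x macro,
#'   rows sum 1), `assignment` (crisp, 1-based), `pi_macro`,
#'   `T_macro` (crisp-projected transition matrix), `K_macro`
#'   (generator of `T_macro` via [generator_from_tmatrix()], per unit
#'   `lag * dt`), `msm`.
#' @export
coarse_grain <- function(msm, n_macro, gap_tol = 1e-3) {
  T <- msm$T; pi <- msm$pi
  n <- nrow(T)
  stopifnot(n_macro >= 1, n_macro <= n)
  if (n_macro == 1L) {
    return(structure(list(membership = matrix(1, n, 1),
                          assignment = rep(1L, n), pi_macro = 1,
                          T_macro = matrix(1, 1, 1),
                          K_macro = matrix(0, 1, 1), msm = msm),
                     class = "coarse_model"))
  }
  ev <- eigen(T)
  ord <- order(-Re(ev$values))
  lam <- Re(ev$values[ord])
  if (any(abs(Im(ev$values[ord][seq_len(n_macro)])) > 1e-8))
    warning("complex eigenvalues among the slow spectrum")
  if (n_macro < n && abs(lam[n_macro] - lam[n_macro + 1]) < gap_tol)
    warning("no spectral gap after ", n_macro, " states")
  # right eigenvectors 2..n_macro
  X <- Re(ev$vectors[, ord[seq_len(n_macro)], drop = FALSE])
  X[, 1] <- 1
  # inner-simplex vertex search (furthest point from affine span so far)
  verts <- integer(n_macro)
  d <- sqrt(rowSums(scale(X, scale = FALSE)^2))
  verts[1] <- which.max(d)
  for (k in 2:n_macro) {
    B <- X[verts[1:(k - 1)], , drop = FALSE]
    proj <- function(i) {
      # distance of X[i,] to affine hull of rows of B
      A <- t(B[-1, , drop = FALSE]) - B[1, ]
      v <- X[i, ] - B[1, ]
      if (ncol(A) == 0 || k == 2) sqrt(sum(v^2))
      else {
        cf <- qr.solve(qr(A), v)
        sqrt(sum((v - A %*% cf)^2))
      }
    }
    verts[k] <- which.max(vapply(seq_len(n), proj, numeric(1)))
  }
  # barycentric coordinates w.r.t. the vertex states
  V <- X[verts, , drop = FALSE]
  M <- t(qr.solve(t(V), t(X)))   # rows: coefficients summing to 1
  M[M < 0] <- 0
  M <- M / rowSums(M)
  assign <- max.col(M, ties.method = "first")
  pi_macro <- vapply(seq_len(n_macro), function(a) sum(pi[assign == a]),
                     numeric(1))
  # crisp projection of the transition matrix: flux between macrostates
  Tm <- matrix(0, n_macro, n_macro)
  for (a in seq_len(n_macro)) for (b in seq_len(n_macro)) {
    Tm[a, b] <- sum(pi[assign == a] *
                      rowSums(T[assign == a, assign == b, drop = FALSE])) /
      pi_macro[a]
  }
  K <- tryCatch(generator_from_tmatrix(Tm, msm$lag * msm$dt)$K,
                error = function(e) matrix(NA_real_, n_macro, n_macro))
  structure(list(membership = M, assignment = assign, pi_macro = pi_macro,
                 T_macro = Tm, K_macro = K, msm = msm),
            class = "coarse_model")
}

#' @export
print.coarse_model <- function(x, ...) {
  cat(sprintf("<coarse_model> %d macrostates, populations: %s\n",
              length(x$pi_macro),
              paste(sprintf("%.3f", x$pi_macro), collapse = " ")))
  invisible(x)
}

#' Rate-matrix generator from a transition matrix
#'
#' Matrix logarithm of `T` divided by the lag, via eigendecomposition
#' (real for reversible chains). Small negative off-diagonal entries arising
#' from the projection are clipped to zero and diagonals repaired to keep
#' zero row sums; the size of that repair is reported.
#'
#' @param T row-stochastic transition matrix.
#' @param tau lag time in physical units (seconds for rates in rad/s... the
#'   returned rates have units 1/`tau` units).
#' @return list: `K` (rate matrix), `clip` (largest clipped magnitude),
#'   `eigenvalues` of `T`.
#' @export
generator_from_tmatrix <- function(T, tau = 1) {
  T <- as.matrix(T)
  if (max(abs(rowSums(T) - 1)) > 1e-8) stop("T is not row-stochastic")
  ev <- eigen(T)
  if (any(Re(ev$values) <= 0 & abs(Im(ev$values)) < 1e-12))
    stop("matrix logarithm undefined: non-positive real eigenvalue ",
         "(lag too long for a generator description)")
  L <- ev$vectors %*% (log(ev$values) * solve(ev$vectors))
  if (max(abs(Im(L))) > 1e-8)
    warning("non-negligible imaginary part in matrix logarithm")
  K <- Re(L) / tau
  off <- K; diag(off) <- 0
  clip <- max(0, -min(off))
  off[off < 0] <- 0
  diag(off) <- -rowSums(off)
  list(K = off, clip = clip, eigenvalues = ev$values)
}

#' Read discrete trajectories (one integer label per line)
#' @param paths character vector of files.
#' @return list of integer vectors.
#' @export
read_dtrajs <- function(paths) {
  lapply(paths, function(p) as.integer(readLines(p)))
}
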