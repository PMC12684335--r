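#' Coarse kinetic block from an MSM
#'
#' Helper turning a (possibly partial) simulation MSM into a coarse-grained
#' kinetic block for [augment_with_experiment()]: the MSM is coarse-grained
#' to the macrostates it visits and its coarse generator converted to rates
#' per second.
#'
#' @param msm an `msm` estimated from one simulation block.
#' @param n_macro macrostates within this block.
#' @param states global macrostate indices (length `n_macro`) this block's
#'   macrostates correspond to; the order follows decreasing block
#'   population unless a `match_by` permutation is given.
#' @param match_by optional explicit permutation mapping the coarse model's
#'   macrostate order to `states`.
#' @return list with `states`, `K` (rad/s, `n_macro` x `n_macro`),
#'   `pi` (within-block), `coarse` (the `coarse_model`).
#' @export
kinetic_block <- function(msm, n_macro, states, match_by = NULL) {
  stopifnot(length(states) == n_macro)
  cg <- coarse_grain(msm, n_macro)
  perm <- match_by %||% order(-cg$pi_macro)
  K <- cg$K_macro[perm, perm, drop = FALSE]
  list(states = states, K = K, pi = cg$pi_macro[perm] / sum(cg$pi_macro),
       coarse = cg)
}

# global network from parameters: pi by softmax, detailed-balance rates from
# symmetric log-fluxes; theta = c(pi logits (n-1), log-flux per pair)
.theta_to_network <- function(theta, n) {
  lp <- c(theta[seq_len(n - 1)], 0)
  pi <- exp(lp - max(lp)); pi <- pi / sum(pi)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  S <- matrix(0, n, n)
  S[pairs] <- exp(theta[(n - 1) + seq_len(nrow(pairs))])
  S <- S + t(S)
  K <- S / pi
  diag(K) <- 0
  diag(K) <- -rowSums(K)
  list(K = K, pi = pi)
}

.network_to_theta <- function(K, pi) {
  n <- length(pi)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  S <- pi * K                      # symmetric under detailed balance
  S <- (S + t(S)) / 2
  c(log(pi[-n] / pi[n]), log(pmax(S[pairs], 1e-12)))
}

#' Augment simulation kinetics with experimental dispersion data
#'
#' Estimates a single global few-state kinetic network from simulation
#' blocks that need not be mutually connected, by finding the smallest
#' perturbation of the simulation-derived kinetics that brings the predicted
#' CPMG dispersion into agreement with experiment. Free parameters are the
#' inter-block exchange fluxes (absent from simulation) and a global
#' population rebalancing; intra-block rates may deviate from their
#' simulation values subject to a log-space penalty. The network is
#' parametrised by stationary populations (softmax) and symmetric exchange
#' fluxes, so detailed balance holds by construction. The objective is
#' \deqn{\sum_{r,f,\nu} \left(\frac{R_{2,eff}^{obs} - R_{2,eff}^{calc}}
#'   {\sigma}\right)^2 + \lambda \sum_{(i,j)\in sim}
#'   (\log k_{ij} - \log k_{ij}^{sim})^2}
#' minimised by seeded multistart Levenberg-Marquardt (the penalty enters as
#' extra residuals).
#'
#' @param blocks list of blocks from [kinetic_block()] (or lists with
#'   `states` and `K` in rad/s). Within-block populations implied by each
#'   `K` seed the optimiser; across-block weights start equal.
#' @param curves `dispersion_curves` table (>= 1 field).
#' @param offsets_ppm matrix of per-state chemical-shift offsets, one row
#'   per residue present in `curves` (rownames = residue numbers), one
#'   column per global state; `NULL` to fit them jointly (bounded
#'   `offset_bound`).
#' @param r2_0 intrinsic R2: matrix residues x fields (dimnames residue /
#'   field MHz), a scalar, or `NULL` to fit per residue and field.
#' @param n_states number of global macrostates; default inferred from
#'   `blocks`.
#' @param lambda penalty weight on intra-block kinetic deviations.
#' @param n_starts multistarts over inter-block rate seeds.
#' @param seed RNG seed for the multistart jitter.
#' @param nucleus passed to the forward model.
#' @param offset_bound bound (ppm) on jointly fitted offsets.
#' @return object of class `augmented_network`: `network`
#'   ([kinetic_network()] with population-ordered states), `pi`, `K`
#'   (rad/s), `chi2` (experimental part), `perturbation` (RMS log-space
#'   deviation of intra-block rates), `offsets_ppm`, `r2_0`, `converged`,
#'   `n_eval`.
#' @export
augment_with_experiment <- function(blocks, curves, offsets_ppm = NULL,
                                    r2_0 = NULL, n_states = NULL,
                                    lambda = 1, n_starts = 8,
                                    seed = 20250101, nucleus = "N",
                                    offset_bound = 6) {
  stopifnot(length(blocks) >= 1, nrow(curves) > 0)
  n <- n_states %||% max(unlist(lapply(blocks, `[[`, "states")))
  fields <- sort(unique(curves$field_mhz))
  resids <- sort(unique(curves$residue))
  nr <- length(resids); nf <- length(fields)
  disconnected <- length(blocks) > 1

  # simulation prior: intra-block rates mapped onto the global index set
  K_sim <- matrix(NA_real_, n, n)
  for (b in blocks) {
    s <- b$states
    off <- b$K; diag(off) <- NA
    K_sim[s, s] <- off
  }
  sim_pairs <- which(!is.na(K_sim) & K_sim > 0, arr.ind = TRUE)
  if (nrow(sim_pairs) == 0 && disconnected)
    stop("no intra-block rates and disconnected blocks: unidentifiable")

  fit_off <- is.null(offsets_ppm)
  if (!fit_off) {
    offsets_ppm <- as.matrix(offsets_ppm)
    stopifnot(nrow(offsets_ppm) == nr, ncol(offsets_ppm) == n)
  }
  fit_r2 <- is.null(r2_0)
  if (!fit_r2 && length(r2_0) == 1L)
    r2_0 <- matrix(r2_0, nr, nf, dimnames = list(resids, fields))

  n_pair <- n * (n - 1) / 2
  n_core <- (n - 1) + n_pair
  n_off <- if (fit_off) nr * (n - 1) else 0   # state 1 is the reference
  n_r2  <- if (fit_r2) nr * nf else 0

  sig <- ifelse(curves$r2eff_err > 0, curves$r2eff_err, 1)
  n_eval <- 0L

  unpack <- function(theta) {
    net <- .theta_to_network(theta[seq_len(n_core)], n)
    offs <- if (fit_off) {
      cbind(0, matrix(theta[n_core + seq_len(n_off)], nr, n - 1))
    } else offsets_ppm
    r2m <- if (fit_r2) {
      matrix(exp(theta[n_core + n_off + seq_len(n_r2)]), nr, nf)
    } else r2_0
    list(net = net, offs = offs, r2m = r2m)
  }

  sel_idx <- lapply(seq_len(nr), function(ri) lapply(seq_len(nf), function(fi)
    which(curves$residue == resids[ri] & curves$field_mhz == fields[fi])))

  resfun <- function(theta) {
    n_eval <<- n_eval + 1L
    p <- unpack(theta)
    Kt <- t(p$net$K)
    calc <- numeric(nrow(curves))
    for (ri in seq_len(nr)) for (fi in seq_len(nf)) {
      sel <- sel_idx[[ri]][[fi]]
      if (length(sel) == 0) next
      omega <- ppm_to_rad(p$offs[ri, ], fields[fi], nucleus)
      A0 <- Kt + 1i * diag(omega, n) - diag(rep(p$r2m[ri, fi], n), n)
      calc[sel] <- .bm_rate(A0, curves$nu_cpmg[sel])
    }
    pen <- sqrt(lambda) *
      (log(pmax(p$net$K[sim_pairs], 1e-300)) - log(K_sim[sim_pairs]))
    c((curves$r2eff - calc) / sig, pen)
  }

  # seed populations: equal block weights times within-block populations
  pi0 <- rep(1e-3, n)
  for (b in blocks) {
    pib <- b$pi %||% tryCatch(stationary_from_K(b$K),
                              error = function(e) rep(1, length(b$states)))
    pi0[b$states] <- pib / length(blocks)
  }
  pi0 <- pi0 / sum(pi0)
  K0 <- K_sim
  r2_start <- vapply(seq_len(nf), function(fi) vapply(seq_len(nr), function(ri) {
    sel <- curves$residue == resids[ri] & curves$field_mhz == fields[fi]
    if (any(sel)) min(curves$r2eff[sel]) else 10
  }, numeric(1)), numeric(nr))
  r2_start <- matrix(r2_start, nr, nf)

  starts <- with_seed(seed, lapply(seq_len(n_starts), function(s) {
    Kst <- K0
    # unknown (inter-block) rates: log-uniform over 10^1..10^4 rad/s
    Kst[is.na(Kst)] <- 10^stats::runif(sum(is.na(Kst)), 1, 4)
    diag(Kst) <- 0; diag(Kst) <- -rowSums(Kst)
    pis <- pi0 * exp(stats::rnorm(n, 0, if (s == 1) 0 else 0.5))
    pis <- pis / sum(pis)
    th <- .network_to_theta(Kst, pis)
    if (fit_off)
      th <- c(th, stats::runif(n_off, -2, 2))
    if (fit_r2) th <- c(th, log(as.numeric(r2_start)))
    th
  }))

  lower <- rep(-Inf, n_core + n_off + n_r2)
  upper <- rep(Inf, n_core + n_off + n_r2)
  if (fit_off) {
    lower[n_core + seq_len(n_off)] <- -offset_bound
    upper[n_core + seq_len(n_off)] <- offset_bound
  }

  best <- NULL
  for (th0 in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                         fn = resfun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 300, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(f)) next
    if (is.null(best) || f$deviance < best$deviance) best <- f
  }
  if (is.null(best)) stop("augmentation optimiser failed to converge ",
                          "from every start")
  p <- unpack(best$par)
  resid_exp <- resfun(best$par)[seq_len(nrow(curves))]
  chi2 <- sum(resid_exp^2)
  pert <- if (nrow(sim_pairs) > 0) {
    sqrt(mean((log(pmax(p$net$K[sim_pairs], 1e-300)) -
                 log(K_sim[sim_pairs]))^2))
  } else 0
  net <- kinetic_network(p$net$K, pi = p$net$pi,
                         offsets_ppm = rep(0, n),
                         r2 = rep(mean(p$r2m), n),
                         names = paste0("M", seq_len(n)))
  structure(list(network = net, pi = p$net$pi, K = p$net$K,
                 chi2 = chi2, perturbation = pert,
                 offsets_ppm = `dimnames<-`(p$offs, list(resids, NULL)),
                 r2_0 = `dimnames<-`(p$r2m, list(resids, fields)),
                 lambda = lambda, K_sim = K_sim,
                 converged = best$info %in% 1:4, n_eval = n_eval,
                 residues = resids, fields = fields),
            class = "augmented_network")
}

#' @export
print.augmented_network <- function(x, ...) {
  cat("<augmented_network>", length(x$pi), "states\n")
  cat("  populations:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat(sprintf("  chi2 (exp) = %.2f, perturbation = %.3f, converged = %s\n",
              x$chi2, x$perturbation, x$converged))
  invisible(x)
}

#' Serialise an augmented network to JSON
#'
#' @param aug `augmented_network` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(aug, path) {
  states <- lapply(seq_along(aug$pi), function(i) {
    list(name = aug$network$names[i], population = aug$pi[i],
         offsets_ppm = as.numeric(aug$offsets_ppm[, i]))
  })
  jsonlite::write_json(
    list(states = states, rates_rad_s = aug$K, chi2 = aug$chi2,
         perturbation = aug$perturbation),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
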