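# Independent arithmetic oracles used across the suite. These are written
# as plain transcriptions of the textbook formulas, separate from the
# package's code paths.

# spreadsheet-level 15N relaxation rates: dipolar + CSA, rigid or
# Lipari-Szabo spectral density
oracle_rates <- function(tau_c, mhz, S2 = 1, tau_e = 0,
                         r_nh = 1.02e-10, csa = -172e-6) {
  gH <- 2.6752218744e8; gN <- -2.7126189e7
  hbar <- 1.054571817e-34; mu0 <- 4 * pi * 1e-7
  wH <- 2 * pi * mhz * 1e6
  wN <- abs(wH * gN / gH)
  J <- function(w) {
    tp <- if (tau_e > 0) 1 / (1 / tau_c + 1 / tau_e) else 0
    0.4 * (S2 * tau_c / (1 + (w * tau_c)^2) +
             if (tau_e > 0) (1 - S2) * tp / (1 + (w * tp)^2) else 0)
  }
  d <- (mu0 / (4 * pi)) * hbar * gH * gN / r_nh^3
  d2 <- d^2 / 4
  c2 <- (wN * csa)^2 / 3
  R1 <- d2 * (J(wH - wN) + 3 * J(wN) + 6 * J(wH + wN)) + c2 * J(wN)
  R2 <- d2 / 2 * (4 * J(0) + J(wH - wN) + 3 * J(wN) + 6 * J(wH) +
                    6 * J(wH + wN)) + c2 / 6 * (4 * J(0) + 3 * J(wN))
  NOE <- 1 + d2 * (gH / gN) * (6 * J(wH + wN) - J(wH - wN)) / R1
  c(R1 = R1, R2 = R2, hetNOE = NOE)
}

# dense series matrix exponential with scaling and squaring -- a different
# algorithm from the package's eigendecomposition route
oracle_expm <- function(A) {
  n <- nrow(A)
  nrm <- max(rowSums(Mod(A)))
  j <- max(0L, ceiling(log2(max(nrm, 1))) + 4L)
  As <- A / 2^j
  E <- diag(1 + 0i, n); term <- diag(1 + 0i, n)
  for (k in 1:25) {
    term <- term %*% As / k
    E <- E + term
  }
  for (k in seq_len(j)) E <- E %*% E
  E
}

# amplitude-read-out CPMG propagation using oracle_expm, step by step
# (no two-echo squaring shortcut)
oracle_bm_amplitude <- function(network, mhz, nu, trelax, nucleus = "N") {
  f <- field_context(mhz)
  omega <- ppm_to_rad(network$offsets_ppm, f, nucleus)
  r2 <- if (is.list(network$r2)) network$r2[[as.character(mhz)]] else
    rep_len(network$r2, network$n)
  A <- t(network$K) + 1i * diag(omega, network$n) - diag(r2, network$n)
  vapply(nu, function(v) {
    n_echo <- as.integer(round(2 * trelax * v))
    tau_cp <- trelax / (2 * n_echo)
    P <- oracle_expm(A * tau_cp)
    m <- as.complex(network$pi)
    for (k in seq_len(n_echo)) m <- P %*% Conj(P %*% m)
    -log(Mod(sum(m)) / sum(network$pi)) / trelax
  }, numeric(1))
}

# brute-force pair tally for transition counts
oracle_counts <- function(dtraj, lag, n) {
  C <- matrix(0, n, n)
  for (i in seq_len(length(dtraj) - lag)) {
    C[dtraj[i] + 1, dtraj[i + lag] + 1] <- C[dtraj[i] + 1, dtraj[i + lag] + 1] + 1
  }
  C
}

# detailed-balance violation of an msm
db_violation <- function(m) {
  P <- m$pi * m$T
  max(abs(P - t(P)))
}

# a well-spaced CPMG grid compatible with trelax = 0.04
cpmg_grid <- function() seq(50, 1000, by = 50)
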