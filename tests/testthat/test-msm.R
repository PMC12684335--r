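test_that("transition counts match direct tallies", {
  expect_equal(count_matrix(c(0L, 1L, 0L, 1L, 0L), 1),
               matrix(c(0, 2, 2, 0), 2, 2))
  expect_equal(count_matrix(rep(2L, 10), 1, n_states = 3)[3, 3], 9)
  # seeded CTMC sample against the brute-force pair tally
  K <- matrix(c(-200, 150, 50, 80, -120, 40, 30, 70, -100), 3, 3,
              byrow = TRUE)
  d <- simulate_ctmc(K, 1e-4, 5000, seed = 12)
  expect_equal(count_matrix(d, 3), oracle_counts(d, 3, 3))
  expect_error(count_matrix(c(0L, 1L), 5), "lag")
})

test_that("reversible estimates satisfy detailed balance to 1e-10", {
  K <- matrix(c(-200, 150, 50, 80, -120, 40, 30, 70, -100), 3, 3,
              byrow = TRUE)
  for (seed in 1:3) {
    d <- simulate_ctmc(K, 1e-4, 20000, seed = seed)
    m <- estimate_msm(count_matrix(d, 2), lag = 2, dt = 1e-4)
    expect_lt(db_violation(m), 1e-10)
    expect_equal(rowSums(m$T), rep(1, 3), tolerance = 1e-10)
    expect_equal(as.numeric(m$pi %*% m$T), m$pi, tolerance = 1e-9)
  }
})

test_that("symmetric counts give the closed-form answer", {
  m <- estimate_msm(matrix(c(9, 1, 1, 9), 2, 2))
  expect_equal(m$pi, c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(m$T, matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2), tolerance = 1e-9)
})

test_that("stationary distribution recovers the planted truth", {
  K <- matrix(c(-300, 250, 50, 100, -150, 50, 20, 60, -80), 3, 3,
              byrow = TRUE)
  pi_true <- colchidyn:::stationary_from_K(K)
  dt <- 1e-4; nf <- 1e5
  d <- simulate_ctmc(K, dt, nf, seed = 99)
  m <- estimate_msm(count_matrix(d, 1), lag = 1, dt = dt)
  # 3 sigma on the occupancy, with the effective sample size set by the
  # slowest relaxation time of the planted chain (frames are correlated)
  lam <- sort(Re(eigen(K, only.values = TRUE)$values), decreasing = TRUE)
  t_slow <- 1 / abs(lam[2])                     # seconds
  n_eff <- nf * dt / (2 * t_slow)
  occ <- tabulate(d + 1L, 3) / nf
  for (i in 1:3) {
    se <- sqrt(pi_true[i] * (1 - pi_true[i]) / n_eff)
    expect_lt(abs(occ[i] - pi_true[i]), 3 * se)
    expect_lt(abs(m$pi[i] - pi_true[i]), 3 * se)
  }
})

test_that("disconnected counts are restricted to the largest strong set", {
  C <- matrix(0, 4, 4)
  C[1, 2] <- C[2, 1] <- 50
  C[3, 4] <- C[4, 3] <- 5
  C[1, 1] <- C[2, 2] <- 50; C[3, 3] <- C[4, 4] <- 5
  expect_message(m <- estimate_msm(C), "dropping")
  expect_equal(m$active, c(0L, 1L))
  expect_equal(nrow(m$T), 2)
})

test_that("implied timescales follow the eigenvalue formula", {
  T <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2)
  expect_equal(implied_timescales(T), -1 / log(0.8), tolerance = 1e-12)
  # invariant under state relabeling
  T3 <- matrix(c(0.8, 0.15, 0.05,
                 0.1, 0.8, 0.1,
                 0.05, 0.15, 0.8), 3, 3, byrow = TRUE)
  p <- c(3, 1, 2)
  expect_equal(implied_timescales(T3), implied_timescales(T3[p, p]),
               tolerance = 1e-9)
  # identity chain: nothing relaxes
  expect_true(all(is.infinite(implied_timescales(diag(3)))))
})

make_block_T <- function(n_blocks, per = 4, intra = 0.2, inter = 0.001) {
  n <- n_blocks * per
  blocks <- rep(seq_len(n_blocks), each = per)
  T <- matrix(inter, n, n)
  for (b in seq_len(n_blocks)) T[blocks == b, blocks == b] <- intra
  list(T = T / rowSums(T), blocks = blocks)
}

test_that("coarse-graining recovers planted metastable partitions", {
  for (nb in 2:4) {
    bt <- make_block_T(nb)
    set.seed(100 + nb)
    # sample a trajectory from the block chain
    n <- nrow(bt$T); s <- 1L; traj <- integer(15000)
    for (i in seq_along(traj)) {
      traj[i] <- s - 1L
      s <- sample.int(n, 1, prob = bt$T[s, ])
    }
    m <- estimate_msm(count_matrix(traj, 1))
    cg <- coarse_grain(m, nb)
    # each planted block maps to exactly one macrostate
    tab <- table(cg$assignment, bt$blocks[m$active + 1])
    expect_true(all(colSums(tab > 0) == 1))
    expect_equal(sum(cg$pi_macro), 1, tolerance = 1e-12)
    expect_true(all(abs(rowSums(cg$membership) - 1) < 1e-9))
    expect_true(all(cg$membership >= 0 & cg$membership <= 1 + 1e-12))
  }
})

test_that("single-macrostate coarse model is trivial", {
  m <- estimate_msm(matrix(c(9, 1, 1, 9), 2, 2))
  cg <- coarse_grain(m, 1)
  expect_equal(cg$pi_macro, 1)
  expect_equal(cg$assignment, c(1L, 1L))
})

test_that("generator round-trips through the matrix exponential", {
  K <- matrix(c(-0.3, 0.2, 0.1,
                0.05, -0.1, 0.05,
                0.1, 0.3, -0.4), 3, 3, byrow = TRUE)
  tau <- 0.5
  T <- Re(colchidyn:::expm_taylor((K * tau) + 0i))
  g <- generator_from_tmatrix(T, tau)
  expect_lt(max(abs(g$K - K)) / max(abs(K)), 1e-6)
  expect_true(all(abs(rowSums(g$K)) < 1e-10))
  # independent matrix-logarithm route
  expect_equal(g$K, pracma::logm(T) / tau, tolerance = 1e-8)
  expect_equal(generator_from_tmatrix(diag(3), 1)$K, matrix(0, 3, 3))
  # oscillatory/negative spectrum has no generator
  bad <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(generator_from_tmatrix(bad, 1), "logarithm")
})

test_that("dtraj files round-trip", {
  d <- simulate_ctmc(matrix(c(-5, 5, 5, -5), 2, 2), 0.01, 100, seed = 2)
  p <- tempfile()
  writeLines(as.character(d), p)
  expect_equal(read_dtrajs(p)[[1]], as.integer(d))
  unlink(p)
})
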